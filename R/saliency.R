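# Grad-CAM ageing salience. For a regression head the backpropagated
# scalar is the predicted age itself; the target layer is the last
# convolutional feature map before global pooling.

#' Grad-CAM context for one subject
#'
#' Runs the model forward on one image, retaining the final
#' convolutional feature stack `F` (`h x w x K`, post-ReLU), and
#' computes the exact gradient of the scalar output with respect to
#' every element of `F` by backpropagation through the
#' global-average-pooling + linear head.
#'
#' @param model a trained [AgeModel-class].
#' @param image an [AgedImage-class] or pixel matrix.
#' @param extraChannel optional salience matrix as channel 2.
#' @return list with `F` (h x w x K), `grad` (same shape), `Z` (pixels
#'   per map) and `yhat`.
#' @export
gradCamContext <- function(model, image, extraChannel = NULL) {
  px <- if (is(image, "AgedImage")) pixels(image) else image
  x <- stackImages(list(px), if (!is.null(extraChannel))
    list(extraChannel))
  if (dim(x)[3] != model@inputChannels)
    stop("input channel count does not match the model")
  fw <- forwardPass(model@weights, x, retain = TRUE)
  d <- dim(fw$a3)
  F3 <- array(fw$a3, dim = d[1:3])
  Z <- d[1] * d[2]
  # d yhat / d F_ij^k through GAP + linear head: fcW_k / Z everywhere
  grad <- array(rep(model@weights$fcW / Z, each = Z), dim = d[1:3])
  list(F = F3, grad = grad, Z = Z, yhat = fw$yhat)
}

#' Grad-CAM channel weights
#'
#' `w_k = (1/Z) * sum_ij d(yhat)/d(F_ij^k)`: the spatial mean of the
#' gradient of the model output over each feature map.
#'
#' @param ctx a context from [gradCamContext()] (fields `F`, `grad`,
#'   `Z`).
#' @return numeric vector of K weights.
#' @export
channelWeights <- function(ctx) {
  if (is.null(ctx$grad)) stop("gradients missing from Grad-CAM context")
  d <- dim(ctx$grad)
  colMeans(matrix(ctx$grad, d[1] * d[2], d[3]))
}

#' Raw ageing salience map
#'
#' `M = ReLU(sum_k w_k F^k)` at feature-map resolution; no
#' normalization at this step.
#'
#' @param ctx a context from [gradCamContext()].
#' @param weights K channel weights from [channelWeights()].
#' @param id,age metadata carried on the result.
#' @return a raw [SalienceMap-class] (`normalized = FALSE`).
#' @export
salienceMap <- function(ctx, weights, id = "subject", age = NA_real_) {
  d <- dim(ctx$F)
  if (length(weights) != d[3])
    stop("weights length must equal the number of feature maps")
  m <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) m <- m + weights[k] * ctx$F[, , k]
  m <- pmax(m, 0)
  new("SalienceMap", values = m, id = id, age = age, normalized = FALSE)
}

#' Upsample a salience map to the image grid
#'
#' Bilinear upsampling to the preprocessed image resolution; when
#' `normalize`, min-max scales to `[0, 1]` (an identically zero map
#' stays zero).
#'
#' @param map a [SalienceMap-class].
#' @param target `(H, W)` image grid.
#' @param normalize logical.
#' @return a [SalienceMap-class] on the target grid.
#' @export
toImageGrid <- function(map, target, normalize = TRUE) {
  v <- mapValues(map)
  if (target[1] < nrow(v) || target[2] < ncol(v))
    stop("target grid must be at least the source resolution")
  v <- resizeBilinear(v, target)
  v <- pmax(v, 0)
  if (normalize) {
    rng <- range(v)
    if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
    else if (rng[2] > 0) v <- v / rng[2]
  }
  new("SalienceMap", values = v, id = map@id, age = map@age,
      normalized = normalize)
}

#' Full per-subject salience computation
#'
#' Context, channel weights, weighted map and upsampling in one call.
#'
#' @inheritParams gradCamContext
#' @param target `(H, W)` output grid; defaults to the image size.
#' @param normalize min-max normalize to `[0, 1]` (the default; makes
#'   subjects comparable in the per-age average).
#' @return a [SalienceMap-class] on the image grid.
#' @export
subjectSalience <- function(model, image, target = NULL,
                            extraChannel = NULL, normalize = TRUE) {
  px <- if (is(image, "AgedImage")) pixels(image) else image
  if (is.null(target)) target <- dim(px)
  ctx <- gradCamContext(model, image, extraChannel)
  m <- salienceMap(ctx, channelWeights(ctx),
                   id = if (is(image, "AgedImage")) image@id else "subject",
                   age = if (is(image, "AgedImage")) image@age else NA_real_)
  toImageGrid(m, target, normalize)
}

#' Salience maps for a whole cohort
#'
#' @param model a trained baseline [AgeModel-class].
#' @param cohort a [PhantomCohort-class].
#' @param which optional manifest row indices (default all).
#' @param normalize per-map min-max normalization (default TRUE).
#' @return list of [SalienceMap-class] on the image grid.
#' @export
cohortSalience <- function(model, cohort, which = NULL, normalize = TRUE) {
  images <- cohortImages(cohort)
  if (is.null(which)) which <- seq_along(images)
  lapply(which, function(i)
    subjectSalience(model, images[[i]], normalize = normalize))
}
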