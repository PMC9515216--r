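# tiny-cnn age regressor: forward/backward passes over the Rcpp conv
# kernels, trained with L1 loss and Adam. Arrays are (H, W, C, N),
# column-major.

#' Mean absolute (L1) training loss
#'
#' `(1/N) * sum(|pred - true|)` in years.
#'
#' @param pred,true numeric age vectors of equal length.
#' @return scalar loss in years.
#' @export
l1Loss <- function(pred, true) {
  if (length(pred) == 0L || length(pred) != length(true))
    stop("pred and true must be equal-length, non-empty vectors")
  mean(abs(pred - true))
}

# He-normal initialization of all weights from one seed.
initWeights <- function(backbone, seed) {
  ch <- c(backbone$inputChannels, backbone$channels)
  withSeed(seed, {
    w <- list()
    for (i in 1:3) {
      fan <- 9 * ch[i]
      w[[paste0("W", i)]] <- array(rnorm(9 * ch[i] * ch[i + 1],
                                         sd = sqrt(2 / fan)),
                                   dim = c(3, 3, ch[i], ch[i + 1]))
      w[[paste0("b", i)]] <- numeric(ch[i + 1])
    }
    w$fcW <- rnorm(ch[4], sd = sqrt(1 / ch[4]))
    w$fcB <- 0
    w
  })
}

# Forward pass; retain = TRUE keeps intermediates for backprop /
# Grad-CAM. Output F3 (post-ReLU final conv map) is the Grad-CAM layer.
forwardPass <- function(weights, x, retain = FALSE) {
  z1 <- cpp_conv2d_fwd(x, weights$W1, weights$b1)
  a1 <- pmax(z1, 0); dim(a1) <- dim(z1)
  p1 <- cpp_maxpool2_fwd(a1)
  z2 <- cpp_conv2d_fwd(p1$out, weights$W2, weights$b2)
  a2 <- pmax(z2, 0); dim(a2) <- dim(z2)
  p2 <- cpp_maxpool2_fwd(a2)
  z3 <- cpp_conv2d_fwd(p2$out, weights$W3, weights$b3)
  a3 <- pmax(z3, 0); dim(a3) <- dim(z3)
  d3 <- dim(a3)
  Z <- d3[1] * d3[2]
  gap <- colMeans(matrix(a3, Z, d3[3] * d3[4]))
  gap <- matrix(gap, d3[3], d3[4])
  yhat <- as.numeric(crossprod(gap, weights$fcW)) + weights$fcB
  if (!retain) return(list(yhat = yhat))
  list(yhat = yhat, x = x, a1 = a1, p1 = p1, a2 = a2, p2 = p2, a3 = a3,
       gap = gap, Z = Z)
}

# Backward pass for dLoss/dyhat vector dy (length N); returns gradient
# list matching the weight list.
backwardPass <- function(weights, cache, dy) {
  d3 <- dim(cache$a3)
  N <- d3[4]; K <- d3[3]; Z <- cache$Z
  gfcW <- as.numeric(cache$gap %*% dy)
  gfcB <- sum(dy)
  # dL/dgap = fcW outer dy; spread uniformly over the Z pixels
  dgap <- outer(weights$fcW, dy)                     # K x N
  da3 <- array(rep(dgap / Z, each = Z), dim = d3)
  da3[cache$a3 <= 0] <- 0
  b3 <- cpp_conv2d_bwd(cache$p2$out, weights$W3, da3)
  dp2 <- cpp_maxpool2_bwd(cache$p2$arg, b3$dx, dim(cache$a2))
  dp2[cache$a2 <= 0] <- 0
  b2 <- cpp_conv2d_bwd(cache$p1$out, weights$W2, dp2)
  dp1 <- cpp_maxpool2_bwd(cache$p1$arg, b2$dx, dim(cache$a1))
  dp1[cache$a1 <= 0] <- 0
  b1 <- cpp_conv2d_bwd(cache$x, weights$W1, dp1)
  list(W1 = b1$dw, b1 = b1$db, W2 = b2$dw, b2 = b2$db,
       W3 = b3$dw, b3 = b3$db, fcW = gfcW, fcB = gfcB)
}

# Stack a list of AgedImages (or matrices) into an (H, W, C, N) array;
# extraChannel: optional list of matrices appended as channel 2.
stackImages <- function(images, extraChannel = NULL) {
  mats <- lapply(images, function(im)
    if (is(im, "AgedImage")) pixels(im) else im)
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]]); N <- length(mats)
  C <- if (is.null(extraChannel)) 1L else 2L
  x <- array(0, dim = c(H, W, C, N))
  for (i in seq_len(N)) {
    x[, , 1, i] <- mats[[i]]
    if (C == 2L) x[, , 2, i] <- extraChannel[[i]]
  }
  x
}

#' Train the age regressor
#'
#' Minimizes the L1 loss with Adam over seeded mini-batches; logs
#' per-epoch train and validation loss and keeps the weights of the
#' best validation epoch. Initialization and batch order are fully
#' determined by `config$seed`.
#'
#' @param cohort a [PhantomCohort-class] whose manifest has a `split`
#'   column (see [splitCohort()]).
#' @param backbone spec from [tinyCnnBackbone()].
#' @param config list: `epochs` (default 30), `batchSize` (32), `lr`
#'   (1e-3, cosine-decayed), `weightDecay` (0.01, decoupled, weights
#'   only), `seed` (1).
#' @param extraChannel optional list of per-subject salience matrices
#'   appended as a second input channel (constrained training).
#' @return a trained [AgeModel-class].
#' @export
trainAgeModel <- function(cohort, backbone = NULL, config = list(),
                          extraChannel = NULL) {
  cfg <- modifyList(list(epochs = 30L, batchSize = 32L, lr = 1e-3,
                         weightDecay = 0.01, seed = 1L), config)
  manifest <- cohortManifest(cohort)
  if (!"split" %in% names(manifest) || all(is.na(manifest$split)))
    stop("cohort has no split plan; call splitCohort() first")
  images <- cohortImages(cohort)
  sz <- dim(pixels(images[[1]]))
  if (is.null(backbone))
    backbone <- tinyCnnBackbone(inputSize = sz,
                                inputChannels = if (is.null(extraChannel)) 1L
                                                else 2L)
  itr <- which(manifest$split == "train")
  iva <- which(manifest$split == "val")
  if (!length(itr)) stop("train split is empty")
  xtr <- stackImages(images[itr],
                     if (!is.null(extraChannel)) extraChannel[itr])
  ytr <- manifest$age[itr]
  xva <- if (length(iva))
    stackImages(images[iva], if (!is.null(extraChannel)) extraChannel[iva])
  else NULL
  yva <- manifest$age[iva]

  weights <- initWeights(backbone, cfg$seed)
  # head bias starts at the training mean age: the constant part of the
  # target is carried by the bias term from step one, not absorbed as
  # spurious positive contributions of constant image structures
  weights$fcB <- mean(ytr)
  mState <- lapply(weights, function(w) w * 0)
  vState <- lapply(weights, function(w) w * 0)
  step <- 0L
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric())
  best <- list(loss = Inf, weights = weights)
  nb <- ceiling(length(itr) / cfg$batchSize)
  for (ep in seq_len(cfg$epochs)) {
    lrEp <- cfg$lr * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs))
    perm <- withSeed(deriveSeed(cfg$seed, ep), sample.int(length(itr)))
    epLoss <- 0
    for (b in seq_len(nb)) {
      sel <- perm[((b - 1) * cfg$batchSize + 1):min(b * cfg$batchSize,
                                                    length(itr))]
      xb <- xtr[, , , sel, drop = FALSE]
      yb <- ytr[sel]
      fw <- forwardPass(weights, xb, retain = TRUE)
      loss <- l1Loss(fw$yhat, yb)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep)
      epLoss <- epLoss + loss * length(sel)
      dy <- sign(fw$yhat - yb) / length(sel)
      grads <- backwardPass(weights, fw, dy)
      step <- step + 1L
      for (nm in names(weights)) {
        g <- grads[[nm]]
        mState[[nm]] <- 0.9 * mState[[nm]] + 0.1 * g
        vState[[nm]] <- 0.999 * vState[[nm]] + 0.001 * g^2
        mh <- mState[[nm]] / (1 - 0.9^step)
        vh <- vState[[nm]] / (1 - 0.999^step)
        upd <- mh / (sqrt(vh) + 1e-8)
        # decoupled weight decay on weights, not biases: features whose
        # activations carry no age signal decay away instead of
        # lingering as constant contributions to the output
        if (nm %in% c("W1", "W2", "W3", "fcW"))
          upd <- upd + cfg$weightDecay * weights[[nm]]
        weights[[nm]] <- weights[[nm]] - lrEp * upd
      }
    }
    trLoss <- epLoss / length(itr)
    vaLoss <- if (!is.null(xva) && length(yva))
      l1Loss(forwardPass(weights, xva)$yhat, yva) else trLoss
    history <- rbind(history, data.frame(epoch = ep, trainLoss = trLoss,
                                         valLoss = vaLoss))
    if (vaLoss <= best$loss) best <- list(loss = vaLoss, weights = weights)
  }
  new("AgeModel", backbone = backbone, weights = best$weights,
      inputChannels = backbone$inputChannels, config = cfg,
      history = history)
}

#' Predict ages for images
#'
#' @param model a trained [AgeModel-class].
#' @param images list of [AgedImage-class] (or matrices), or a
#'   [PhantomCohort-class].
#' @param extraChannel optional list of salience matrices (2-channel
#'   models).
#' @param batchSize forward batch size.
#' @return numeric vector of predicted ages in years.
#' @export
predictAges <- function(model, images, extraChannel = NULL,
                        batchSize = 128L) {
  if (is(images, "PhantomCohort")) images <- cohortImages(images)
  if (is(images, "AgedImage") || is.matrix(images)) images <- list(images)
  n <- length(images)
  out <- numeric(n)
  for (b in seq_len(ceiling(n / batchSize))) {
    sel <- ((b - 1) * batchSize + 1):min(b * batchSize, n)
    x <- stackImages(images[sel],
                     if (!is.null(extraChannel)) extraChannel[sel])
    if (dim(x)[3] != model@inputChannels)
      stop("input channel count does not match the model")
    out[sel] <- forwardPass(model@weights, x)$yhat
  }
  out
}

#' Feature-to-output head of the model
#'
#' Evaluates only the global-average-pooling + linear head on a given
#' final-layer feature stack. Used to check Grad-CAM gradients against
#' finite differences: the head is the map from the target layer to the
#' scalar output.
#'
#' @param model an [AgeModel-class].
#' @param feats array `(h, w, K)` of final-layer features.
#' @return scalar model output (predicted age).
#' @export
headForward <- function(model, feats) {
  d <- dim(feats)
  gap <- colMeans(matrix(feats, d[1] * d[2], d[3]))
  sum(gap * model@weights$fcW) + model@weights$fcB
}

#' Save / load a trained model
#'
#' Single-file serialized weights plus backbone and a config hash.
#'
#' @param model an [AgeModel-class].
#' @param path file path.
#' @return `saveModel`: invisibly, the path; `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(backbone = model@backbone, weights = model@weights,
               inputChannels = model@inputChannels, config = model@config,
               history = model@history,
               hash = configHash(model@config)), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  s <- readRDS(path)
  new("AgeModel", backbone = s$backbone, weights = s$weights,
      inputChannels = s$inputChannels, config = s$config,
      history = s$history)
}

#' MAE of the constant mean-age predictor
#'
#' The no-image baseline: predict the training-split mean age for every
#' test subject. Any useful regressor must beat this.
#'
#' @param cohort a split [PhantomCohort-class].
#' @return scalar MAE in years on the test split.
#' @export
constantBaselineMae <- function(cohort) {
  m <- cohortManifest(cohort)
  mu <- mean(m$age[m$split == "train"])
  mean(abs(m$age[m$split == "test"] - mu))
}
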