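# ARDA: per-age aggregation of normalized salience maps, percentile
# thresholding of ageing-significant regions, per-instance
# quantification, the distribution band, and rendering.

#' Build per-age ARDA maps
#'
#' `A_a = (1/N_a) * sum_n M_{a,n}` element-wise over all normalized
#' salience maps of subjects with completed age `a` (ages binned by
#' `floor`). One map is emitted per integer age with at least one
#' contributor.
#'
#' @param maps list of normalized [SalienceMap-class] on a common grid.
#' @return named list of [ArdaMap-class], names = integer ages.
#' @export
buildArda <- function(maps) {
  if (!length(maps)) stop("no salience maps supplied")
  dims <- vapply(maps, function(m) dim(mapValues(m)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("salience maps are on mixed grids")
  if (!all(vapply(maps, isNormalized, logical(1))))
    stop("salience maps must be normalized before aggregation")
  ages <- vapply(maps, function(m) floor(subjectAge(m)), numeric(1))
  out <- list()
  for (a in sort(unique(ages))) {
    sel <- which(ages == a)
    acc <- mapValues(maps[[sel[1]]])
    if (length(sel) > 1)
      for (i in sel[-1]) acc <- acc + mapValues(maps[[i]])
    out[[as.character(a)]] <- new("ArdaMap", values = acc / length(sel),
                                  age = as.integer(a),
                                  nSubjects = length(sel))
  }
  out
}

levelProb <- function(level)
  switch(level, median = 0.5, p75 = 0.75, p90 = 0.90,
         stop("unknown threshold level: ", level))

#' Ageing-significant region of a map
#'
#' Thresholds at the requested percentile of the map's own pixel values
#' (linear-interpolation quantile); a pixel is significant when its
#' value is `>=` the threshold, so ties are included and a constant map
#' is entirely significant.
#'
#' @param map an [ArdaMap-class] or [SalienceMap-class].
#' @param level `"median"`, `"p75"` or `"p90"`.
#' @return a [SignificantRegion-class].
#' @export
significantRegion <- function(map, level = c("median", "p75", "p90")) {
  level <- match.arg(level)
  v <- mapValues(map)
  if (!length(v)) stop("empty map")
  thr <- unname(quantile(v, levelProb(level), type = 7))
  new("SignificantRegion", mask = v >= thr, level = level,
      thresholdValue = thr)
}

#' Quantify ARDA per anatomical instance
#'
#' For every labeled instance, the mean map value over the intersection
#' of the instance mask with the ageing-significant region. An empty
#' intersection is recorded as missing (`NA`), never as zero.
#'
#' @param map an [ArdaMap-class] (or per-subject [SalienceMap-class]).
#' @param region a [SignificantRegion-class] on the same grid.
#' @param labels integer label matrix aligned to the map.
#' @param instanceNames optional names for label ids `1..k`.
#' @return data.frame (age, instance, level, value, nPixels).
#' @export
quantifyInstances <- function(map, region, labels, instanceNames = NULL) {
  v <- mapValues(map)
  if (!identical(dim(labels), dim(v)) ||
      !identical(dim(regionMask(region)), dim(v)))
    stop("label map and region must align with the map grid")
  age <- if (is(map, "ArdaMap")) mapAge(map) else floor(subjectAge(map))
  ids <- sort(unique(labels[labels > 0]))
  nm <- function(k) {
    if (!is.null(instanceNames) && k <= length(instanceNames))
      instanceNames[k] else paste0("instance", k)
  }
  rows <- lapply(ids, function(k) {
    sel <- labels == k & regionMask(region)
    n <- sum(sel)
    data.frame(age = age, instance = nm(k), level = region@level,
               value = if (n) mean(v[sel]) else NA_real_,
               nPixels = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Quantified-ARDA surface over ages, instances and levels
#'
#' Runs [significantRegion()] and [quantifyInstances()] for every ARDA
#' map and threshold level and returns the tidy long table behind the
#' age x instance x level surface plots: ages ascending, instances in
#' declared order, levels ordered median < p75 < p90. Missing cells
#' stay missing.
#'
#' @param ardaMaps list from [buildArda()].
#' @param labels integer label matrix (shared phantom geometry) or a
#'   function(age) returning one per age.
#' @param instanceNames optional instance names for label ids.
#' @param levels threshold levels to evaluate.
#' @return data.frame (age, instance, level, value, nPixels).
#' @export
ardaSurface <- function(ardaMaps, labels, instanceNames = NULL,
                        levels = c("median", "p75", "p90")) {
  rows <- list()
  for (A in ardaMaps) {
    lab <- if (is.function(labels)) labels(mapAge(A)) else labels
    for (lv in levels) {
      reg <- significantRegion(A, lv)
      rows[[length(rows) + 1]] <-
        quantifyInstances(A, reg, lab, instanceNames)
    }
  }
  out <- do.call(rbind, rows)
  out$level <- factor(out$level, levels = c("median", "p75", "p90"))
  ord <- order(out$age,
               if (!is.null(instanceNames))
                 match(out$instance, instanceNames) else out$instance,
               out$level)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-subject instance salience statistics
#'
#' For each subject, thresholds that subject's own normalized salience
#' map at `level` and quantifies each instance; then returns the mean
#' and standard deviation of these per-subject values across subjects
#' of the same completed age -- the data behind the distribution-band
#' plot.
#'
#' @param maps list of normalized [SalienceMap-class] on the image grid.
#' @param labels label matrix or function(age) -> matrix.
#' @param instanceNames optional names for label ids.
#' @param level threshold level (default `"p75"`, as in the band plot).
#' @return data.frame (instance, age, mu, sigma, n).
#' @export
instanceStats <- function(maps, labels, instanceNames = NULL,
                          level = "p75") {
  per <- lapply(maps, function(m) {
    lab <- if (is.function(labels)) labels(floor(subjectAge(m))) else labels
    q <- quantifyInstances(m, significantRegion(m, level), lab,
                           instanceNames)
    q$age <- floor(subjectAge(m))
    q
  })
  all <- do.call(rbind, per)
  agg <- aggregate(value ~ instance + age, data = all,
                   FUN = function(v) c(mu = mean(v), sigma = sd(v),
                                       n = length(v)),
                   na.action = stats::na.omit)
  out <- data.frame(instance = agg$instance, age = agg$age,
                    mu = agg$value[, "mu"], sigma = agg$value[, "sigma"],
                    n = agg$value[, "n"], stringsAsFactors = FALSE)
  out[order(out$instance, out$age), , drop = FALSE]
}

#' Normal distribution band for quantified salience
#'
#' `mu +/- k*sigma` with the ideal-normal coverage
#' `100 * (Phi(k) - Phi(-k))` percent, two decimals. With
#' `mu = 0.089, sigma = 0.015, k = 2` the band is `(0.059, 0.119)` with
#' 95.45% coverage.
#'
#' @param mu,sigma mean and standard deviation (`sigma >= 0`).
#' @param kSigma band half-width in standard deviations.
#' @return list `low`, `high`, `coveragePct`.
#' @export
normalBand <- function(mu, sigma, kSigma = 2) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  list(low = mu - kSigma * sigma, high = mu + kSigma * sigma,
       coveragePct = round(100 * (pnorm(kSigma) - pnorm(-kSigma)), 2))
}

#' Render an ARDA map over its base image
#'
#' Maps salience through a blue-to-red colormap (0 = blue, 1 = red) and
#' alpha-blends it over the grayscale base. Deterministic for fixed
#' inputs; rendering never alters quantification values.
#'
#' @param map an [ArdaMap-class] or [SalienceMap-class].
#' @param base an [AgedImage-class] on the same grid (or `NULL` for the
#'   colormap alone).
#' @param alpha blend weight of the colormap in `[0, 1]`.
#' @return `(H, W, 3)` RGB array in `[0, 1]`.
#' @export
renderArda <- function(map, base = NULL, alpha = 0.5) {
  v <- mapValues(map)
  if (!is.null(base) && !identical(dim(pixels(base)), dim(v)))
    stop("base image grid does not match the map")
  ramp <- colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(clamp01(as.numeric(v))) / 255
  H <- nrow(v); W <- ncol(v)
  rgb <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(cols[, ch], H, W)
  if (is.null(base)) return(rgb)
  g <- pixels(base)
  out <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) out[, , ch] <- (1 - alpha) * g + alpha * rgb[, , ch]
  clamp01(out)
}
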