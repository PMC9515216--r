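# Attention-constrained age estimation and two-pass retest inference.
# The salience channel is always the subject's own Grad-CAM map from
# the frozen baseline model, min-max normalized on the image grid.

#' Construct a retest configuration
#'
#' @param baseline single-channel [AgeModel-class].
#' @param constrained two-channel [AgeModel-class] from
#'   [trainConstrained()].
#' @param ka age threshold in years; 25 by default, the boundary
#'   between the 4-25 and 26-40 reporting super-groups.
#' @return a [RetestConfig-class].
#' @export
retestConfig <- function(baseline, constrained, ka = 25) {
  new("RetestConfig", ka = ka, baseline = baseline,
      constrained = constrained)
}

# Salience channel for each cohort subject from the frozen baseline.
salienceChannels <- function(baseline, cohort) {
  lapply(cohortImages(cohort), function(im)
    mapValues(subjectSalience(baseline, im)))
}

#' Train the attention-constrained model
#'
#' Subjects with true age strictly greater than `ka` receive their own
#' baseline Grad-CAM salience map as a second input channel; the rest
#' receive a zero channel, so a single two-channel network serves both
#' regimes at test time. The baseline stays frozen and only generates
#' the salience channels; training minimizes the L1 loss.
#'
#' @param cohort a split [PhantomCohort-class].
#' @param baseline trained single-channel [AgeModel-class].
#' @param ka age threshold in years.
#' @param config training config (see [trainAgeModel()]).
#' @return a two-channel [AgeModel-class].
#' @export
trainConstrained <- function(cohort, baseline, ka = 25, config = list()) {
  if (!is(baseline, "AgeModel") || baseline@inputChannels != 1L)
    stop("a trained single-channel baseline model is required")
  chans <- salienceChannels(baseline, cohort)
  ages <- cohortManifest(cohort)$age
  zero <- matrix(0, nrow(chans[[1]]), ncol(chans[[1]]))
  chans <- lapply(seq_along(chans), function(i)
    if (ages[i] > ka) chans[[i]] else zero)
  trainAgeModel(cohort, config = config, extraChannel = chans)
}

#' Two-pass retest prediction
#'
#' Pass 1: the baseline predicts `y1`. If `y1 <= ka` the subject is not
#' retested and `y1` is final. If `y1` is strictly greater than `ka`,
#' the subject's salience map is computed from the baseline,
#' concatenated to the image, and the constrained model's prediction
#' `y2` becomes final. Exactly one retest at most.
#'
#' @param images list of [AgedImage-class] or a [PhantomCohort-class].
#' @param config a [RetestConfig-class].
#' @return trace data.frame (id, y, y1, retested, y2, final).
#' @export
retestPredict <- function(images, config) {
  if (is(images, "PhantomCohort")) images <- cohortImages(images)
  if (is(images, "AgedImage")) images <- list(images)
  y1 <- predictAges(config@baseline, images)
  retested <- y1 > config@ka
  y2 <- rep(NA_real_, length(images))
  if (any(retested)) {
    idx <- which(retested)
    chans <- lapply(images[idx], function(im)
      mapValues(subjectSalience(config@baseline, im)))
    y2[idx] <- predictAges(config@constrained, images[idx],
                           extraChannel = chans)
  }
  data.frame(
    id = vapply(images, function(im) im@id, character(1)),
    y = vapply(images, subjectAge, numeric(1)),
    y1 = y1, retested = retested, y2 = y2,
    final = ifelse(retested, y2, y1),
    stringsAsFactors = FALSE)
}

#' Audit a retest trace
#'
#' Checks the retest contract on every row: retested if and only if the
#' first pass exceeded `ka`, and the final prediction equals the second
#' pass when retested and the first pass otherwise.
#'
#' @param trace data.frame from [retestPredict()].
#' @param ka the threshold used.
#' @return number of violating rows (0 on a clean trace).
#' @export
auditTrace <- function(trace, ka) {
  bad <- (trace$retested != (trace$y1 > ka)) |
    (trace$retested & (is.na(trace$y2) | trace$final != trace$y2)) |
    (!trace$retested & trace$final != trace$y1)
  sum(bad)
}

#' Compare baseline, always-constrained and retest inference
#'
#' Evaluates the three inference modes on the identical test split:
#' the baseline alone; the constrained model with every subject's
#' salience channel (always-constrained); and the two-pass retest. The
#' metric tables share the age-group layout of the evaluation suite.
#'
#' @param cohort a split [PhantomCohort-class].
#' @param config a [RetestConfig-class].
#' @return list of metric data.frames `baseline`, `constrained`,
#'   `retest`, plus the retest `trace`.
#' @export
compareConditions <- function(cohort, config) {
  m <- cohortManifest(cohort)
  sel <- which(m$split == "test")
  images <- cohortImages(cohort)[sel]
  base <- data.frame(id = m$id[sel], y = m$age[sel],
                     yPred = predictAges(config@baseline, images))
  chans <- lapply(images, function(im)
    mapValues(subjectSalience(config@baseline, im)))
  cons <- data.frame(id = m$id[sel], y = m$age[sel],
                     yPred = predictAges(config@constrained, images,
                                         extraChannel = chans))
  trace <- retestPredict(images, config)
  rts <- data.frame(id = trace$id, y = trace$y, yPred = trace$final)
  list(baseline = evaluatePredictions(base),
       constrained = evaluatePredictions(cons),
       retest = evaluatePredictions(rts),
       trace = trace)
}
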