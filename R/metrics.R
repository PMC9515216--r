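# Evaluation metric suite: MAE +/- SD of absolute error, median signed
# error, IQR of absolute error, cumulative score CS-5 and its mean
# cumulative variant, reported per age group and overall.

#' Cumulative score at a year threshold
#'
#' `CS-j = 100 * fraction of subjects with |error| <= j` years.
#'
#' @param err signed errors (pred - true) in years.
#' @param j threshold in years.
#' @return percentage.
#' @export
cumulativeScore <- function(err, j = 5) 100 * mean(abs(err) <= j)

#' Mean cumulative score over 1..5 years
#'
#' Implemented as the mean of CS-j for j = 1..5, a standard reading of
#' "mean cumulative score". Isolated in this one function so another
#' definition can be swapped in.
#'
#' @param err signed errors in years.
#' @return percentage.
#' @export
meanCumulativeScore5 <- function(err)
  mean(vapply(1:5, function(j) cumulativeScore(err, j), numeric(1)))

#' Percent reduction between two positive scalars
#'
#' `100 * (old - new) / old`, reported to two decimals. Used to express
#' stability gains, e.g. an SD drop from 2.24 to 1.54 years is a 31.25%
#' reduction.
#'
#' @param old,new positive scalars.
#' @return percentage, rounded to two decimals.
#' @export
percentReduction <- function(old, new) {
  if (!is.finite(old) || old <= 0) stop("old value must be positive")
  round(100 * (old - new) / old, 2)
}

metricsRow <- function(group, y, yp) {
  err <- yp - y
  ae <- abs(err)
  data.frame(group = group, n = length(y),
             MAE = mean(ae), SD = sd(ae),
             ME.Med = median(err), IQR = IQR(ae),
             CS5 = cumulativeScore(err, 5),
             MCS5 = meanCumulativeScore5(err),
             stringsAsFactors = FALSE)
}

# Brute-force recomputation used as a built-in self-check of every
# report: explicit loops, no shared code with metricsRow's vectorized
# path beyond base arithmetic.
metricsRowLoop <- function(y, yp) {
  n <- length(y)
  s <- 0; for (i in seq_len(n)) s <- s + abs(yp[i] - y[i])
  mae <- s / n
  cs <- 0; for (i in seq_len(n)) if (abs(yp[i] - y[i]) <= 5) cs <- cs + 1
  c(MAE = mae, CS5 = 100 * cs / n)
}

#' Evaluate a prediction set
#'
#' Builds the full metric table: one row per age group (the seven
#' five-year bins), the 4-25 and 26-40 super-groups, and an `All` row.
#' Every row is cross-checked against an independent loop recomputation
#' of MAE and CS-5; a disagreement aborts.
#'
#' @param preds data.frame with columns `y` (true age) and `yPred`.
#' @return data.frame of metrics (years; CS in percent).
#' @export
evaluatePredictions <- function(preds) {
  if (!nrow(preds)) stop("empty prediction set")
  grp <- as.character(ageGroup(preds$y))
  rows <- list()
  addRow <- function(name, sel) {
    if (!any(sel)) return()
    r <- metricsRow(name, preds$y[sel], preds$yPred[sel])
    chk <- metricsRowLoop(preds$y[sel], preds$yPred[sel])
    stopifnot(abs(r$MAE - chk["MAE"]) < 1e-9,
              abs(r$CS5 - chk["CS5"]) < 1e-9)
    rows[[length(rows) + 1]] <<- r
  }
  for (g in levels(ageGroup(4)))
    addRow(g, grp == g)
  addRow("4-25", preds$y < 26)
  addRow("26-40", preds$y >= 26)
  addRow("All", rep(TRUE, nrow(preds)))
  do.call(rbind, rows)
}

#' Build a prediction set for a cohort split
#'
#' @param model an [AgeModel-class].
#' @param cohort a split [PhantomCohort-class].
#' @param split which split to evaluate (default `"test"`).
#' @param extraChannel optional salience channel list (full cohort
#'   order).
#' @return data.frame (id, y, yPred, split, ageGroup).
#' @export
predictionSet <- function(model, cohort, split = "test",
                          extraChannel = NULL) {
  m <- cohortManifest(cohort)
  sel <- which(m$split == split)
  yp <- predictAges(model, cohortImages(cohort)[sel],
                    if (!is.null(extraChannel)) extraChannel[sel])
  data.frame(id = m$id[sel], y = m$age[sel], yPred = yp, split = split,
             ageGroup = as.character(ageGroup(m$age[sel])),
             stringsAsFactors = FALSE)
}
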