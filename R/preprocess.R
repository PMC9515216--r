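# Reading, screening, preprocessing and split planning. All geometry
# follows the package convention: 0-based (row, column) indexing,
# half-open crop intervals, gray values in [0, 1].

#' Read a grayscale PNG as a matrix in `[0, 1]`
#'
#' Multichannel PNGs are converted by averaging the color channels.
#'
#' @param path PNG file path.
#' @return numeric matrix (rows = image rows).
#' @export
readGrayPNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3])], c(1, 2), mean)
  a
}

#' Decimal age from birth and imaging dates
#'
#' Day count divided by 365.25 (accounting for leap years), rounded to
#' the nearest hundredth of a year.
#'
#' @param birthDate,imagingDate `Date` objects (or strings coercible).
#' @return decimal age in years.
#' @export
#' @examples
#' decimalAge(as.Date("2000-01-01"), as.Date("2020-01-01"))
decimalAge <- function(birthDate, imagingDate) {
  b <- as.Date(birthDate); d <- as.Date(imagingDate)
  days <- as.numeric(d - b)
  if (any(days < 0)) stop("imaging date precedes birth date")
  round(days / 365.25, 2)
}

#' The seven age groups of the study design
#'
#' Bins 4-10, 11-15, 16-20, 21-25, 26-30, 31-35, 36-40 on completed
#' years.
#'
#' @param age decimal ages in years.
#' @return factor of group labels.
#' @export
ageGroup <- function(age) {
  if (any(age < 4 | age > 40)) stop("ages must lie in [4, 40]")
  edges <- c(4, 11, 16, 21, 26, 31, 36, 41)
  labs <- c("4-10", "11-15", "16-20", "21-25", "26-30", "31-35", "36-40")
  cut(floor(age), breaks = edges, labels = labs, right = FALSE)
}

#' Screen an image for study eligibility
#'
#' Sets the `age_out_of_range` flag when the age falls outside 4-40
#' years; the `incomplete`, `restoration` and `posture` flags are
#' pass-through manual annotations supplied by the caller (these defects
#' are screened visually, not detected algorithmically).
#'
#' @param image an [AgedImage-class].
#' @param annotations character subset of
#'   `c("incomplete", "restoration", "posture")`.
#' @return the image with `qcFlags` set.
#' @export
screenImage <- function(image, annotations = character()) {
  if (is.na(image@age)) stop("age metadata missing")
  bad <- setdiff(annotations, c("incomplete", "restoration", "posture"))
  if (length(bad)) stop("unknown annotation(s): ", paste(bad, collapse = ", "))
  flags <- annotations
  if (image@age < 4 || image@age > 40)
    flags <- c(flags, "age_out_of_range")
  image@qcFlags <- unique(flags)
  image
}

#' Preprocess an image for the network
#'
#' Contrast-limited adaptive histogram equalization (CLAHE, 8x8 tiles),
#' zero-padding to a square frame, then bilinear resizing to the target
#' size; the label map, when present, follows the same geometry with
#' nearest-neighbor sampling. Output intensities are clipped to
#' `[0, 1]`.
#'
#' @param image an [AgedImage-class].
#' @param targetSize `(H, W)` output size.
#' @param claheClip CLAHE clip limit (multiple of the mean tile count;
#'   0 disables contrast enhancement).
#' @return the preprocessed [AgedImage-class].
#' @export
preprocessImage <- function(image, targetSize = c(224L, 224L),
                            claheClip = 2) {
  px <- pixels(image)
  stopIfNot2d(px)
  if (claheClip > 0) {
    nt <- max(2L, min(8L, floor(min(dim(px)) / 8)))
    # CLAHE needs tile-aligned dimensions: replicate-pad, equalize, crop
    H <- nrow(px); W <- ncol(px)
    Hp <- as.integer(ceiling(H / nt) * nt)
    Wp <- as.integer(ceiling(W / nt) * nt)
    padded <- px[c(seq_len(H), rep(H, Hp - H)),
                 c(seq_len(W), rep(W, Wp - W)), drop = FALSE]
    e <- EBImage::clahe(EBImage::Image(t(padded)), nx = nt, ny = nt,
                        limit = claheClip)
    px <- t(EBImage::imageData(e))[seq_len(H), seq_len(W), drop = FALSE]
  }
  px <- clamp01(resizeBilinear(padSquare(px), targetSize))
  lm <- labelMap(image)
  if (!is.null(lm)) {
    lm <- resizeNearest(padSquare(lm), targetSize)
    storage.mode(lm) <- "integer"
  }
  AgedImage(px, age = image@age, id = image@id,
            orientation = image@orientation, labelMap = lm,
            qcFlags = image@qcFlags)
}

#' Seeded augmentation: random affine plus horizontal flip
#'
#' Draws a rotation, translation and isotropic scale uniformly within
#' the configured bounds and flips horizontally with probability
#' `flipProb`; a flip toggles the stored orientation. The label map
#' follows with nearest-neighbor sampling. Deterministic given the
#' seed.
#'
#' @param image a preprocessed [AgedImage-class].
#' @param seed integer seed.
#' @param rotation max |rotation| in degrees.
#' @param translation max |translation| as a fraction of the image size.
#' @param scaleRange `(low, high)` isotropic scale bounds.
#' @param flipProb horizontal-flip probability.
#' @return the augmented [AgedImage-class].
#' @export
augmentImage <- function(image, seed, rotation = 10, translation = 0.05,
                         scaleRange = c(0.9, 1.1), flipProb = 0.5) {
  draws <- withSeed(seed, list(
    rot = runif(1, -rotation, rotation),
    ty = runif(1, -translation, translation),
    tx = runif(1, -translation, translation),
    sc = runif(1, scaleRange[1], scaleRange[2]),
    flip = runif(1) < flipProb))
  px <- pixels(image); lm <- labelMap(image)
  identityAffine <- draws$rot == 0 && draws$ty == 0 && draws$tx == 0 &&
    draws$sc == 1
  if (!identityAffine) {
    px <- affineSample(px, draws$rot, c(draws$ty, draws$tx), draws$sc)
    if (!is.null(lm)) {
      lm <- affineSample(lm, draws$rot, c(draws$ty, draws$tx), draws$sc,
                         interp = "nearest")
      storage.mode(lm) <- "integer"
    }
  }
  ori <- image@orientation
  if (draws$flip) {
    px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
    if (!is.null(lm)) lm <- lm[, rev(seq_len(ncol(lm))), drop = FALSE]
    ori <- if (ori == "right-facing") "left-facing" else "right-facing"
  }
  AgedImage(clamp01(px), age = image@age, id = image@id, orientation = ori,
            labelMap = lm, qcFlags = image@qcFlags)
}

#' Age-group-stratified train/val/test split
#'
#' Within each of the seven age groups, subjects are assigned to splits
#' in the given fractions using largest-remainder apportionment and a
#' seeded permutation, so splits are disjoint, exhaustive and
#' reproducible. Empty groups are skipped with a warning.
#'
#' @param manifest data.frame with an `age` column.
#' @param fractions `(train, val, test)` fractions summing to 1.
#' @param seed integer seed.
#' @return the manifest with a `split` column.
#' @export
stratifiedSplit <- function(manifest, fractions = c(0.70, 0.15, 0.15),
                            seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  groups <- ageGroup(manifest$age)
  split <- rep(NA_character_, nrow(manifest))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    n <- length(idx)
    if (!n) { warning("empty age group skipped: ", g); next }
    base <- floor(n * fractions)
    rem <- n * fractions - base
    extra <- n - sum(base)
    if (extra > 0) {
      give <- order(rem, decreasing = TRUE)[seq_len(extra)]
      base[give] <- base[give] + 1L
    }
    lab <- rep(c("train", "val", "test"), times = base)
    perm <- withSeed(deriveSeed(seed, match(g, levels(groups))),
                     sample.int(n))
    split[idx[perm]] <- lab
  }
  manifest$split <- split
  manifest
}

#' Apply a split plan to a cohort
#'
#' @param cohort a [PhantomCohort-class].
#' @inheritParams stratifiedSplit
#' @return the cohort with its manifest's `split` column filled.
#' @export
splitCohort <- function(cohort, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  cohort@manifest <- stratifiedSplit(cohort@manifest, fractions, seed)
  cohort
}
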