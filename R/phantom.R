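# Synthetic ageing-phantom generator. Each instance is an analytic
# shape whose linear size follows a piecewise-multiplicative age
# response: fast fractional change per year during development, slow
# change after the stage break. With known per-instance change rates the
# phantom provides ground truth for attention-recovery tests.

#' Construct a phantom cohort configuration
#'
#' Defaults mirror the study conditions: ages 4-40 years, one
#' fast-changing instance (a tooth row, emulating dental development and
#' wear), one slow-changing instance (a cranial ellipse) and one static
#' distractor (a rectangular block), on a blank background with mild
#' additive acquisition noise.
#'
#' @param nSubjects number of subjects.
#' @param ageMin,ageMax age range in years.
#' @param imageSize `(H, W)` in pixels.
#' @param instances list of [PhantomInstanceSpec-class]; `NULL` for the
#'   default three-instance set.
#' @param noiseSd additive truncated-Gaussian noise SD (gray units).
#' @param seed integer cohort seed.
#' @return a [PhantomCohortConfig-class].
#' @export
phantomCohortConfig <- function(nSubjects = 100L, ageMin = 4, ageMax = 40,
                                imageSize = c(128L, 128L), instances = NULL,
                                noiseSd = 0.01, seed = 1L) {
  if (is.null(instances)) instances <- defaultPhantomInstances()
  new("PhantomCohortConfig", nSubjects = as.integer(nSubjects),
      ageMin = ageMin, ageMax = ageMax, imageSize = as.integer(imageSize),
      instances = instances, noiseSd = noiseSd, seed = as.integer(seed))
}

#' Default phantom instance set
#'
#' Three instances with distinct age regimes: `tooth_row` changes fast
#' before the stage break (5% of linear size per year) and slowly after
#' (1%/y), `cranium` changes slowly throughout (3%/y then 0.8%/y), and
#' `block` is static. Rates are linear-size fractions per year; the
#' rendered area therefore grows with the square of the size factor.
#'
#' Each instance has a distinct local appearance (periodic tooth
#' texture at 0.9, solid bone-bright ellipse at 0.7, solid low-contrast
#' block at 0.3): as in real radiographs, where materials differ in
#' attenuation, structures must be locally distinguishable for any
#' local-feature attribution to separate them -- a phantom whose static
#' distractor looks identical to an ageing structure pixel-for-pixel
#' poses an unidentifiable problem, not a harder one.
#'
#' @return list of [PhantomInstanceSpec-class].
#' @export
defaultPhantomInstances <- function() {
  list(
    phantomInstance("tooth_row", "tooth-row", center = c(0.5, 0.78),
                    baseSize = c(0.30, 0.09), changeRateYoung = 0.05,
                    changeRateOld = 0.01, stageBreak = 18, intensity = 0.90),
    phantomInstance("cranium", "ellipse", center = c(0.42, 0.30),
                    baseSize = c(0.28, 0.18), changeRateYoung = 0.03,
                    changeRateOld = 0.008, stageBreak = 18, intensity = 0.70),
    phantomInstance("block", "rectangle", center = c(0.85, 0.38),
                    baseSize = c(0.16, 0.36), changeRateYoung = 0,
                    changeRateOld = 0, stageBreak = 18, intensity = 0.30))
}

#' Linear size factor of an instance at a given age
#'
#' Piecewise-multiplicative response anchored at age 4:
#' `(1 + ry)^(min(a, b) - 4) * (1 + ro)^(max(a - b, 0))` for rates
#' `ry`, `ro` and stage break `b`.
#'
#' @param spec a [PhantomInstanceSpec-class].
#' @param age age in years (>= 4).
#' @return positive scalar size factor.
#' @export
instanceSizeFactor <- function(spec, age) {
  b <- spec@stageBreak
  (1 + spec@changeRateYoung)^(pmin(age, b) - 4) *
    (1 + spec@changeRateOld)^(pmax(age - b, 0))
}

# Rasterize one instance onto (pixels, labels). Coordinates: x = column
# fraction, y = row fraction, origin top-left.
rasterInstance <- function(pixels, labels, spec, age, labelId) {
  H <- nrow(pixels); W <- ncol(pixels)
  f <- instanceSizeFactor(spec, age)
  cx <- spec@center[1] * W; cy <- spec@center[2] * H
  hw <- spec@baseSize[1] * f * W / 2   # half width in px
  hh <- spec@baseSize[2] * f * H / 2   # half height in px
  xs <- matrix((seq_len(W) - 0.5), H, W, byrow = TRUE)
  ys <- matrix((seq_len(H) - 0.5), H, W)
  inside <- switch(spec@baseShape,
    ellipse = ((xs - cx) / hw)^2 + ((ys - cy) / hh)^2 <= 1,
    rectangle = abs(xs - cx) <= hw & abs(ys - cy) <= hh,
    arc = {
      # upper half annulus: outer radius from width, thickness 35%
      r <- sqrt(((xs - cx) / hw)^2 + ((ys - cy) / hh)^2)
      r <= 1 & r >= 0.65 & ys <= cy
    },
    `tooth-row` = {
      # four teeth with 70% duty cycle inside the bounding box
      inBox <- abs(xs - cx) <= hw & abs(ys - cy) <= hh
      phase <- ((xs - (cx - hw)) / (2 * hw)) %% 0.25
      inBox & phase <= 0.25 * 0.7
    },
    stop("unknown baseShape: ", spec@baseShape))
  pixels[inside] <- spec@intensity
  labels[inside] <- labelId
  list(pixels = pixels, labels = labels)
}

#' Render one phantom subject
#'
#' Rasterizes every configured instance at its age-dependent size, adds
#' truncated-Gaussian acquisition noise drawn only from the subject seed
#' stream, and clips to `[0, 1]`. Returns the image together with its
#' ground-truth instance label map (instances rendered in declared
#' order; on overlap the later instance owns the pixel).
#'
#' @param config a [PhantomCohortConfig-class].
#' @param age age in years within the configured range.
#' @param subjectSeed integer seed for this subject's noise.
#' @param id subject identifier.
#' @return an [AgedImage-class] with label map.
#' @export
renderSubject <- function(config, age, subjectSeed = 1L, id = "phantom") {
  if (age < config@ageMin || age > config@ageMax)
    stop(sprintf("age %.2f outside configured range [%.2f, %.2f]",
                 age, config@ageMin, config@ageMax))
  H <- config@imageSize[1]; W <- config@imageSize[2]
  pixels <- matrix(0, H, W)
  labels <- matrix(0L, H, W)
  for (i in seq_along(config@instances)) {
    r <- rasterInstance(pixels, labels, config@instances[[i]], age, i)
    pixels <- r$pixels; labels <- r$labels
  }
  if (config@noiseSd > 0) {
    noise <- withSeed(subjectSeed,
                      matrix(rnorm(H * W, 0, config@noiseSd), H, W))
    pixels <- clamp01(pixels + noise)
  }
  AgedImage(pixels, age = round(age, 2), id = id,
            labelMap = labels)
}

#' Generate a full phantom cohort
#'
#' Ages are sampled uniformly over the configured range from the cohort
#' seed and rounded to hundredths of a year; per-subject noise seeds are
#' derived deterministically from the cohort seed, so the same config
#' always regenerates a bit-identical cohort. Optionally writes 8-bit
#' PNG images, integer-label PNG masks and a manifest CSV.
#'
#' @param config a [PhantomCohortConfig-class].
#' @param dir output directory, or `NULL` to keep the cohort in memory.
#' @return a [PhantomCohort-class].
#' @export
generateCohort <- function(config, dir = NULL) {
  n <- config@nSubjects
  ages <- withSeed(config@seed,
                   round(runif(n, config@ageMin, config@ageMax), 2))
  seeds <- vapply(seq_len(n), function(i) deriveSeed(config@seed, i),
                  integer(1))
  ids <- sprintf("ph%05d", seq_len(n))
  images <- lapply(seq_len(n), function(i)
    renderSubject(config, ages[i], seeds[i], ids[i]))
  manifest <- data.frame(id = ids, age = ages,
                         orientation = "right-facing",
                         split = NA_character_, seed = seeds,
                         stringsAsFactors = FALSE)
  cohort <- new("PhantomCohort", images = images, manifest = manifest,
                config = config)
  if (!is.null(dir)) writeCohort(cohort, dir)
  cohort
}

#' Write a phantom cohort to disk
#'
#' Images as 8-bit grayscale PNG, label maps as integer-label PNG
#' (label k stored as gray level k/255), manifest as CSV.
#'
#' @param cohort a [PhantomCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  for (img in cohort@images) {
    png::writePNG(pixels(img), file.path(dir, paste0(img@id, ".png")))
    lm <- labelMap(img)
    if (!is.null(lm))
      png::writePNG(lm / 255, file.path(dir, paste0(img@id, "_labels.png")))
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(cohort@manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `manifest.csv` and PNGs.
#' @return a [PhantomCohort-class] (config slot holds a minimal stub).
#' @export
readCohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    px <- readGrayPNG(file.path(dir, paste0(id, ".png")))
    lp <- file.path(dir, paste0(id, "_labels.png"))
    lm <- if (file.exists(lp)) {
      m <- round(readGrayPNG(lp) * 255)
      storage.mode(m) <- "integer"
      m
    } else NULL
    AgedImage(px, age = manifest$age[i], id = id,
              orientation = manifest$orientation[i], labelMap = lm)
  })
  sz <- dim(pixels(images[[1]]))
  cfg <- phantomCohortConfig(nSubjects = nrow(manifest),
                             imageSize = sz,
                             seed = if ("seed" %in% names(manifest))
                               manifest$seed[1] else 0L)
  new("PhantomCohort", images = images, manifest = manifest, config = cfg)
}
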