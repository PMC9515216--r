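#' AgedImage: one grayscale image with age metadata
#'
#' Container for a single subject: pixel matrix in `[0, 1]`, decimal age
#' in years, facing orientation, an optional integer instance label map
#' aligned to the pixels, and screening flags set by [screenImage()].
#'
#' @slot id character subject identifier.
#' @slot pixels numeric matrix, gray values in `[0, 1]`, rows = image rows.
#' @slot age numeric decimal age in years.
#' @slot orientation `"right-facing"` or `"left-facing"`.
#' @slot labelMap integer matrix of instance labels (0 = background) with
#'   the same dimensions as `pixels`, or a 0x0 matrix when absent.
#' @slot qcFlags character vector of screening flags.
#' @export
setClass("AgedImage",
  representation(id = "character", pixels = "matrix", age = "numeric",
                 orientation = "character", labelMap = "matrix",
                 qcFlags = "character"),
  prototype(id = NA_character_, age = NA_real_,
            orientation = "right-facing",
            labelMap = matrix(integer(), 0, 0), qcFlags = character()),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@pixels) || length(dim(object@pixels)) != 2L)
      msg <- c(msg, "pixels must be a 2D numeric matrix")
    if (length(object@age) != 1L ||
        (!is.na(object@age) && !is.finite(object@age)))
      msg <- c(msg, "age must be a single finite number (or NA)")
    if (!object@orientation %in% c("right-facing", "left-facing"))
      msg <- c(msg, "orientation must be 'right-facing' or 'left-facing'")
    if (length(object@labelMap) &&
        !identical(dim(object@labelMap), dim(object@pixels)))
      msg <- c(msg, "labelMap dimensions must match pixels")
    if (length(msg)) msg else TRUE
  })

#' Construct an AgedImage
#'
#' @param pixels gray matrix in `[0, 1]`.
#' @param age decimal age in years.
#' @param id subject identifier.
#' @param orientation facing direction.
#' @param labelMap optional integer label matrix (`NULL` for none).
#' @param qcFlags screening flags.
#' @return an [AgedImage-class] object.
#' @export
AgedImage <- function(pixels, age, id = "subject",
                      orientation = "right-facing", labelMap = NULL,
                      qcFlags = character()) {
  if (is.null(labelMap)) labelMap <- matrix(integer(), 0, 0)
  storage.mode(labelMap) <- "integer"
  new("AgedImage", id = as.character(id), pixels = pixels,
      age = as.numeric(age), orientation = orientation,
      labelMap = labelMap, qcFlags = qcFlags)
}

#' SalienceMap: per-subject ageing salience
#'
#' Non-negative Grad-CAM salience for one subject, either at the raw
#' feature-map resolution or upsampled to the image grid (see
#' [toImageGrid()]). When `normalized`, values were min-max scaled so the
#' maximum is 1 unless the map is identically zero.
#'
#' @slot values non-negative numeric matrix.
#' @slot id subject identifier.
#' @slot age decimal age in years.
#' @slot normalized logical scalar.
#' @export
setClass("SalienceMap",
  representation(values = "matrix", id = "character", age = "numeric",
                 normalized = "logical"),
  validity = function(object) {
    msg <- character()
    if (any(object@values < -1e-12))
      msg <- c(msg, "salience values must be non-negative")
    if (isTRUE(object@normalized) && length(object@values) &&
        max(object@values) > 1 + 1e-9)
      msg <- c(msg, "normalized salience must not exceed 1")
    if (length(msg)) msg else TRUE
  })

#' ArdaMap: per-age average ageing salience
#'
#' Element-wise mean of all normalized salience maps of subjects with
#' the same completed age, together with the number of contributors.
#'
#' @slot values numeric matrix on the image grid.
#' @slot age integer age in completed years.
#' @slot nSubjects number of salience maps averaged.
#' @export
setClass("ArdaMap",
  representation(values = "matrix", age = "integer", nSubjects = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' SignificantRegion: thresholded ageing-significant mask
#'
#' Pixels of an ARDA (or salience) map at or above a percentile
#' threshold of that map's own values.
#'
#' @slot mask logical matrix.
#' @slot level one of `"median"`, `"p75"`, `"p90"`.
#' @slot thresholdValue the percentile value used.
#' @export
setClass("SignificantRegion",
  representation(mask = "matrix", level = "character",
                 thresholdValue = "numeric"),
  validity = function(object) {
    if (!object@level %in% c("median", "p75", "p90"))
      "level must be one of 'median', 'p75', 'p90'" else TRUE
  })

#' PhantomInstanceSpec: one synthetic anatomical instance
#'
#' Geometry and age response of a labeled structure in the phantom.
#' Sizes and centers are in unit image coordinates `(x, y)` with the
#' origin at the top-left. The linear dimensions at age `a` scale by
#' `(1 + changeRateYoung)^(min(a, stageBreak) - 4) *
#'  (1 + changeRateOld)^(max(a - stageBreak, 0))`,
#' a piecewise response with fast change during development and slow
#' change after the stage break.
#'
#' @slot name label string.
#' @slot baseShape `"ellipse"`, `"rectangle"`, `"arc"` or `"tooth-row"`.
#' @slot center numeric `(x, y)` in `[0, 1]`.
#' @slot baseSize numeric `(width, height)` in unit coordinates at age 4.
#' @slot changeRateYoung fractional change of linear size per year below
#'   the stage break.
#' @slot changeRateOld fractional change per year at/after the break.
#' @slot stageBreak age in years separating the two regimes.
#' @slot intensity base gray level in `[0, 1]`.
#' @export
setClass("PhantomInstanceSpec",
  representation(name = "character", baseShape = "character",
                 center = "numeric", baseSize = "numeric",
                 changeRateYoung = "numeric", changeRateOld = "numeric",
                 stageBreak = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@baseShape %in% c("ellipse", "rectangle", "arc", "tooth-row"))
      msg <- c(msg, "unknown baseShape")
    if (!all(is.finite(c(object@changeRateYoung, object@changeRateOld))) ||
        object@changeRateYoung < 0 || object@changeRateOld < 0)
      msg <- c(msg, "change rates must be finite and >= 0")
    if (object@intensity < 0 || object@intensity > 1)
      msg <- c(msg, "intensity must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a PhantomInstanceSpec
#'
#' @param name label string.
#' @param baseShape shape family.
#' @param center `(x, y)` unit coordinates.
#' @param baseSize `(width, height)` unit coordinates at age 4.
#' @param changeRateYoung,changeRateOld fractional linear change per year.
#' @param stageBreak age separating the fast and slow regimes.
#' @param intensity base gray level.
#' @return a [PhantomInstanceSpec-class].
#' @export
phantomInstance <- function(name, baseShape = "ellipse",
                            center = c(0.5, 0.5), baseSize = c(0.2, 0.2),
                            changeRateYoung = 0, changeRateOld = 0,
                            stageBreak = 18, intensity = 0.8) {
  new("PhantomInstanceSpec", name = name, baseShape = baseShape,
      center = as.numeric(center), baseSize = as.numeric(baseSize),
      changeRateYoung = changeRateYoung, changeRateOld = changeRateOld,
      stageBreak = stageBreak, intensity = intensity)
}

#' PhantomCohortConfig: full description of a synthetic cohort
#'
#' Same config + seed always regenerates a bit-identical cohort.
#'
#' @slot nSubjects number of subjects.
#' @slot ageMin,ageMax age range in years (default 4-40).
#' @slot imageSize integer `(H, W)` in pixels.
#' @slot instances list of [PhantomInstanceSpec-class].
#' @slot noiseSd additive truncated-Gaussian noise SD in gray units.
#' @slot seed integer cohort seed.
#' @export
setClass("PhantomCohortConfig",
  representation(nSubjects = "integer", ageMin = "numeric", ageMax = "numeric",
                 imageSize = "integer", instances = "list",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
    if (object@ageMin >= object@ageMax) msg <- c(msg, "ageMin must be < ageMax")
    if (object@ageMin < 0 || object@noiseSd < 0)
      msg <- c(msg, "ages and noiseSd must be non-negative")
    if (!all(vapply(object@instances, is, logical(1), "PhantomInstanceSpec")))
      msg <- c(msg, "instances must all be PhantomInstanceSpec")
    if (length(msg)) msg else TRUE
  })

#' PhantomCohort: generated images plus their manifest
#'
#' @slot images list of [AgedImage-class].
#' @slot manifest data.frame with columns id, age, orientation, split, seed.
#' @slot config the [PhantomCohortConfig-class] that produced it.
#' @export
setClass("PhantomCohort",
  representation(images = "list", manifest = "data.frame",
                 config = "PhantomCohortConfig"))

#' AgeModel: a trained convolutional age regressor
#'
#' Three same-padded 3x3 convolution stages with ReLU, 2x2 max pooling
#' after the first two, global average pooling and a linear head. The
#' last convolutional feature map (before pooling) is the Grad-CAM
#' target layer.
#'
#' @slot backbone backbone spec list (see [tinyCnnBackbone()]).
#' @slot weights named list of parameter arrays.
#' @slot inputChannels 1 for plain images, 2 with a salience channel.
#' @slot config training configuration used.
#' @slot history per-epoch data.frame of train/val loss.
#' @export
setClass("AgeModel",
  representation(backbone = "list", weights = "list",
                 inputChannels = "integer", config = "list",
                 history = "data.frame"))

#' RetestConfig: the two-pass retest inference setup
#'
#' @slot ka age threshold in years; a first-pass prediction strictly
#'   greater than `ka` triggers the constrained second pass.
#' @slot baseline single-channel [AgeModel-class].
#' @slot constrained two-channel [AgeModel-class].
#' @export
setClass("RetestConfig",
  representation(ka = "numeric", baseline = "AgeModel",
                 constrained = "AgeModel"),
  validity = function(object) {
    msg <- character()
    if (object@ka < 4 || object@ka > 40) msg <- c(msg, "ka must be in [4, 40]")
    if (object@baseline@inputChannels != 1L)
      msg <- c(msg, "baseline model must accept 1 channel")
    if (object@constrained@inputChannels != 2L)
      msg <- c(msg, "constrained model must accept 2 channels")
    if (length(msg)) msg else TRUE
  })
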