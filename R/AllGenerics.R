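#' @name accessors
#' @title Accessors for ardaceph data classes
#' @description Slot accessors for the image, salience and ARDA
#'   containers; use these instead of `@`.
#' @param x an ardaceph object.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "AgedImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setMethod("labelMap", "AgedImage", function(x)
  if (length(x@labelMap)) x@labelMap else NULL)

#' @rdname accessors
#' @export
setGeneric("subjectAge", function(x) standardGeneric("subjectAge"))
#' @rdname accessors
#' @export
setMethod("subjectAge", "AgedImage", function(x) x@age)
#' @rdname accessors
#' @export
setMethod("subjectAge", "SalienceMap", function(x) x@age)

#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname accessors
#' @export
setMethod("orientation", "AgedImage", function(x) x@orientation)

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setMethod("qcFlags", "AgedImage", function(x) x@qcFlags)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "SalienceMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("mapValues", "ArdaMap", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "SalienceMap", function(x) x@normalized)

#' @rdname accessors
#' @export
setGeneric("mapAge", function(x) standardGeneric("mapAge"))
#' @rdname accessors
#' @export
setMethod("mapAge", "ArdaMap", function(x) x@age)

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setMethod("nSubjects", "ArdaMap", function(x) x@nSubjects)
#' @rdname accessors
#' @export
setMethod("nSubjects", "PhantomCohort", function(x) nrow(x@manifest))

#' @rdname accessors
#' @export
setGeneric("regionMask", function(x) standardGeneric("regionMask"))
#' @rdname accessors
#' @export
setMethod("regionMask", "SignificantRegion", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))
#' @rdname accessors
#' @export
setMethod("thresholdValue", "SignificantRegion", function(x) x@thresholdValue)

#' @rdname accessors
#' @export
setGeneric("cohortImages", function(x) standardGeneric("cohortImages"))
#' @rdname accessors
#' @export
setMethod("cohortImages", "PhantomCohort", function(x) x@images)

#' @rdname accessors
#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))
#' @rdname accessors
#' @export
setMethod("cohortManifest", "PhantomCohort", function(x) x@manifest)

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setMethod("trainingHistory", "AgeModel", function(x) x@history)

setMethod("show", "AgedImage", function(object) {
  cat(sprintf("AgedImage '%s': %d x %d, age %.2f y, %s%s\n",
              object@id, nrow(object@pixels), ncol(object@pixels),
              object@age, object@orientation,
              if (length(object@labelMap)) ", labeled" else ""))
  if (length(object@qcFlags))
    cat("  qc flags:", paste(object@qcFlags, collapse = ", "), "\n")
})

setMethod("show", "SalienceMap", function(object) {
  cat(sprintf("SalienceMap '%s': %d x %d, age %.2f y, %s\n",
              object@id, nrow(object@values), ncol(object@values),
              object@age,
              if (object@normalized) "normalized" else "raw"))
})

setMethod("show", "ArdaMap", function(object) {
  cat(sprintf("ArdaMap age %d y: %d x %d, %d subject(s), range [%.3f, %.3f]\n",
              object@age, nrow(object@values), ncol(object@values),
              object@nSubjects, min(object@values), max(object@values)))
})

setMethod("show", "SignificantRegion", function(object) {
  cat(sprintf("SignificantRegion (%s >= %.4f): %d of %d pixels\n",
              object@level, object@thresholdValue,
              sum(object@mask), length(object@mask)))
})

setMethod("show", "PhantomCohort", function(object) {
  m <- object@manifest
  cat(sprintf("PhantomCohort: %d subject(s), %d x %d px, ages %.2f-%.2f y\n",
              nrow(m), object@config@imageSize[1], object@config@imageSize[2],
              min(m$age), max(m$age)))
})

setMethod("show", "AgeModel", function(object) {
  cat(sprintf("AgeModel (%s, %d-channel input): %d parameters\n",
              object@backbone$name, object@inputChannels,
              countParameters(object)))
  if (nrow(object@history))
    cat(sprintf("  trained %d epoch(s); final val loss %.3f y\n",
                nrow(object@history),
                object@history$valLoss[nrow(object@history)]))
})
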