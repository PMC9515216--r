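# The three attention-concentrated crops. Coordinates are (x = column,
# rightward; y = row, downward) from the top-left origin; boxes are
# half-open [upper-left, lower-right). The fixed 100-pixel offsets
# assume full-resolution (~2144-wide) frames and scale proportionally
# on small images.

regionOffset <- function(W) {
  if (W < 300) as.integer(round(100 * W / 2144)) else 100L
}

#' Evaluate one attention-concentrated region box
#'
#' For a right-facing image of width `W`, height `H` (offset `o`):
#' teeth `(0, H/2 - o) -> (2W/3 + o, H)`; craniofacial
#' `(0, 0) -> (W, H/2 + o)`; cervical spine
#' `(2W/3 - o, H/2 - o) -> (W, H)`. Fractional coordinates are floored
#' and boxes clipped to the frame. Left-facing boxes are the horizontal
#' mirror (`x -> W - x` with corners swapped); mirroring twice restores
#' the original box.
#'
#' @param name `"teeth"`, `"craniofacial"` or `"cervical_spine"`.
#' @param W,H image width and height in pixels.
#' @param orientation `"right-facing"` (default) or `"left-facing"`.
#' @return named integer vector `(x0, y0, x1, y1)`, half-open.
#' @export
regionBox <- function(name, W, H, orientation = "right-facing") {
  o <- regionOffset(W)
  if (W <= 2 * o || H <= 2 * o)
    stop("image too small for the region offsets")
  thirds <- floor(2 * W / 3)
  half <- floor(H / 2)
  box <- switch(name,
    teeth = c(0L, half - o, min(thirds + o, W), H),
    craniofacial = c(0L, 0L, W, min(half + o, H)),
    cervical_spine = c(max(thirds - o, 0L), half - o, W, H),
    stop("unknown region name: ", name))
  box <- as.integer(c(max(box[1], 0L), max(box[2], 0L),
                      min(box[3], W), min(box[4], H)))
  if (orientation == "left-facing")
    box <- as.integer(c(W - box[3], box[2], W - box[1], box[4]))
  else if (orientation != "right-facing")
    stop("orientation must be 'right-facing' or 'left-facing'")
  setNames(box, c("x0", "y0", "x1", "y1"))
}

#' Select or discard a region of an image
#'
#' `select` crops the image (and label map) to the box; `discard`
#' keeps the full frame with the box zeroed out, so the network input
#' geometry is unchanged across discard conditions.
#'
#' @param image an [AgedImage-class].
#' @param box half-open `(x0, y0, x1, y1)` from [regionBox()].
#' @param mode `"select"` or `"discard"`.
#' @return the modified [AgedImage-class].
#' @export
applyRegion <- function(image, box, mode = c("select", "discard")) {
  mode <- match.arg(mode)
  px <- pixels(image); lm <- labelMap(image)
  H <- nrow(px); W <- ncol(px)
  if (box["x1"] <= box["x0"] || box["y1"] <= box["y0"])
    stop("empty region box")
  if (box["x0"] < 0 || box["y0"] < 0 || box["x1"] > W || box["y1"] > H)
    stop("region box outside the image")
  rows <- (box["y0"] + 1):box["y1"]
  cols <- (box["x0"] + 1):box["x1"]
  if (mode == "select") {
    px <- px[rows, cols, drop = FALSE]
    if (!is.null(lm)) lm <- lm[rows, cols, drop = FALSE]
  } else {
    px[rows, cols] <- 0
    if (!is.null(lm)) lm[rows, cols] <- 0L
  }
  AgedImage(px, age = image@age, id = image@id,
            orientation = image@orientation, labelMap = lm,
            qcFlags = image@qcFlags)
}

# Apply one (region, mode) condition to every image of a cohort.
applyRegionCohort <- function(cohort, region, mode) {
  images <- lapply(cohortImages(cohort), function(im) {
    d <- dim(pixels(im))
    applyRegion(im, regionBox(region, W = d[2], H = d[1],
                              orientation = im@orientation), mode)
  })
  # selection changes the frame size; re-pad to a square network input
  if (mode == "select") {
    side <- max(vapply(images, function(im) max(dim(pixels(im))),
                       integer(1)))
    side <- as.integer(ceiling(side / 4) * 4)
    images <- lapply(images, function(im) {
      px <- resizeBilinear(padSquare(pixels(im)), c(side, side))
      AgedImage(px, age = im@age, id = im@id, orientation = im@orientation)
    })
  }
  new("PhantomCohort", images = images, manifest = cohortManifest(cohort),
      config = cohort@config)
}

#' Region select/discard experiment
#'
#' Trains and evaluates one model per condition -- each listed region
#' selected (cropped to) or discarded (zeroed) -- plus the full-image
#' baseline, all on identical splits, and returns the overall metric
#' rows side by side.
#'
#' @param cohort a split [PhantomCohort-class].
#' @param conditions list of `list(region =, mode =)` entries.
#' @param config training config (see [trainAgeModel()]).
#' @return data.frame of overall metrics, one row per condition plus
#'   `baseline`.
#' @export
regionExperiment <- function(cohort, conditions, config = list()) {
  known <- c("teeth", "craniofacial", "cervical_spine")
  for (cd in conditions)
    if (!cd$region %in% known)
      stop("unknown region in condition: ", cd$region)
  evalOne <- function(coh, label) {
    model <- trainAgeModel(coh, config = config)
    mt <- evaluatePredictions(predictionSet(model, coh))
    row <- mt[mt$group == "All", , drop = FALSE]
    row$condition <- label
    row
  }
  rows <- list(evalOne(cohort, "baseline"))
  for (cd in conditions) {
    coh <- applyRegionCohort(cohort, cd$region, cd$mode)
    rows[[length(rows) + 1]] <-
      evalOne(coh, paste(cd$mode, cd$region, sep = ":"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("condition", setdiff(names(out), "condition"))]
}
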