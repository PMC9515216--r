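test_that("region boxes evaluate the documented corner formulas", {
  W <- 2144L; H <- 2304L
  teeth <- regionBox("teeth", W, H)
  expect_equal(unname(teeth), c(0L, 1052L, 1529L, 2304L))
  cran <- regionBox("craniofacial", W, H)
  expect_equal(unname(cran[1:2]), c(0L, 0L))
  expect_equal(unname(cran[3:4]), c(2144L, 1252L))
  cs <- regionBox("cervical_spine", W, H)
  expect_equal(unname(cs[1:2]), c(1329L, 1052L))
  expect_equal(unname(cs[3:4]), c(2144L, 2304L))
  expect_error(regionBox("jaw", W, H), "unknown region")
  expect_error(regionBox("teeth", 320L, 150L), "too small")
})

test_that("left-facing boxes mirror and mirroring is an involution", {
  W <- 2144L; H <- 2304L
  for (nm in c("teeth", "craniofacial", "cervical_spine")) {
    r <- regionBox(nm, W, H, "right-facing")
    l <- regionBox(nm, W, H, "left-facing")
    expect_equal(unname(c(l["x0"], l["x1"])),
                 unname(c(W - r["x1"], W - r["x0"])))
    expect_equal(unname(c(l["y0"], l["y1"])),
                 unname(c(r["y0"], r["y1"])))
    # mirroring the mirrored corners restores the original box
    back <- c(W - l["x1"], l["y0"], W - l["x0"], l["y1"])
    expect_equal(unname(back), unname(r))
  }
})

test_that("offsets scale proportionally on small frames", {
  b <- regionBox("teeth", 64L, 64L)
  off <- as.integer(round(100 * 64 / 2144))
  expect_equal(unname(b), c(0L, 32L - off, min(floor(2 * 64 / 3) + off, 64L),
                            64L))
})

test_that("the three regions jointly cover the frame", {
  W <- 640L; H <- 600L
  cov <- matrix(FALSE, H, W)
  for (nm in c("teeth", "craniofacial", "cervical_spine")) {
    b <- regionBox(nm, W, H)
    cov[(b["y0"] + 1):b["y1"], (b["x0"] + 1):b["x1"]] <- TRUE
  }
  expect_true(all(cov))
})

test_that("select and discard partition the image's pixel mass", {
  co <- smallCohort(n = 4L)
  im <- cohortImages(co)[[2]]
  b <- regionBox("teeth", ncol(pixels(im)), nrow(pixels(im)))
  selected <- applyRegion(im, b, "select")
  discarded <- applyRegion(im, b, "discard")
  expect_equal(sum(pixels(selected)) + sum(pixels(discarded)),
               sum(pixels(im)))
  # select pixel count equals the box area
  expect_equal(length(pixels(selected)),
               (b["x1"] - b["x0"]) * (b["y1"] - b["y0"]),
               ignore_attr = TRUE)
  # discard zeroes the box but keeps the frame
  expect_identical(dim(pixels(discarded)), dim(pixels(im)))
  expect_equal(sum(pixels(discarded)[(b["y0"] + 1):b["y1"],
                                     (b["x0"] + 1):b["x1"]]), 0)
  # a whole-frame box selects the identity
  whole <- c(x0 = 0L, y0 = 0L, x1 = ncol(pixels(im)),
             y1 = nrow(pixels(im)))
  expect_identical(pixels(applyRegion(im, whole, "select")), pixels(im))
  expect_error(applyRegion(im, c(x0 = 5L, y0 = 5L, x1 = 5L, y1 = 9L)),
               "empty")
})

test_that("region experiments rank an informative region above its loss", {
  # all age signal sits in the teeth box: discarding it must hurt more
  # than selecting it
  inst <- list(phantomInstance("tooth_row", "tooth-row",
                               center = c(0.35, 0.78),
                               baseSize = c(0.26, 0.09),
                               changeRateYoung = 0.05,
                               changeRateOld = 0.01, stageBreak = 18,
                               intensity = 0.9))
  cfg <- phantomCohortConfig(nSubjects = 160L, imageSize = c(32L, 32L),
                             instances = inst, noiseSd = 0, seed = 77L)
  co <- splitCohort(generateCohort(cfg), seed = 78L)
  res <- regionExperiment(co,
                          list(list(region = "teeth", mode = "select"),
                               list(region = "teeth", mode = "discard")),
                          config = list(epochs = 8L, batchSize = 16L,
                                        seed = 3L))
  expect_equal(nrow(res), 3L)
  maeOf <- function(lbl) res$MAE[res$condition == lbl]
  expect_lt(maeOf("select:teeth"), maeOf("discard:teeth"))
  expect_error(regionExperiment(co, list(list(region = "nose",
                                              mode = "select"))),
               "unknown region")
})
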