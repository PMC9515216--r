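test_that("decimal age divides day counts by 365.25", {
  d0 <- as.Date("2010-03-15")
  expect_equal(decimalAge(d0, d0), 0)
  # an interval constructed to be exactly 20 * 365.25 days
  expect_equal(decimalAge(d0, d0 + 20 * 365.25), 20)
  expect_equal(decimalAge(d0, d0 + 10000), round(10000 / 365.25, 2))
  expect_error(decimalAge(d0, d0 - 1), "precedes")
})

test_that("decimal age is monotone in the imaging date", {
  d0 <- as.Date("2000-06-01")
  ages <- decimalAge(d0, d0 + seq(0, 12000, by = 500))
  expect_true(all(diff(ages) >= 0))
})

test_that("screening flags age range and passes annotations through", {
  im <- AgedImage(matrix(0.5, 8, 8), age = 3.5)
  expect_true("age_out_of_range" %in% qcFlags(screenImage(im)))
  im2 <- AgedImage(matrix(0.5, 8, 8), age = 20)
  expect_length(qcFlags(screenImage(im2)), 0L)
  expect_setequal(qcFlags(screenImage(im2, c("posture", "restoration"))),
                  c("posture", "restoration"))
  expect_error(screenImage(im2, "blurry"), "unknown annotation")
  expect_error(screenImage(AgedImage(matrix(0.5, 4, 4), age = NA)),
               "missing")
})

test_that("screening filters the expected number of cohort members", {
  ages <- c(rep(20, 95), rep(2, 3), rep(45, 2))
  flagged <- vapply(ages, function(a)
    length(qcFlags(screenImage(AgedImage(matrix(0.1, 4, 4), age = a)))) > 0,
    logical(1))
  expect_equal(sum(!flagged), 95L)
})

test_that("preprocessing pads to square, resizes and preserves labels", {
  lm <- matrix(0L, 100, 200)
  lm[40:60, 80:120] <- 1L
  lm[10:20, 10:30] <- 2L
  px <- matrix(runif(100 * 200), 100, 200)
  im <- AgedImage(px, age = 12, labelMap = lm)
  out <- preprocessImage(im, targetSize = c(224L, 224L))
  expect_identical(dim(pixels(out)), c(224L, 224L))
  expect_identical(dim(labelMap(out)), c(224L, 224L))
  expect_true(all(pixels(out) >= 0 & pixels(out) <= 1))
  # the same label set survives nearest-neighbor resizing
  expect_setequal(unique(as.vector(labelMap(out))),
                  unique(as.vector(lm)))
})

test_that("a flat image stays flat through preprocessing", {
  im <- AgedImage(matrix(0.4, 64, 64), age = 10)
  out <- pixels(preprocessImage(im, targetSize = c(64L, 64L)))
  expect_lt(diff(range(out)), 1e-6)
})

test_that("preprocessing rejects degenerate input", {
  expect_error(preprocessImage(AgedImage(matrix(numeric(0), 0, 0), age = 5)),
               "matrix")
})

test_that("augmentation is seeded, and flipping twice restores the image", {
  co <- smallCohort(n = 4L)
  im <- cohortImages(co)[[1]]
  a <- augmentImage(im, seed = 10L)
  b <- augmentImage(im, seed = 10L)
  expect_identical(pixels(a), pixels(b))
  # zero-amplitude affine and no flip is the identity
  idd <- augmentImage(im, seed = 1L, rotation = 0, translation = 0,
                      scaleRange = c(1, 1), flipProb = 0)
  expect_identical(pixels(idd), pixels(im))
  # flip with probability 1 is an involution and toggles orientation
  f1 <- augmentImage(im, seed = 2L, rotation = 0, translation = 0,
                     scaleRange = c(1, 1), flipProb = 1)
  expect_identical(orientation(f1), "left-facing")
  f2 <- augmentImage(f1, seed = 3L, rotation = 0, translation = 0,
                     scaleRange = c(1, 1), flipProb = 1)
  expect_identical(pixels(f2), pixels(im))
  expect_identical(orientation(f2), orientation(im))
})

test_that("stratified splits are exact, disjoint and reproducible", {
  manifest <- data.frame(id = sprintf("s%03d", 1:100),
                         age = rep(seq(4.5, 10, length.out = 10), 10))
  sp <- suppressWarnings(stratifiedSplit(manifest, c(0.70, 0.15, 0.15), seed = 3L))
  expect_equal(as.vector(table(sp$split)[c("train", "val", "test")]),
               c(70L, 15L, 15L))
  expect_false(any(is.na(sp$split)))
  expect_identical(sp, suppressWarnings(
    stratifiedSplit(manifest, c(0.70, 0.15, 0.15), seed = 3L)))
  all_train <- suppressWarnings(stratifiedSplit(manifest, c(1, 0, 0), seed = 1L))
  expect_true(all(all_train$split == "train"))
})

test_that("split manifests cover every subject across mixed age groups", {
  m <- cohortManifest(smallCohort(n = 80L))
  expect_false(any(is.na(m$split)))
  expect_setequal(unique(m$split), c("train", "val", "test"))
})
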