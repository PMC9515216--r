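test_that("per-age aggregation is the element-wise mean", {
  # a single subject's map is returned unchanged
  one <- randomNormalizedMaps(1, ages = 20.4)
  A <- buildArda(one)
  expect_equal(mapValues(A[["20"]]), mapValues(one[[1]]))
  expect_equal(nSubjects(A[["20"]]), 1L)
  # averaging identical maps is idempotent
  twin <- c(one, one)
  expect_equal(mapValues(buildArda(twin)[["20"]]), mapValues(one[[1]]))
  # 50 random maps against an accumulate-and-divide loop oracle
  maps <- randomNormalizedMaps(50, ages = rep(c(12.1, 12.9, 30.5), 17)[1:50])
  A <- buildArda(maps)
  for (a in names(A)) {
    sel <- which(floor(vapply(maps, subjectAge, numeric(1))) ==
                   as.integer(a))
    acc <- matrix(0, 12, 12)
    for (i in sel) acc <- acc + mapValues(maps[[i]])
    expect_equal(mapValues(A[[a]]), acc / length(sel), tolerance = 1e-12)
    expect_equal(nSubjects(A[[a]]), length(sel))
  }
})

test_that("aggregation rejects mixed grids and unnormalized maps", {
  m1 <- randomNormalizedMaps(1, size = 8L, ages = 10)
  m2 <- randomNormalizedMaps(1, size = 12L, seed = 2L, ages = 10)
  expect_error(buildArda(c(m1, m2)), "mixed grids")
  raw <- m1
  raw[[1]]@normalized <- FALSE
  expect_error(buildArda(raw), "normalized")
})

test_that("the ARDA map lies within the envelope of its inputs", {
  maps <- randomNormalizedMaps(20, ages = rep(15.5, 20))
  A <- mapValues(buildArda(maps)[["15"]])
  lo <- Reduce(pmin, lapply(maps, mapValues))
  hi <- Reduce(pmax, lapply(maps, mapValues))
  expect_true(all(A >= lo - 1e-12 & A <= hi + 1e-12))
})

test_that("threshold masks use interpolated percentiles with >= ties", {
  vals <- matrix(sample(1:100), 10, 10)
  A <- new("ArdaMap", values = vals / 100, age = 20L, nSubjects = 1L)
  r90 <- significantRegion(A, "p90")
  expect_equal(sum(regionMask(r90)), 10L)  # sort-and-count: top 10 of 100
  expect_equal(thresholdValue(r90),
               unname(quantile(vals / 100, 0.9)))
  # constant map: threshold equals the constant, everything significant
  C <- new("ArdaMap", values = matrix(0.5, 6, 6), age = 10L,
           nSubjects = 1L)
  expect_true(all(regionMask(significantRegion(C, "median"))))
  # two-valued half/half map at the median keeps the high half (with ties)
  tv <- new("ArdaMap", values = matrix(rep(c(0.2, 0.8), each = 18), 6, 6),
            age = 10L, nSubjects = 1L)
  expect_equal(sum(regionMask(significantRegion(tv, "median"))), 18L)
  expect_error(significantRegion(A, "p95"))
})

test_that("threshold masks are nested across levels", {
  maps <- randomNormalizedMaps(100, size = 9L,
                               ages = withSeed(30L, runif(100, 4, 40)))
  for (m in maps) {
    md <- regionMask(significantRegion(m, "median"))
    p75 <- regionMask(significantRegion(m, "p75"))
    p90 <- regionMask(significantRegion(m, "p90"))
    expect_true(all(p90 <= p75))
    expect_true(all(p75 <= md))
  }
})

test_that("instance quantification averages map values inside the mask", {
  v <- matrix(0.4, 8, 8)
  A <- new("ArdaMap", values = v, age = 12L, nSubjects = 2L)
  labels <- matrix(0L, 8, 8)
  labels[2:4, 2:4] <- 1L   # inside the all-true region
  labels[6:8, 6:8] <- 2L
  reg <- significantRegion(A, "median")
  q <- quantifyInstances(A, reg, labels, c("a", "b"))
  expect_equal(q$value[q$instance == "a"], 0.4)
  # an instance disjoint from the region is missing, never zero
  v2 <- v; v2[1, ] <- 1  # the p90 region becomes the top row only
  A2 <- new("ArdaMap", values = v2, age = 12L, nSubjects = 2L)
  q2 <- quantifyInstances(A2, significantRegion(A2, "p90"), labels,
                          c("a", "b"))
  expect_true(all(is.na(q2$value)))
  expect_true(all(q2$nPixels == 0))
  # random map and masks against a per-pixel loop oracle
  vr <- withSeed(31L, matrix(runif(64), 8, 8))
  Ar <- new("ArdaMap", values = vr, age = 12L, nSubjects = 1L)
  regr <- significantRegion(Ar, "p75")
  qr <- quantifyInstances(Ar, regr, labels, c("a", "b"))
  for (k in 1:2) {
    acc <- c(); mask <- regionMask(regr)
    for (i in 1:8) for (j in 1:8)
      if (labels[i, j] == k && mask[i, j]) acc <- c(acc, vr[i, j])
    expect_equal(qr$value[k], mean(acc))
  }
  expect_error(quantifyInstances(A, reg, matrix(0L, 4, 4)), "align")
})

test_that("quantification is invariant to relabeling and subject order", {
  maps <- randomNormalizedMaps(12, ages = rep(18.2, 12))
  labels <- matrix(0L, 12, 12); labels[3:6, 3:6] <- 1L
  labels2 <- labels * 5L  # same geometry, different id
  A1 <- buildArda(maps)[["18"]]
  A2 <- buildArda(rev(maps))[["18"]]
  r1 <- significantRegion(A1, "p75"); r2 <- significantRegion(A2, "p75")
  q1 <- quantifyInstances(A1, r1, labels)
  q2 <- quantifyInstances(A2, r2, labels2)
  expect_equal(q1$value, q2$value)
})

test_that("the surface table is tidy, complete and ordered", {
  maps <- randomNormalizedMaps(10, ages = rep(c(8.5, 22.3), 5))
  A <- buildArda(maps)
  labels <- matrix(0L, 12, 12)
  labels[2:5, 2:5] <- 1L; labels[7:10, 2:5] <- 2L; labels[2:5, 7:10] <- 3L
  surf <- ardaSurface(A, labels, c("i1", "i2", "i3"))
  expect_equal(nrow(surf), 2 * 3 * 3)  # 2 ages x 3 instances x 3 levels
  expect_identical(levels(surf$level), c("median", "p75", "p90"))
  expect_true(!is.unsorted(surf$age))
})

test_that("the normal band reproduces the worked example and edge cases", {
  b <- normalBand(0.089, 0.015, 2)
  expect_equal(b$low, 0.059)
  expect_equal(b$high, 0.119)
  expect_equal(b$coveragePct, 95.45)
  expect_equal(normalBand(0, 1, 1)$coveragePct, 68.27)
  d <- normalBand(0.5, 0, 2)
  expect_equal(d$low, 0.5)
  expect_equal(d$high, 0.5)
  expect_error(normalBand(0.1, -0.01), ">= 0")
})

test_that("per-subject instance statistics have non-negative spread", {
  co <- smallCohort(n = 120L)
  model <- smallModel()
  m <- cohortManifest(co)
  idx <- which(m$split == "test")
  maps <- cohortSalience(model, co, which = idx)
  labels <- labelMap(cohortImages(co)[[1]])
  st <- instanceStats(maps, function(a)
    labelMap(renderSubject(co@config, a, 0L)),
    instanceNames = c("tooth_row", "cranium", "block"))
  expect_true(all(st$sigma[!is.na(st$sigma)] >= 0))
  expect_true(all(st$n >= 1))
})

test_that("rendering maps zero to blue, one to red, and respects alpha", {
  v <- matrix(c(0, 1, 0.5, 0.25), 2, 2)
  A <- new("ArdaMap", values = v, age = 10L, nSubjects = 1L)
  rgbArr <- renderArda(A, base = NULL, alpha = 1)
  expect_equal(rgbArr[1, 1, ], c(0, 0, 1))  # salience 0 -> blue
  expect_equal(rgbArr[2, 1, ], c(1, 0, 0))  # salience 1 -> red
  base <- AgedImage(matrix(0.5, 2, 2), age = 10)
  blended0 <- renderArda(A, base, alpha = 0)
  for (ch in 1:3) expect_equal(blended0[, , ch], pixels(base))
  zero <- new("ArdaMap", values = matrix(0, 2, 2), age = 10L,
              nSubjects = 1L)
  tint <- renderArda(zero, base, alpha = 0.5)
  expect_true(all(tint[, , 3] > tint[, , 1]))  # pure blue tint
  expect_error(renderArda(A, AgedImage(matrix(0.5, 3, 3), age = 10)),
               "grid")
})
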