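test_that("a static phantom renders identically at any age", {
  inst <- list(phantomInstance("still", "ellipse", center = c(0.5, 0.5),
                               baseSize = c(0.3, 0.2)))
  cfg <- phantomCohortConfig(nSubjects = 1L, imageSize = c(48L, 48L),
                             instances = inst, noiseSd = 0, seed = 1L)
  a <- renderSubject(cfg, 5, 1L)
  b <- renderSubject(cfg, 35, 1L)
  expect_identical(pixels(a), pixels(b))
  expect_identical(labelMap(a), labelMap(b))
})

test_that("rendering is a pure function of (config, age, seed)", {
  cfg <- phantomCohortConfig(nSubjects = 1L, imageSize = c(48L, 48L),
                             noiseSd = 0.05, seed = 3L)
  a <- renderSubject(cfg, 17.25, 99L)
  b <- renderSubject(cfg, 17.25, 99L)
  expect_identical(pixels(a), pixels(b))
  d <- renderSubject(cfg, 17.25, 100L)
  expect_false(identical(pixels(a), pixels(d)))
  expect_error(renderSubject(cfg, 41, 1L), "outside")
})

test_that("rendered area follows the closed-form growth factor", {
  inst <- list(phantomInstance("grow", "ellipse", center = c(0.5, 0.5),
                               baseSize = c(0.25, 0.18),
                               changeRateYoung = 0.05, stageBreak = 18))
  cfg <- phantomCohortConfig(nSubjects = 1L, imageSize = c(256L, 256L),
                             instances = inst, noiseSd = 0, seed = 1L)
  n10 <- sum(labelMap(renderSubject(cfg, 10, 1L)) == 1L)
  n6 <- sum(labelMap(renderSubject(cfg, 6, 1L)) == 1L)
  # linear sizes scale by 1.05 per year below the break, area by its square
  expect_equal(n10 / n6, 1.05^(2 * (10 - 6)), tolerance = 0.02)
})

test_that("instance pixel counts are non-decreasing in age without noise", {
  cfg <- phantomCohortConfig(nSubjects = 1L, imageSize = c(96L, 96L),
                             noiseSd = 0, seed = 1L)
  ages <- seq(4, 40, by = 3)
  for (k in 1:2) {  # the two changing instances
    counts <- vapply(ages, function(a)
      sum(labelMap(renderSubject(cfg, a, 1L)) == k), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("label maps only carry configured instance ids", {
  cfg <- phantomCohortConfig(nSubjects = 1L, imageSize = c(64L, 64L),
                             noiseSd = 0, seed = 1L)
  lm <- labelMap(renderSubject(cfg, 30, 1L))
  expect_true(all(unique(as.vector(lm)) %in%
                    0:length(cfg@instances)))
  expect_setequal(setdiff(unique(as.vector(lm)), 0L), 1:3)
})

test_that("cohort generation is deterministic and respects the age range", {
  cfg <- phantomCohortConfig(nSubjects = 1L, imageSize = c(32L, 32L),
                             seed = 5L)
  one <- generateCohort(cfg)
  expect_equal(nrow(cohortManifest(one)), 1L)
  expect_true(cohortManifest(one)$age >= 4 && cohortManifest(one)$age <= 40)

  cfg2 <- phantomCohortConfig(nSubjects = 200L, imageSize = c(16L, 16L),
                              seed = 11L)
  a <- generateCohort(cfg2)
  b <- generateCohort(cfg2)
  expect_identical(cohortManifest(a), cohortManifest(b))
  expect_identical(lapply(cohortImages(a), pixels),
                   lapply(cohortImages(b), pixels))
})

test_that("sampled ages are uniform over the range", {
  cfg <- phantomCohortConfig(nSubjects = 2000L, imageSize = c(16L, 16L),
                             seed = 29L)
  ages <- cohortManifest(generateCohort(cfg))$age
  counts <- table(factor(floor(ages), levels = 4:39))
  p <- suppressWarnings(chisq.test(as.vector(counts))$p.value)
  expect_gt(p, 0.001)
})

test_that("written cohorts round-trip through PNG within 8-bit precision", {
  cfg <- phantomCohortConfig(nSubjects = 3L, imageSize = c(32L, 32L),
                             noiseSd = 0, seed = 2L)
  co <- generateCohort(cfg)
  dir <- file.path(tempfile("cohort"), "out")
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_identical(cohortManifest(back)$id, cohortManifest(co)$id)
  expect_lt(max(abs(pixels(cohortImages(back)[[1]]) -
                      pixels(cohortImages(co)[[1]]))), 1 / 254)
  expect_identical(labelMap(cohortImages(back)[[2]]),
                   labelMap(cohortImages(co)[[2]]))
  expect_error(writeCohort(co, file.path(dir, "manifest.csv", "x")))
})
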