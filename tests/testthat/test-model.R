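test_that("L1 loss matches hand sums and an elementwise oracle", {
  expect_equal(l1Loss(c(10, 20), c(10, 20)), 0)
  expect_equal(l1Loss(c(10, 20), c(12, 26)), 4)
  p <- withSeed(1L, runif(100, 4, 40))
  y <- withSeed(2L, runif(100, 4, 40))
  acc <- 0
  for (i in 1:100) acc <- acc + abs(p[i] - y[i])
  expect_equal(l1Loss(p, y), acc / 100, tolerance = 1e-12)
  expect_error(l1Loss(numeric(0), numeric(0)), "non-empty")
})

test_that("convolution matches a per-pixel loop oracle", {
  x <- withSeed(3L, array(rnorm(6 * 7 * 2 * 2), c(6, 7, 2, 2)))
  w <- withSeed(4L, array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3)))
  b <- c(0.1, -0.2, 0.3)
  out <- ardaceph:::cpp_conv2d_fwd(x, w, b)
  ref <- array(0, c(6, 7, 3, 2))
  for (n in 1:2) for (k in 1:3) for (i in 1:6) for (j in 1:7) {
    acc <- b[k]
    for (c in 1:2) for (dh in -1:1) for (dw in -1:1) {
      ii <- i + dh; jj <- j + dw
      if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 7)
        acc <- acc + x[ii, jj, c, n] * w[dh + 2, dw + 2, c, k]
    }
    ref[i, j, k, n] <- acc
  }
  expect_equal(out, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("convolution gradients agree with finite differences", {
  x <- withSeed(5L, array(rnorm(5 * 5 * 2 * 1), c(5, 5, 2, 1)))
  w <- withSeed(6L, array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2)))
  b <- c(0, 0)
  dout <- withSeed(7L, array(rnorm(5 * 5 * 2 * 1), c(5, 5, 2, 1)))
  g <- ardaceph:::cpp_conv2d_bwd(x, w, dout)
  lossOf <- function(xx, ww)
    sum(ardaceph:::cpp_conv2d_fwd(xx, ww, b) * dout)
  eps <- 1e-6
  for (idx in c(1, 7, 20, 36)) {  # spot-check weight gradients
    wp <- w; wm <- w
    wp[idx] <- wp[idx] + eps; wm[idx] <- wm[idx] - eps
    expect_equal(g$dw[idx], (lossOf(x, wp) - lossOf(x, wm)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (idx in c(2, 13, 30)) {  # spot-check input gradients
    xp <- x; xm <- x
    xp[idx] <- xp[idx] + eps; xm[idx] <- xm[idx] - eps
    expect_equal(g$dx[idx], (lossOf(xp, w) - lossOf(xm, w)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("max pooling selects maxima and routes gradients to them", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  p <- ardaceph:::cpp_maxpool2_fwd(x)
  expect_equal(as.vector(p$out), c(6, 8, 14, 16))
  dx <- ardaceph:::cpp_maxpool2_bwd(p$arg, array(1, c(2, 2, 1, 1)),
                                    dim(x))
  expect_equal(sum(dx), 4)
  expect_equal(dx[2, 2, 1, 1], 1)  # x[2,2] = 6 is a block maximum
})

test_that("training logs history, checkpoints and is seed-deterministic", {
  co <- smallCohort(n = 24L, size = 16L)
  cfg <- list(epochs = 2L, batchSize = 8L, seed = 9L)
  m1 <- trainAgeModel(co, config = cfg)
  expect_equal(nrow(trainingHistory(m1)), 2L)
  expect_true(all(is.finite(trainingHistory(m1)$trainLoss)))
  m2 <- trainAgeModel(co, config = cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@weights, m2@weights)
  path <- tempfile(fileext = ".rds")
  saveModel(m1, path)
  m3 <- loadModel(path)
  expect_identical(m3@weights, m1@weights)
  expect_equal(predictAges(m3, cohortImages(co)[1:3]),
               predictAges(m1, cohortImages(co)[1:3]))
})

test_that("parameter counts match layer-by-layer hand arithmetic", {
  # single 3x3 conv, 1 -> 8 channels, with bias
  expect_equal(9 * 1 * 8 + 8, 80)
  bb <- tinyCnnBackbone(inputSize = c(64L, 64L), channels = c(8L, 16L, 16L))
  hand <- (9 * 1 * 8 + 8) + (9 * 8 * 16 + 16) + (9 * 16 * 16 + 16) +
    (16 + 1)
  expect_equal(countParameters(bb), hand)
  co <- smallCohort(n = 24L, size = 16L)
  m <- trainAgeModel(co, config = list(epochs = 1L, batchSize = 8L,
                                       seed = 1L))
  expect_equal(countParameters(m), countParameters(m@backbone))
})

test_that("the EfficientNet-B0 stage plan has the documented shape", {
  plan <- effnetB0Plan()$stagePlan
  expect_equal(nrow(plan), 9L)
  expect_equal(plan$resolution[1], "224x224")
  expect_equal(plan$channels[9], 1280L)
  expect_equal(plan$resolution[9], "7x7")
  expect_equal(round(countParameters(effnetB0Plan()) / 1e6), 5)
})

test_that("backbone constraints are enforced", {
  expect_error(tinyCnnBackbone(inputSize = c(30L, 30L)), "divisible")
  expect_error(tinyCnnBackbone(inputSize = c(8L, 8L)), "4x4")
})
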