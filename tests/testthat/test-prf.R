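test_that("double-gamma HRF has canonical shape", {
  h <- hrfDoubleGamma(dt = 0.1)
  expect_equal(max(h), 1)
  # positive lobe of the canonical kernel peaks near 5 s
  expect_true(abs((which.max(h) - 1) * 0.1 - 5) <= 0.5)
  # undershoot vanishes as the ratio grows
  h2 <- hrfDoubleGamma(list(peakDelay = 6, underDelay = 16, peakDisp = 1,
                            underDisp = 1, ratio = 1e9), dt = 0.1)
  expect_true(all(h2 >= -1e-12))
  expect_error(hrfDoubleGamma(list(peakDelay = -1, underDelay = 16,
                                   peakDisp = 1, underDisp = 1, ratio = 6)),
               "positive")
})

test_that("cartesian-to-polar follows the field convention", {
  expect_equal(cartesianToPolar(4.5, 0), list(angle = 0, ecc = 4.5))
  expect_equal(cartesianToPolar(0, 4.5), list(angle = 90, ecc = 4.5))
  p <- cartesianToPolar(-3, -3)
  expect_equal(p$angle, 225)
  expect_equal(p$ecc, 3 * sqrt(2))
  expect_equal(cartesianToPolar(0, 0), list(angle = 0, ecc = 0))
})

test_that("forward prediction sums Gaussian-aperture overlap then convolves", {
  pred <- predictTimecourse(list(x = 3, y = 0, sigma = 1), ap64, hrf1)
  expect_length(pred, 192)
  # independent brute-force oracle: explicit per-frame pixel loop
  px <- cortmag:::pixelCoords(64, 12.4)
  g <- exp(-((px$x - 3)^2 + (px$y - 0)^2) / 2)
  neural <- vapply(seq_len(192),
                   function(f) sum(ap64@frames[f, ] * g) * ap64@degPerPix^2,
                   numeric(1))
  hpad <- c(hrf1, rep(0, 192))
  manual <- vapply(seq_len(192), function(t)
    sum(neural[t:1] * hpad[seq_len(t)]), numeric(1))
  expect_equal(pred, manual, tolerance = 1e-10)
  # a pRF far outside the aperture predicts nothing
  far <- predictTimecourse(list(x = 40, y = 0, sigma = 1), ap64, hrf1)
  expect_true(max(abs(far)) < 1e-8)
})

test_that("prediction is linear in the aperture", {
  px <- cortmag:::pixelCoords(64, 12.4)
  left <- px$x < 0
  a1 <- ap64; a1@frames[, !left] <- 0
  a2 <- ap64; a2@frames[, left] <- 0
  prf <- list(x = 1, y = 2, sigma = 1.5)
  expect_equal(predictTimecourse(prf, a1, hrf1) +
                 predictTimecourse(prf, a2, hrf1),
               predictTimecourse(prf, ap64, hrf1), tolerance = 1e-12)
})

test_that("coarse-to-fine fit recovers noiseless pRFs and gates inclusion", {
  set.seed(42)
  n <- 12
  truth <- data.frame(x = runif(n, -7, 7), y = runif(n, -7, 7),
                      sigma = runif(n, 0.5, 3))
  series <- vapply(seq_len(n), function(i)
    predictTimecourse(truth[i, ], ap64, hrf1), numeric(192))
  fit <- fitPRF(series, ap64, hrf1)
  err <- pmax(abs(fit@x - truth$x), abs(fit@y - truth$y),
              abs(fit@sigma - truth$sigma))
  expect_true(all(err <= 0.1))
  # self-fit explains everything
  expect_true(all(fit@r2 > 1 - 1e-6))
  expect_true(all(inclusionFlags(fit)))
  # R^2 invariant to affine rescaling of the series
  fit2 <- fitPRF(2 * series[, 1] + 5, ap64, hrf1)
  expect_equal(fit2@r2, fit@r2[1], tolerance = 1e-6)
  # flat series is excluded with R^2 = 0
  flat <- fitPRF(rep(1, 192), ap64, hrf1, refine = FALSE)
  expect_equal(flat@r2, 0)
  expect_false(inclusionFlags(flat))
})

test_that("noise lowers variance explained and white noise is excluded", {
  mesh <- meshSubset(isoLeft, which(eccentricities(isoLeft) > 0.5 &
                                      eccentricities(isoLeft) < 11)[1:15])
  clean <- simulateBold(mesh, ap64, hrf1, noiseSd = 0, seed = 7)
  pred <- vapply(seq_len(nVertices(mesh)), function(v) {
    ang <- polarAngles(mesh)[v]; ecc <- eccentricities(mesh)[v]
    predictTimecourse(list(x = ecc * cospi(ang / 180),
                           y = ecc * sinpi(ang / 180),
                           sigma = sigmaFromEccentricity(ecc)), ap64, hrf1)
  }, numeric(192))
  # zero-noise simulation equals the forward prediction exactly
  expect_equal(clean, pred, tolerance = 1e-12,
               ignore_attr = TRUE)
  noisy <- simulateBold(mesh, ap64, hrf1,
                        noiseSd = 0.5 * stats::sd(clean), seed = 7)
  fitClean <- fitPRF(clean, ap64, hrf1, refine = FALSE)
  fitNoisy <- fitPRF(noisy, ap64, hrf1, refine = FALSE)
  expect_lt(median(fitNoisy@r2), median(fitClean@r2))
  # pure white noise rarely passes the 10% gate
  set.seed(11)
  wn <- matrix(rnorm(192 * 30), 192)
  fitWN <- fitPRF(wn, ap64, hrf1)
  expect_gte(mean(!inclusionFlags(fitWN)), 0.95)
})

test_that("BOLD simulation validates inputs and is seed-reproducible", {
  mesh <- meshSubset(isoLeft, 1:8)
  expect_error(simulateBold(mesh, ap64, sigmaMap = -1), "positive")
  b1 <- simulateBold(mesh, ap64, noiseSd = 0.3, seed = 5)
  b2 <- simulateBold(mesh, ap64, noiseSd = 0.3, seed = 5)
  expect_identical(b1, b2)
  expect_false(identical(b1, simulateBold(mesh, ap64, noiseSd = 0.3,
                                          seed = 6)))
})
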