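test_that("Weibull observer hits the asymptotes and the threshold point", {
  obs <- psychometricObserver(threshold = 0.02, lapse = 0)
  expect_gt(pCorrect(obs, "UVM", 1), 0.999)
  expect_equal(pCorrect(obs, "UVM", 1e-5), 0.5, tolerance = 1e-6)
  # p at c* equals the 3-down-1-up convergence accuracy, 0.794
  obs2 <- psychometricObserver(threshold = 0.02)
  expect_equal(round(pCorrect(obs2, "LVM", 0.02), 3), 0.794)
  # monotone non-decreasing in contrast
  cs <- seq(0.001, 1, length.out = 200)
  expect_true(all(diff(pCorrect(obs2, "HM_left", cs)) >= 0))
  expect_error(pCorrect(obs2, "UVM", 0), "contrast")
})

test_that("staircase steps down after 3 correct and up after 1 incorrect", {
  st <- staircaseInit()
  st <- staircaseUpdate(st, TRUE)
  st <- staircaseUpdate(st, TRUE)
  expect_equal(st@level, 0.5)  # no step before the third correct
  st <- staircaseUpdate(st, TRUE)
  expect_lt(st@level, 0.5)
  lvl <- st@level
  st <- staircaseUpdate(st, FALSE)
  expect_gt(st@level, lvl)
})

test_that("a scripted response sequence reproduces the hand-traced levels", {
  # script C,C,C, C,C,C, I, C,C,C with initial level 0.5, step 0.3 log10:
  # two down-steps of 0.3, an up reversal (step halves to 0.15), then a
  # down reversal (step halves to 0.075)
  st <- staircaseInit()
  for (r in c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
              TRUE, TRUE, TRUE))
    st <- staircaseUpdate(st, r)
  expect_equal(st@levels[4], 10^(log10(0.5) - 0.3))      # 0.2505936
  expect_equal(st@levels[7], 10^(log10(0.5) - 0.6))      # 0.1255943
  expect_equal(st@levels[8], 10^(log10(0.5) - 0.6 + 0.15))  # 0.1774028
  expect_equal(st@level, 10^(log10(0.5) - 0.45 - 0.075))    # 0.1492791
  expect_equal(st@step, 0.075)
  expect_equal(st@reversalLevels,
               c(log10(0.5) - 0.6, log10(0.5) - 0.45))
})

test_that("PEST doubles the step on the third same-direction step", {
  st <- staircaseInit()
  # three down-steps in a row: 9 consecutive correct responses
  for (i in 1:9) st <- staircaseUpdate(st, TRUE)
  expect_equal(st@step, 0.6)  # doubled on the third step
  # and the step never exceeds the configured maximum
  for (i in 1:9) st <- staircaseUpdate(st, TRUE)
  expect_lte(st@step, 0.6)
})

test_that("blocks are reproducible and estimate thresholds", {
  obs <- psychometricObserver(threshold = 0.02)
  b1 <- runBlock(obs, 50, seed = 11)
  b2 <- runBlock(obs, 50, seed = 11)
  expect_identical(b1, b2)
  expect_equal(nrow(b1$trials), 200)
  expect_equal(unname(table(b1$trials$location)), rep(50L, 4),
               ignore_attr = TRUE)
  # near-step observer: threshold estimate lands close to the edge
  steep <- psychometricObserver(threshold = 0.02, slope = 20, lapse = 0)
  est <- replicate(60, {
    b <- runBlock(steep, 50, seed = sample.int(1e6, 1))
    exp(mean(log(b$threshold)))
  })
  expect_lt(abs(median(log10(est)) - log10(0.02)), 0.15)
})

test_that("converged accuracy sits near the staircase target", {
  acc <- simulateConvergenceAccuracy(20, 200, seed = 3)
  expect_lt(abs(acc - 100 * staircaseConvergenceAccuracy(3)), 3)
})

test_that("threshold aggregation averages blocks then takes reciprocals", {
  mk <- function(th) list(threshold = stats::setNames(rep(th, 4),
                                                      cortmagLocations()),
                          trials = NULL, blockIndex = 1)
  blocks <- lapply(c(0.01, 0.02, 0.02, 0.02, 0.03), mk)
  agg <- aggregateObserver(blocks)
  expect_equal(unname(agg$threshold), rep(0.02, 4))
  expect_equal(unname(agg$sensitivity), rep(50, 4))
  allSame <- lapply(rep(0.01, 5), mk)
  expect_equal(unname(aggregateObserver(allSame)$sensitivity), rep(100, 4))
  expect_error(aggregateObserver(blocks[1:4]), "expected 5 blocks")
  expect_equal(unname(aggregateObserver(blocks[1:4],
                                        relax = TRUE)$threshold)[1],
               mean(c(0.01, 0.02, 0.02, 0.02)))
})

test_that("convergence accuracy solves the up-down balance point", {
  expect_equal(round(100 * staircaseConvergenceAccuracy(3), 1), 79.4)
  expect_equal(staircaseConvergenceAccuracy(1), 0.5)
  expect_equal(staircaseConvergenceAccuracy(2), sqrt(0.5))
})

test_that("across-block threshold means are nearly unbiased for c*", {
  obs <- psychometricObserver(threshold = 0.02)
  set.seed(21)
  est <- replicate(60, {
    blocks <- lapply(1:5, function(b)
      runBlock(obs, 50, seed = sample.int(1e6, 1), blockIndex = b))
    aggregateObserver(blocks)$threshold
  })
  expect_true(all(abs(rowMeans(est) / 0.02 - 1) <= 0.05))
})
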