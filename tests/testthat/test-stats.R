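test_that("asymmetry indices are difference-over-mean percentages", {
  expect_identical(hvaIndex(1, 1), 0)
  expect_identical(vmaIndex(2.5, 2.5), 0)
  expect_equal(hvaIndex(1.5, 1.0), 40)
  expect_equal(vmaIndex(1.2, 1.0), 100 * 0.2 / 1.1)
  expect_equal(vmaIndex(1.0, 1.2), -100 * 0.2 / 1.1)
  # antisymmetry and scale invariance
  expect_equal(hvaIndex(2, 3), -hvaIndex(3, 2))
  expect_equal(hvaIndex(7 * 2, 7 * 3), hvaIndex(2, 3))
  expect_error(hvaIndex(-1, 2), "positive")
})

test_that("meridian aggregation means sensitivities and sums areas", {
  cs <- matrix(c(60, 40, 30, 35), 1, dimnames = list(NULL,
                                                     cortmagLocations()))
  sa <- matrix(c(700, 740, 300, 350), 1, dimnames = list(NULL,
                                                         cortmagLocations()))
  tab <- new("CohortTable", observerId = c("a", "b"),
             cs = rbind(cs, cs), wedgeArea = rbind(sa, sa),
             v1Area = c(2000, 2100), cortexArea = c(1.8e5, 1.9e5))
  agg <- meridianAggregate(tab)
  expect_equal(agg$cs$HM[1], 50)
  expect_equal(agg$cs$VM[1], 32.5)
  expect_equal(agg$area$HM[1], 1440)
  expect_equal(agg$area$VM[1], 650)
})

test_that("Spearman rho matches a brute-force average-rank oracle", {
  expect_equal(spearmanRho(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearmanRho(1:8, rev(1:8), "two.sided")$rho, -1)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  # oracle: explicit average ranks + product-moment formula
  avgRank <- function(v) vapply(v, function(vi)
    mean(which(sort(v) == vi)), numeric(1))
  rx <- avgRank(x); ry <- avgRank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearmanRho(x, y)$rho, oracle)
  expect_true(is.na(spearmanRho(rep(1, 5), 1:5)$rho))
})

test_that("pooled correlation is a rank statistic over all pairs", {
  co <- makeCohort(coupling = 1, noiseSd = 0, seed = 2)
  expect_equal(pooledCorrelation(co$table)$rho, 1)
  # invariant under monotone transforms of CS
  tab2 <- co$table
  tab2@cs <- log(tab2@cs) - min(log(tab2@cs)) + 1
  expect_equal(pooledCorrelation(tab2)$rho, 1)
})

test_that("centering removes the targeted factor", {
  m <- matrix(rnorm(20), 5, 4)
  expect_equal(rowSums(centerData(m, "observer")), rep(0, 5))
  expect_equal(colSums(centerData(m, "location")), rep(0, 4))
  # with a strong location effect, observer-centred data retain more of the
  # CS-area association than location-centred data
  co <- makeCohort(sizeSpread = 1.0001, coupling = 0, noiseSd = 0.02,
                   seed = 5)
  csO <- centerData(contrastSensitivities(co$table), "observer")
  saO <- centerData(wedgeAreas(co$table), "observer")
  csL <- centerData(contrastSensitivities(co$table), "location")
  saL <- centerData(wedgeAreas(co$table), "location")
  rhoO <- cor(as.vector(csO), as.vector(saO), method = "spearman")
  rhoL <- cor(as.vector(csL), as.vector(saL), method = "spearman")
  expect_gt(rhoO, rhoL)
})

test_that("shuffle nulls isolate observer and location variance", {
  # location-only structure: the across-observers null preserves it
  loc <- makeCohort(sizeSpread = 1.0001, coupling = 0, noiseSd = 0.02,
                    seed = 8)
  rho <- pooledCorrelation(loc$table)$rho
  nObs <- shuffleNull(loc$table, "across_observers", 1000, seed = 1)
  nLoc <- shuffleNull(loc$table, "across_locations", 1000, seed = 1)
  expect_lt(abs(nullPercentile(nObs) - rho), 0.1)
  expect_lt(nullPercentile(nLoc), rho - 0.3)
  # observer-only structure: the across-locations null preserves it
  obs <- makeCohort(groupHvaSA = 0, groupVmaSA = 0, groupHvaCS = 0,
                    groupVmaCS = 0, coupling = 1, noiseSd = 0.02, seed = 9)
  rho2 <- pooledCorrelation(obs$table)$rho
  nObs2 <- shuffleNull(obs$table, "across_observers", 1000, seed = 2)
  nLoc2 <- shuffleNull(obs$table, "across_locations", 1000, seed = 2)
  expect_lt(abs(nullPercentile(nLoc2) - rho2), 0.1)
  expect_lt(nullPercentile(nObs2), rho2 - 0.3)
  # determinism and the percentile invariant
  nRep <- shuffleNull(loc$table, "across_observers", 1000, seed = 1)
  expect_identical(nObs@rho, nRep@rho)
  expect_equal(nullPercentile(nObs),
               unname(quantile(nObs@rho, 0.95, type = 7)))
  expect_warning(shuffleNull(loc$table, nIter = 50, seed = 1), "coarse")
})

test_that("V1 normalization is a scale-invariant ratio", {
  expect_equal(normalizeV1(1300, 1e5), 0.013)
  expect_equal(normalizeV1(2600, 2e5), 0.013)
  expect_error(normalizeV1(1300, 0), "cortexArea")
})

test_that("paired t test matches hand computation with Cohen's d", {
  out <- pairedT(c(2, 4, 6), c(1, 2, 3))
  expect_equal(out$t, 2 * sqrt(3))
  expect_equal(out$df, 2)
  expect_equal(out$d, 2)
  flip <- pairedT(c(1, 2, 3), c(2, 4, 6))
  expect_equal(flip$t, -out$t)
  expect_equal(flip$d, -out$d)
  same <- pairedT(1:4, 1:4)
  expect_true(same$degenerate)
  expect_equal(same$d, 0)
})

test_that("split-block indices agree across splits when observers differ", {
  # per-location noise acts as true individual variation in the asymmetries;
  # without it all observers share one HVA and reliability is undefined
  co <- makeCohort(noiseSd = 0.15, seed = 12)
  meas <- measureCohortPsychophysics(co, seed = 13)
  rel <- blockReliability(meas$blockThresholds)
  expect_gt(rel$hva$rho, 0.3)
  # identical splits correlate perfectly
  relSame <- blockReliability(meas$blockThresholds, c(1, 2, 3), c(1, 2, 3))
  expect_equal(relSame$hva$rho, 1)
  expect_equal(relSame$vma$rho, 1)
})
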