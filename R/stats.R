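#' @include AllClasses.R utils.R
NULL

#' Aggregate the four locations into meridian summaries
#'
#' Contrast sensitivity at the horizontal meridian is the mean of the left
#' and right horizontal measurements, and at the vertical meridian the mean
#' of the upper and lower measurements; wedge-ROI surface areas are summed
#' instead (HM = left + right wedges, VM = UVM + LVM).
#'
#' @param table a [CohortTable-class].
#' @return List of two data.frames, `cs` (columns `HM`, `VM`, `UVM`, `LVM`;
#'   means) and `area` (same columns; sums), one row per observer.
#' @export
meridianAggregate <- function(table) {
  cs <- contrastSensitivities(table)
  sa <- wedgeAreas(table)
  list(
    cs = data.frame(
      HM = (cs[, "HM_left"] + cs[, "HM_right"]) / 2,
      VM = (cs[, "UVM"] + cs[, "LVM"]) / 2,
      UVM = cs[, "UVM"], LVM = cs[, "LVM"]),
    area = data.frame(
      HM = sa[, "HM_left"] + sa[, "HM_right"],
      VM = sa[, "UVM"] + sa[, "LVM"],
      UVM = sa[, "UVM"], LVM = sa[, "LVM"])
  )
}

#' Horizontal-vertical asymmetry index
#'
#' `100 * (horizontal - vertical) / mean(horizontal, vertical)`. Zero means
#' no asymmetry; positive values mean a horizontal advantage. Antisymmetric
#' under swapping the inputs and invariant to rescaling both.
#'
#' @param horizontal,vertical positive measurements (vectorized).
#' @return Index in percent.
#' @examples
#' hvaIndex(1.5, 1.0)  # 40
#' @export
hvaIndex <- function(horizontal, vertical) {
  if (any(horizontal <= 0) || any(vertical <= 0))
    stop("inputs must be positive")
  100 * (horizontal - vertical) / ((horizontal + vertical) / 2)
}

#' Vertical-meridian asymmetry index
#'
#' `100 * (lower - upper) / mean(lower, upper)`: positive values mean a
#' lower-vertical advantage.
#'
#' @param lower,upper positive measurements at the lower and upper vertical
#'   meridian (vectorized).
#' @return Index in percent.
#' @export
vmaIndex <- function(lower, upper) {
  hvaIndex(lower, upper)
}

#' Per-observer and group asymmetry indices of a cohort
#'
#' @param table a [CohortTable-class].
#' @return List with per-observer data.frame `perObserver` (columns
#'   `hva_cs`, `vma_cs`, `hva_sa`, `vma_sa`) and the group means `groupMean`.
#' @export
cohortIndices <- function(table) {
  agg <- meridianAggregate(table)
  per <- data.frame(
    hva_cs = hvaIndex(agg$cs$HM, agg$cs$VM),
    vma_cs = vmaIndex(agg$cs$LVM, agg$cs$UVM),
    hva_sa = hvaIndex(agg$area$HM, agg$area$VM),
    vma_sa = vmaIndex(agg$area$LVM, agg$area$UVM))
  list(perObserver = per, groupMean = colMeans(per))
}

#' Spearman rank correlation with a directional alternative
#'
#' Rank correlation with average ranks for ties; exact p-values for n < 10
#' without ties, the large-sample approximation otherwise. One-tailed
#' `"greater"` tests a positive monotonic association.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List with `rho` and `p`. A constant vector gives `rho = NA`.
#' @export
spearmanRho <- function(x, y, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  hasTies <- anyDuplicated(x) || anyDuplicated(y)
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = "spearman", alternative = alternative,
    exact = length(x) < 10 && !hasTies))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Pooled correlation between sensitivity and wedge area
#'
#' Pools all observer-by-location (contrast sensitivity, wedge area) pairs
#' of a cohort into one Spearman correlation.
#'
#' @param table a [CohortTable-class].
#' @param alternative passed to [spearmanRho()].
#' @return List with `rho` and `p`.
#' @export
pooledCorrelation <- function(table, alternative = "greater") {
  spearmanRho(as.vector(contrastSensitivities(table)),
              as.vector(wedgeAreas(table)), alternative)
}

#' Permutation null distributions for the pooled correlation
#'
#' Generates a null distribution of the pooled Spearman correlation by
#' shuffling the pairing between contrast-sensitivity quadruples and
#' surface-area quadruples and reports its 95th percentile (x0.95).
#' `"across_observers"` permutes which observer's CS quadruple is paired
#' with which observer's SA quadruple while maintaining the tie of each
#' value to its location, removing between-observer structure;
#' `"across_locations"` permutes, independently per observer, the location
#' labels of the CS quadruple relative to the SA quadruple, removing the
#' shared location structure. A fresh random permutation is drawn on every
#' iteration (sampling with replacement from the permutation group), so the
#' result is seeded and reproducible.
#'
#' @param table a [CohortTable-class].
#' @param mode `"across_observers"` or `"across_locations"`.
#' @param nIter iterations (default 10000; a warning is logged below 100).
#' @param seed integer seed.
#' @return A [NullDistributionResult-class].
#' @export
shuffleNull <- function(table, mode = c("across_observers",
                                        "across_locations"),
                        nIter = 10000, seed = 1L) {
  mode <- match.arg(mode)
  if (nIter < 100) warning("nIter < 100 gives a very coarse x0.95")
  cs <- contrastSensitivities(table)
  sa <- wedgeAreas(table)
  n <- nrow(cs)
  obsRho <- spearmanRho(as.vector(cs), as.vector(sa))$rho
  set.seed(childSeed(seed, paste0("null-", mode)))
  rho <- vapply(seq_len(nIter), function(i) {
    csPerm <- if (mode == "across_observers") {
      cs[sample.int(n), , drop = FALSE]
    } else {
      t(apply(cs, 1, function(row) row[sample.int(4)]))
    }
    stats::cor(as.vector(csPerm), as.vector(sa), method = "spearman")
  }, numeric(1))
  new("NullDistributionResult",
      observedRho = obsRho, rho = rho,
      x95 = unname(stats::quantile(rho, 0.95, type = 7)),
      mode = mode, seed = as.integer(seed))
}

#' Centre an observers-by-locations matrix
#'
#' `by = "observer"` subtracts each observer's mean across the four
#' locations (isolating the location effect); `by = "location"` subtracts
#' each location's mean across observers (isolating the observer effect).
#'
#' @param m numeric matrix, observers x locations.
#' @param by `"observer"` or `"location"`.
#' @return The centred matrix.
#' @export
centerData <- function(m, by = c("observer", "location")) {
  by <- match.arg(by)
  if (by == "observer") m - rowMeans(m) else sweep(m, 2, colMeans(m))
}

#' Normalize V1 size by total cortical surface area
#'
#' @param v1Area V1 surface area, mm^2.
#' @param cortexArea total cortical surface area, mm^2 (> 0).
#' @return The dimensionless ratio (vectorized).
#' @export
normalizeV1 <- function(v1Area, cortexArea) {
  stopifnot(all(cortexArea > 0))
  v1Area / cortexArea
}

#' Paired-samples t test with Cohen's d
#'
#' @param a,b equal-length paired measurements (n >= 2).
#' @return List with `t`, `df` (= n - 1), `p` (two-sided), `d` (Cohen's d =
#'   mean(diff) / sd(diff)) and `degenerate` (TRUE when the differences
#'   have zero variance, in which case t and p are NA and d is 0).
#' @export
pairedT <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                d = 0, degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(d) / stats::sd(d), degenerate = FALSE)
}

#' Split-block reliability of the asymmetry indices
#'
#' Recomputes contrast sensitivity per observer from two disjoint subsets
#' of blocks, derives HVA and VMA indices from each split, and correlates
#' them across observers.
#'
#' @param blockThresholds observer x block x location array of per-block
#'   thresholds (from [measureCohortPsychophysics()]).
#' @param splitA,splitB disjoint non-empty block index sets.
#' @return List with `hva` and `vma`, each a [spearmanRho()] result across
#'   observers.
#' @export
blockReliability <- function(blockThresholds, splitA = c(1, 3, 5),
                             splitB = c(2, 4)) {
  stopifnot(length(splitA) > 0, length(splitB) > 0)
  idx <- function(split) {
    th <- apply(blockThresholds[, split, , drop = FALSE], c(1, 3), mean)
    cs <- 1 / th
    hm <- (cs[, "HM_left"] + cs[, "HM_right"]) / 2
    vm <- (cs[, "UVM"] + cs[, "LVM"]) / 2
    list(hva = hvaIndex(hm, vm), vma = vmaIndex(cs[, "LVM"], cs[, "UVM"]))
  }
  a <- idx(splitA)
  b <- idx(splitB)
  list(hva = spearmanRho(a$hva, b$hva),
       vma = spearmanRho(a$vma, b$vma))
}
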