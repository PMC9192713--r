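#' @include AllClasses.R utils.R staircase.R
NULL

## ratio r between two quantities whose percentage asymmetry index
## (difference over mean, x100) equals idx: r = (1 + idx/200)/(1 - idx/200)
indexToRatio <- function(idx) (1 + idx / 200) / (1 - idx / 200)

#' Generate a synthetic observer cohort
#'
#' Builds `nObservers` synthetic observers with: log-normal V1 sizes whose
#' +/-2 SD range spans about `sizeSpread`-fold; wedge-ROI areas at the four
#' locations equal to each observer's V1 share times meridian modulations
#' that realize the planted surface-area asymmetries (`groupHvaSA`,
#' `groupVmaSA`, in index points); and contrast sensitivities tied to the
#' corresponding wedge area by a monotone power law. `coupling` blends (in
#' log space) between the area-driven component (coupling = 1: CS is an
#' exact monotone function of wedge area, so the pooled Spearman correlation
#' is 1 at zero noise) and an independent component with its own location
#' effects realizing `groupHvaCS` / `groupVmaCS` and an independent observer
#' factor (coupling = 0: CS carries no observer-level association with the
#' areas). Multiplicative log-normal noise of SD `noiseSd` is applied to
#' both areas and sensitivities. Weibull thresholds are the reciprocals of
#' the planted sensitivities.
#'
#' At coupling = 1 the CS vertical-meridian asymmetry is implied by the
#' power law linking CS to surface area rather than independently
#' plantable; with the default targets it is ~20.7 rather than 20 index
#' points (see the package vignette).
#'
#' @param nObservers cohort size (default 29).
#' @param sizeSpread approximate max/min fold-change in V1 size (default 2).
#' @param groupHvaSA,groupVmaSA planted group surface-area asymmetries,
#'   index points (defaults 60 and 25).
#' @param groupHvaCS,groupVmaCS planted group contrast-sensitivity
#'   asymmetries, index points (defaults 50 and 20).
#' @param coupling area-to-sensitivity coupling in [0, 1] (default 0.8).
#' @param noiseSd SD of multiplicative log-normal noise (default 0.05).
#' @param meanV1 mean V1 area, mm^2, both hemispheres, 0-8 deg
#'   (default 2500).
#' @param meanCS mean contrast sensitivity (default 50).
#' @param wedgeFraction fraction of V1 area covered by the four wedges
#'   combined (default 0.27).
#' @param seed integer seed.
#' @return List with `table` (the planted [CohortTable-class]), `observers`
#'   (list of [PsychometricObserver-class], one per observer) and `planted`
#'   (the noiseless planted CS and wedge-area matrices, for
#'   recovery checks).
#' @export
makeCohort <- function(nObservers = 29, sizeSpread = 2,
                       groupHvaSA = 60, groupVmaSA = 25,
                       groupHvaCS = 50, groupVmaCS = 20,
                       coupling = 0.8, noiseSd = 0.05,
                       meanV1 = 2500, meanCS = 50,
                       wedgeFraction = 0.27, seed = 1L) {
  stopifnot(nObservers >= 2)
  if (coupling < 0 || coupling > 1)
    stop("coupling must lie in [0, 1]")
  set.seed(childSeed(seed, "cohort"))
  locs <- cortmagLocations()

  ## observer sizes: +/-2 SD of log-normal spans ~sizeSpread-fold
  sdLog <- log(sizeSpread) / 4
  v1 <- exp(stats::rnorm(nObservers, log(meanV1), sdLog))
  cortex <- exp(log(1.9e5) +
                  0.3 * (log(v1) - log(meanV1)) +
                  stats::rnorm(nObservers, 0, 0.05))

  ## meridian shares of the total wedge area realizing the SA asymmetries
  rH <- indexToRatio(groupHvaSA)    # (HM_L + HM_R) / (UVM + LVM)
  rV <- indexToRatio(groupVmaSA)    # LVM / UVM
  vShare <- 1 / (1 + rH)
  share <- c(HM_left = rH / (1 + rH) / 2, HM_right = rH / (1 + rH) / 2,
             UVM = vShare / (1 + rV), LVM = vShare * rV / (1 + rV))
  plantedW <- (v1 * wedgeFraction) %o% share
  colnames(plantedW) <- locs
  wedge <- plantedW * exp(matrix(stats::rnorm(nObservers * 4, 0, noiseSd),
                                 nObservers))

  ## CS: power-law link to wedge area blended with an independent component
  ## power-law exponent mapping the SA asymmetry onto the CS asymmetry;
  ## with no planted SA asymmetry the link defaults to proportionality
  beta <- if (abs(rH - 1) < 1e-12) 1 else log(indexToRatio(groupHvaCS)) / log(rH)
  cH <- indexToRatio(groupHvaCS)      # CS location effects (means)
  cV <- indexToRatio(groupVmaCS)
  cLoc <- c(HM_left = cH, HM_right = cH,
            UVM = 2 / (1 + cV), LVM = 2 * cV / (1 + cV))
  cLoc <- cLoc / exp(mean(log(cLoc)))
  vObs <- exp(stats::rnorm(nObservers, 0, sdLog))

  logArea <- log(plantedW) - mean(log(plantedW))
  logIndep <- log(vObs) %o% rep(1, 4) + rep(1, nObservers) %o% log(cLoc)
  plantedCS <- meanCS * exp(coupling * beta * logArea +
                              (1 - coupling) * logIndep)
  colnames(plantedCS) <- locs
  cs <- plantedCS * exp(matrix(stats::rnorm(nObservers * 4, 0, noiseSd),
                               nObservers))

  table <- new("CohortTable",
               observerId = sprintf("obs%02d", seq_len(nObservers)),
               cs = cs, wedgeArea = wedge,
               v1Area = v1, cortexArea = cortex)
  observers <- lapply(seq_len(nObservers), function(i)
    psychometricObserver(threshold = pmin(1, 1 / cs[i, ])))
  list(table = table, observers = observers,
       planted = list(cs = plantedCS, wedgeArea = plantedW))
}

#' Measure a cohort's contrast sensitivities by staircase simulation
#'
#' Runs the full psychophysics protocol for every observer in a synthetic
#' cohort: five 200-trial blocks of four interleaved 3-down-1-up PEST
#' staircases, thresholds averaged across blocks, sensitivity as the
#' reciprocal of the mean threshold. Returns a new [CohortTable-class] with
#' the measured sensitivities alongside the cohort's wedge areas.
#'
#' @param cohort result of [makeCohort()].
#' @param nBlocks blocks per observer (default 5).
#' @param nTrialsPerLocation trials per location per block (default 50).
#' @param seed integer seed.
#' @return List with `table` (measured [CohortTable-class]) and
#'   `blockThresholds` (observer x block x location array, for
#'   split-block reliability analyses).
#' @export
measureCohortPsychophysics <- function(cohort, nBlocks = 5,
                                       nTrialsPerLocation = 50, seed = 1L) {
  n <- length(cohort$observers)
  locs <- cortmagLocations()
  blockTh <- array(NA_real_, c(n, nBlocks, 4),
                   dimnames = list(observerIds(cohort$table), NULL, locs))
  cs <- matrix(NA_real_, n, 4, dimnames = list(NULL, locs))
  for (i in seq_len(n)) {
    blocks <- lapply(seq_len(nBlocks), function(b)
      runBlock(cohort$observers[[i]], nTrialsPerLocation,
               seed = childSeed(seed, sprintf("obs%d", i)),
               blockIndex = b))
    for (b in seq_len(nBlocks)) blockTh[i, b, ] <- blocks[[b]]$threshold
    cs[i, ] <- aggregateObserver(blocks, nExpected = nBlocks)$sensitivity
  }
  table <- new("CohortTable",
               observerId = observerIds(cohort$table),
               cs = cs, wedgeArea = wedgeAreas(cohort$table),
               v1Area = v1Areas(cohort$table),
               cortexArea = cortexAreas(cohort$table))
  list(table = table, blockThresholds = blockTh)
}
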