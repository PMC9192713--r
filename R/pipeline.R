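#' @include AllClasses.R mesh.R wedge.R prf.R bold.R cohort.R stats.R
NULL

#' Default pipeline configuration
#'
#' A flat list of every tunable the end-to-end run uses, with the standard
#' defaults: a 12.4-deg-radius aperture swept in 24 one-second steps over 8
#' sweeps; +/-15 deg wedges pooled +/-8 deg around the boundary over 10
#' log-spaced bands between 1 and 8 deg; the R^2 > 10% inclusion gate; 50
#' trials x 4 locations x 5 blocks of psychophysics; and the planted cohort
#' asymmetries (surface area 60/25, contrast sensitivity 50/20 index
#' points). Override any entry via `...` in [runPipeline()].
#'
#' @return Named list of configuration values.
#' @export
pipelineConfig <- function() {
  list(
    seed = 1L,
    # synthetic cortex
    nEccRings = 121L, nAngleSpokes = 91L, eccRange = c(0.2, 12.4),
    meshHvaSA = 60, meshVmaSA = 25,
    # pRF simulation / fit (run on a vertex subsample for speed)
    doPRF = TRUE, prfVertices = 40L, prfNoiseSd = 0, gridSize = 64L,
    # wedge-ROI
    wedgeHalfWidth = 15, poolHalfWidth = 8, wedgeEccRange = c(1, 8),
    nBands = 10L,
    # cohort + psychophysics
    nObservers = 29L, sizeSpread = 2, groupHvaSA = 60, groupVmaSA = 25,
    groupHvaCS = 50, groupVmaCS = 20, coupling = 0.8, noiseSd = 0.05,
    nBlocks = 5L, nTrialsPerLocation = 50L,
    # statistics
    nIter = 1000L
  )
}

#' Run the full synthesize-simulate-fit-measure-analyse pipeline
#'
#' Executes the stages in dependency order on synthetic data: (1) build
#' left and right hemisphere meshes with the planted magnification
#' asymmetries and measure wedge-ROI areas and V1 size on them, comparing
#' against the analytic magnification integrals; (2) optionally simulate
#' BOLD at a subsample of vertices and refit the pRF model, reporting
#' parameter recovery; (3) generate a cohort, run the staircase
#' psychophysics, and compute the asymmetry indices, pooled Spearman
#' correlation, and both permutation nulls, with recovery diagnostics
#' against the planted ground truth. Fully deterministic under the seed.
#'
#' @param config list from [pipelineConfig()].
#' @param ... individual config overrides, e.g. `runPipeline(seed = 7)`.
#' @return Nested list report with elements `mesh`, `prf` (if enabled),
#'   `cohort` and `stats`.
#' @export
runPipeline <- function(config = pipelineConfig(), ...) {
  over <- list(...)
  config[names(over)] <- over
  cfg <- config
  report <- list(seed = cfg$seed)

  ## stage 1: synthetic cortex and wedge areas
  amp <- solveAsymmetryAmplitudes(cfg$meshHvaSA, cfg$meshVmaSA,
                                  cfg$wedgeHalfWidth)
  model <- magnificationModel(alpha = amp$alpha, gamma = amp$gamma)
  meshL <- makeSyntheticHemisphere(model, cfg$nEccRings, cfg$nAngleSpokes,
                                   cfg$eccRange, hemisphere = "left",
                                   seed = cfg$seed)
  meshR <- makeSyntheticHemisphere(model, cfg$nEccRings, cfg$nAngleSpokes,
                                   cfg$eccRange, hemisphere = "right",
                                   seed = cfg$seed)
  wcfg <- wedgeConfig(cfg$wedgeHalfWidth, cfg$poolHalfWidth,
                      cfg$wedgeEccRange, cfg$nBands)
  wa <- wedgeAreasByMeridian(meshL, meshR, cfg = wcfg)
  comb <- wa$combined
  analytic <- c(
    HM = analyticSectorArea(model, c(-15, 15), cfg$wedgeEccRange) +
      analyticSectorArea(model, c(165, 195), cfg$wedgeEccRange),
    VM = analyticSectorArea(model, c(75, 105), cfg$wedgeEccRange) +
      analyticSectorArea(model, c(255, 285), cfg$wedgeEccRange))
  report$mesh <- list(
    totalArea = sum(vertexAreas(meshL)) + sum(vertexAreas(meshR)),
    v1Area = v1TotalArea(meshL) + v1TotalArea(meshR),
    wedgeAreas = wa$locations,
    hvaSA = hvaIndex(comb[["HM"]], comb[["VM"]]),
    vmaSA = vmaIndex(comb[["LVM"]], comb[["UVM"]]),
    analyticWedgeAreas = analytic,
    plantedHvaSA = cfg$meshHvaSA, plantedVmaSA = cfg$meshVmaSA)

  ## stage 2: pRF simulate-and-recover on a vertex subsample
  if (isTRUE(cfg$doPRF)) {
    aperture <- makeBarAperture(gridSize = cfg$gridSize)
    set.seed(childSeed(cfg$seed, "prf-sample"))
    keep <- which(eccentricities(meshL) >= 0.5 &
                    eccentricities(meshL) <= 11)
    vs <- sample(keep, min(cfg$prfVertices, length(keep)))
    sub <- meshSubset(meshL, vs)
    bold <- simulateBold(sub, aperture, noiseSd = cfg$prfNoiseSd,
                         seed = cfg$seed)
    fit <- fitPRF(bold, aperture)
    truth <- groundTruthRetinotopy(sub)
    err <- pmax(abs(fit@x - truth@x), abs(fit@y - truth@y),
                abs(fit@sigma - truth@sigma))
    report$prf <- list(
      nVertices = length(vs),
      medianR2 = stats::median(fit@r2),
      fracRecovered = mean(err <= 0.1),
      medianError = stats::median(err))
  }

  ## stage 3: cohort, psychophysics, statistics
  cohort <- makeCohort(cfg$nObservers, cfg$sizeSpread,
                       cfg$groupHvaSA, cfg$groupVmaSA,
                       cfg$groupHvaCS, cfg$groupVmaCS,
                       cfg$coupling, cfg$noiseSd, seed = cfg$seed)
  meas <- measureCohortPsychophysics(cohort, cfg$nBlocks,
                                     cfg$nTrialsPerLocation,
                                     seed = cfg$seed)
  measured <- cohortIndices(meas$table)
  planted <- cohortIndices(cohort$table)
  plantedRho <- spearmanRho(as.vector(cohort$planted$cs),
                            as.vector(cohort$planted$wedgeArea))$rho
  pooled <- pooledCorrelation(meas$table)
  nullObs <- shuffleNull(meas$table, "across_observers", cfg$nIter,
                         seed = cfg$seed)
  nullLoc <- shuffleNull(meas$table, "across_locations", cfg$nIter,
                         seed = cfg$seed)
  csMean <- rowMeans(contrastSensitivities(meas$table))
  agg <- meridianAggregate(meas$table)
  report$cohort <- list(
    nObservers = cfg$nObservers,
    groupMeanIndices = measured$groupMean,
    plantedGroupMeanIndices = planted$groupMean,
    plantedPooledRho = plantedRho)
  report$stats <- list(
    pooledRho = pooled$rho, pooledP = pooled$p,
    x95AcrossObservers = nullPercentile(nullObs),
    x95AcrossLocations = nullPercentile(nullLoc),
    exceedsBothNulls = pooled$rho > nullPercentile(nullObs) &&
      pooled$rho > nullPercentile(nullLoc),
    v1SizeCsRho = spearmanRho(v1Areas(meas$table), csMean)$rho,
    v1NormalizedCsRho = spearmanRho(
      normalizeV1(v1Areas(meas$table), cortexAreas(meas$table)),
      csMean)$rho,
    pairedHMvsVM_cs = pairedT(agg$cs$HM, agg$cs$VM),
    pairedLVMvsUVM_cs = pairedT(agg$cs$LVM, agg$cs$UVM),
    blockReliability = if (cfg$nBlocks >= 2)
      blockReliability(meas$blockThresholds,
                       splitA = seq(1, cfg$nBlocks, by = 2),
                       splitB = seq(2, cfg$nBlocks, by = 2)))
  report
}

#' Extract a vertex subset of a mesh as a standalone mesh
#'
#' Keeps the selected vertices and any faces whose three corners are all
#' kept; per-vertex areas are recomputed from the surviving faces so the
#' area invariant holds on the subset (boundary vertices lose the area of
#' dropped triangles).
#'
#' @param mesh a [CorticalMesh-class].
#' @param vertices integer vertex indices to keep.
#' @return A [CorticalMesh-class].
#' @export
meshSubset <- function(mesh, vertices) {
  vertices <- sort(unique(as.integer(vertices)))
  map <- integer(nVertices(mesh))
  map[vertices] <- seq_along(vertices)
  f <- meshFaces(mesh)
  keep <- map[f[, 1]] > 0 & map[f[, 2]] > 0 & map[f[, 3]] > 0
  faces <- matrix(map[f[keep, , drop = FALSE]], ncol = 3)
  storage.mode(faces) <- "integer"
  v <- meshVertices(mesh)[vertices, , drop = FALSE]
  new("CorticalMesh",
      hemisphere = hemisphere(mesh), depth = meshDepth(mesh),
      vertices = v, faces = faces,
      vertexArea = vertexAreasFromFaces(v, faces),
      polarAngle = polarAngles(mesh)[vertices],
      eccentricity = eccentricities(mesh)[vertices])
}
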