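#' @import methods
NULL

## Polar-angle convention used throughout the package:
## 0 deg = right horizontal meridian, 90 = upper vertical, 180 = left
## horizontal, 270 = lower vertical; angles increase counter-clockwise.
## x is positive rightward, y positive upward (deg of visual angle).

#' Canonical location labels
#'
#' The four polar-angle locations at which contrast sensitivity and wedge-ROI
#' surface area are measured, in the fixed column order used by all matrices
#' in the package.
#'
#' @return Character vector `c("HM_left", "HM_right", "UVM", "LVM")`.
#' @export
cortmagLocations <- function() c("HM_left", "HM_right", "UVM", "LVM")

#' CorticalMesh: a triangulated hemisphere surface with retinotopy
#'
#' A flat (2D) triangulated model of one hemisphere of V1 carrying, per
#' vertex: cortical coordinates (mm), surface area (mm^2, one third of the
#' incident triangle areas), and ground-truth retinotopy (polar angle and
#' eccentricity in deg of visual angle).
#'
#' @slot hemisphere `"left"` or `"right"`. The left hemisphere represents the
#'   right visual hemifield (polar angles in (-90, 90] deg, stored mod 360)
#'   and vice versa.
#' @slot depth `"midgray"`, `"pial"` or `"white"`; the cortical depth whose
#'   vertex areas are stored.
#' @slot vertices numeric matrix, one row per vertex, columns cortical u/v
#'   coordinates in mm.
#' @slot faces integer matrix, one row per triangle, three vertex indices.
#' @slot vertexArea numeric, per-vertex surface area in mm^2 (non-negative;
#'   sums exactly to the summed triangle areas).
#' @slot polarAngle numeric, ground-truth pRF polar angle per vertex, deg in
#'   [0, 360).
#' @slot eccentricity numeric, ground-truth eccentricity per vertex, deg in
#'   [0, 12.4].
#'
#' @export
setClass("CorticalMesh",
  representation(
    hemisphere   = "character",
    depth        = "character",
    vertices     = "matrix",
    faces        = "matrix",
    vertexArea   = "numeric",
    polarAngle   = "numeric",
    eccentricity = "numeric"
  )
)

setValidity("CorticalMesh", function(object) {
  msg <- character()
  n <- nrow(object@vertices)
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (!object@depth %in% c("midgray", "pial", "white"))
    msg <- c(msg, "depth must be 'midgray', 'pial' or 'white'")
  if (ncol(object@faces) != 3L)
    msg <- c(msg, "faces must have 3 columns")
  if (nrow(object@faces) > 0 &&
      (min(object@faces) < 1L || max(object@faces) > n))
    msg <- c(msg, "face indices out of range")
  if (length(object@vertexArea) != n ||
      length(object@polarAngle) != n ||
      length(object@eccentricity) != n)
    msg <- c(msg, "per-vertex slots must match the number of vertices")
  if (any(object@vertexArea < 0))
    msg <- c(msg, "vertex areas must be non-negative")
  if (any(object@eccentricity < -1e-9 | object@eccentricity > 12.4 + 1e-9))
    msg <- c(msg, "eccentricities must lie within [0, 12.4] deg")
  tri <- triangleAreas(object@vertices, object@faces)
  if (abs(sum(object@vertexArea) - sum(tri)) >
      1e-6 * max(1, sum(tri)))
    msg <- c(msg, "vertex areas must sum to the total triangle area")
  if (length(msg)) msg else TRUE
})

#' StimulusAperture: a time-ordered stack of contrast aperture frames
#'
#' Binary contrast-aperture frames of a retinotopic-mapping stimulus on a
#' square visual-field pixel grid, one frame per TR.
#'
#' @slot frames numeric matrix, frames x pixels, values in [0, 1]; pixels are
#'   stored column-major over the `gridSize` x `gridSize` grid.
#' @slot gridSize integer, pixels per side.
#' @slot degPerPix numeric, degrees of visual angle per pixel.
#' @slot frameDuration numeric, seconds per frame (the TR).
#' @slot radius numeric, radius of the circular aperture in deg.
#' @slot schedule data.frame with one row per frame: `sweep` (1-8),
#'   `direction` (deg, direction of bar travel), `step` (1-based step within
#'   the sweep), `blank` (logical).
#'
#' @export
setClass("StimulusAperture",
  representation(
    frames        = "matrix",
    gridSize      = "integer",
    degPerPix     = "numeric",
    frameDuration = "numeric",
    radius        = "numeric",
    schedule      = "data.frame"
  )
)

setValidity("StimulusAperture", function(object) {
  msg <- character()
  if (ncol(object@frames) != object@gridSize^2)
    msg <- c(msg, "frames must have gridSize^2 pixel columns")
  if (nrow(object@frames) != nrow(object@schedule))
    msg <- c(msg, "frame count must equal schedule length")
  if (any(object@frames < 0 | object@frames > 1))
    msg <- c(msg, "frame values must lie in [0, 1]")
  blank <- object@schedule$blank
  if (any(rowSums(object@frames[blank, , drop = FALSE]) > 0))
    msg <- c(msg, "blank frames must be all-zero")
  if (length(msg)) msg else TRUE
})

#' RetinotopyMap: per-vertex pRF parameters
#'
#' Fitted (or ground-truth) pRF parameters per mesh vertex, with the derived
#' polar angle / eccentricity and the variance-explained inclusion gate.
#'
#' @slot x,y numeric, pRF centre in deg (signed; x rightward, y upward).
#' @slot sigma numeric, pRF size (Gaussian SD) in deg, positive.
#' @slot gain numeric, fitted response gain (signal units), non-negative.
#' @slot r2 numeric in [0, 1], variance explained by the pRF prediction.
#' @slot polarAngle,eccentricity numeric, derived from (x, y).
#' @slot included logical; `TRUE` iff `r2 > 0.10`, the analysis gate.
#'
#' @export
setClass("RetinotopyMap",
  representation(
    x = "numeric", y = "numeric", sigma = "numeric",
    gain = "numeric", r2 = "numeric",
    polarAngle = "numeric", eccentricity = "numeric",
    included = "logical"
  )
)

setValidity("RetinotopyMap", function(object) {
  n <- length(object@x)
  lens <- c(length(object@y), length(object@sigma), length(object@gain),
            length(object@r2), length(object@polarAngle),
            length(object@eccentricity), length(object@included))
  msg <- character()
  if (any(lens != n))
    msg <- c(msg, "all slots must have equal length")
  if (any(object@r2 < -1e-12 | object@r2 > 1 + 1e-12))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (!identical(object@included, object@r2 > 0.10))
    msg <- c(msg, "included must equal r2 > 0.10")
  if (length(msg)) msg else TRUE
})

#' PsychometricObserver: a simulated 2AFC Weibull observer
#'
#' A Weibull psychometric observer for two-alternative forced-choice contrast
#' discrimination. The threshold `threshold[l]` at each location is the
#' Michelson contrast at which the observer's probability correct equals the
#' 3-down-1-up staircase convergence accuracy (0.5^(1/3), about 79.4%).
#'
#' @slot threshold named numeric, threshold contrast c* per location in
#'   (0, 1]; names are `cortmagLocations()`.
#' @slot slope numeric, Weibull slope (beta), positive.
#' @slot guess numeric, guess rate (0.5 for 2AFC).
#' @slot lapse numeric in [0, 0.5), lapse rate.
#'
#' @export
setClass("PsychometricObserver",
  representation(
    threshold = "numeric",
    slope = "numeric",
    guess = "numeric",
    lapse = "numeric"
  )
)

setValidity("PsychometricObserver", function(object) {
  msg <- character()
  if (any(object@threshold <= 0 | object@threshold > 1))
    msg <- c(msg, "thresholds must lie in (0, 1]")
  if (object@slope <= 0) msg <- c(msg, "slope must be positive")
  if (object@guess < 0 || object@guess >= 1)
    msg <- c(msg, "guess rate must lie in [0, 1)")
  if (object@lapse < 0 || object@lapse >= 0.5)
    msg <- c(msg, "lapse rate must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' CohortTable: per-observer sensitivities and wedge areas
#'
#' The cohort-level data consumed by the asymmetry statistics: per observer,
#' contrast sensitivity and wedge-ROI surface area at the four polar-angle
#' locations, plus V1 size (0-8 deg, both hemispheres) and total cortical
#' surface area.
#'
#' @slot observerId character, one id per observer.
#' @slot cs numeric matrix observers x 4 (columns `cortmagLocations()`),
#'   contrast sensitivity (1 / threshold Michelson contrast).
#' @slot wedgeArea numeric matrix observers x 4, wedge-ROI surface area, mm^2.
#' @slot v1Area numeric, V1 surface area (mm^2, both hemispheres, 0-8 deg).
#' @slot cortexArea numeric, total cortical surface area (mm^2).
#'
#' @export
setClass("CohortTable",
  representation(
    observerId = "character",
    cs = "matrix",
    wedgeArea = "matrix",
    v1Area = "numeric",
    cortexArea = "numeric"
  )
)

setValidity("CohortTable", function(object) {
  msg <- character()
  n <- length(object@observerId)
  if (n < 2) msg <- c(msg, "a cohort needs at least 2 observers")
  for (nm in c("cs", "wedgeArea")) {
    m <- slot(object, nm)
    if (nrow(m) != n || ncol(m) != 4L)
      msg <- c(msg, sprintf("%s must be an observers x 4 matrix", nm))
    else if (!identical(colnames(m), cortmagLocations()))
      msg <- c(msg, sprintf("%s columns must be the canonical locations", nm))
    if (any(!is.finite(m)) || any(m <= 0))
      msg <- c(msg, sprintf("%s values must be positive and finite", nm))
  }
  if (length(object@v1Area) != n || any(object@v1Area <= 0))
    msg <- c(msg, "v1Area must be positive, one value per observer")
  if (length(object@cortexArea) != n || any(object@cortexArea <= 0))
    msg <- c(msg, "cortexArea must be positive, one value per observer")
  if (length(msg)) msg else TRUE
})

#' NullDistributionResult: a permutation null for the pooled correlation
#'
#' The result of shuffling the pairing between contrast-sensitivity and
#' surface-area quadruples (across observers or across locations) and
#' recomputing the pooled Spearman correlation on each iteration.
#'
#' @slot observedRho numeric, the pooled Spearman rho on the unshuffled data.
#' @slot rho numeric vector of permuted pooled rho values (length `nIter`).
#' @slot x95 numeric, the 95th percentile of `rho` (linear interpolation).
#' @slot mode `"across_observers"` or `"across_locations"`.
#' @slot seed integer seed used for the shuffle.
#'
#' @export
setClass("NullDistributionResult",
  representation(
    observedRho = "numeric",
    rho = "numeric",
    x95 = "numeric",
    mode = "character",
    seed = "integer"
  )
)

setValidity("NullDistributionResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("across_observers", "across_locations"))
    msg <- c(msg, "mode must be 'across_observers' or 'across_locations'")
  q <- unname(stats::quantile(object@rho, 0.95, type = 7))
  if (abs(q - object@x95) > 1e-12)
    msg <- c(msg, "x95 must be the 95th percentile of rho")
  if (length(msg)) msg else TRUE
})
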