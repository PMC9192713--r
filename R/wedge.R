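#' @include AllClasses.R utils.R prf.R
NULL

#' DistanceMap: geodesic distance from a meridian line
#'
#' Per-vertex shortest-path distance (mm) along mesh edges from a set of
#' seed vertices on a meridian line; seeds have distance exactly 0 and
#' disconnected vertices are `Inf`.
#'
#' @slot distance numeric, per-vertex distance in mm.
#' @slot meridian label of the seeding meridian.
#' @export
setClass("DistanceMap",
  representation(distance = "numeric", meridian = "character"))

setValidity("DistanceMap", function(object) {
  if (any(object@distance < 0)) "distances must be non-negative" else TRUE
})

#' WedgeConfig: parameters of the wedge-ROI construction
#'
#' @slot halfWidth angular half-width of the wedge, deg (default 15).
#' @slot poolHalfWidth angular half-width of the iso-angle pooling band, deg
#'   (default 8): the boundary distance of each band is the mean distance of
#'   vertices whose pRF angle offset lies within `halfWidth +/-
#'   poolHalfWidth`.
#' @slot eccRange eccentricity range of the wedge, deg (default 1-8).
#' @slot nBands number of log-spaced eccentricity bands (default 10).
#' @slot depth depth label the areas refer to.
#' @export
setClass("WedgeConfig",
  representation(halfWidth = "numeric", poolHalfWidth = "numeric",
                 eccRange = "numeric", nBands = "integer",
                 depth = "character"))

setValidity("WedgeConfig", function(object) {
  msg <- character()
  if (object@halfWidth <= 0 || object@poolHalfWidth < 0)
    msg <- c(msg, "half-widths must be positive")
  if (object@nBands < 1L) msg <- c(msg, "nBands must be >= 1")
  if (diff(object@eccRange) <= 0)
    msg <- c(msg, "eccRange must be increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn WedgeConfig-class Constructor with the standard defaults.
#' @param halfWidth,poolHalfWidth,eccRange,nBands,depth see slots.
#' @export
wedgeConfig <- function(halfWidth = 15, poolHalfWidth = 8,
                        eccRange = c(1, 8), nBands = 10L,
                        depth = "midgray") {
  new("WedgeConfig", halfWidth = halfWidth, poolHalfWidth = poolHalfWidth,
      eccRange = eccRange, nBands = as.integer(nBands), depth = depth)
}

#' WedgeROIMask: the vertex set of one wedge-ROI
#'
#' @slot meridian meridian label.
#' @slot hemisphere hemisphere label.
#' @slot vertices integer vertex indices in the mask.
#' @slot boundaryDistance numeric, per-band iso-angle boundary distance
#'   (mm); `NA` for bands marked invalid (empty pool after widening).
#' @export
setClass("WedgeROIMask",
  representation(meridian = "character", hemisphere = "character",
                 vertices = "integer", boundaryDistance = "numeric"))

## Visual-field angle of a meridian as represented in a given hemisphere.
hemiMeridianAngle <- function(meridian, hemisphere) {
  switch(meridian,
    HM = if (hemisphere == "left") 0 else 180,
    UVM = 90, LVM = 270,
    stop("meridian must be 'HM', 'UVM' or 'LVM'"))
}

#' Find vertices tracing a meridian line on the cortex
#'
#' Automated surrogate for manually drawn meridian line-ROIs: selects
#' included vertices whose pRF polar angle lies within `angleTol` of the
#' meridian, then thins them to a path spanning the eccentricity range by
#' keeping, per log-eccentricity bin, the vertex with the smallest angular
#' offset.
#'
#' @param retinotopy a [RetinotopyMap-class] (inclusion-gated).
#' @param mesh the matching [CorticalMesh-class].
#' @param meridian `"HM"`, `"UVM"` or `"LVM"` (hemisphere-local; `"HM"`
#'   resolves to the hemifield served by the hemisphere).
#' @param angleTol angular tolerance, deg.
#' @param nBins number of eccentricity bins used for thinning.
#' @return Integer vector of vertex indices.
#' @export
meridianLineVertices <- function(retinotopy, mesh, meridian, angleTol = 2,
                                 nBins = 60) {
  target <- hemiMeridianAngle(meridian, hemisphere(mesh))
  off <- angularOffset(polarAngles(retinotopy), target)
  sel <- which(inclusionFlags(retinotopy) & off <= angleTol)
  if (length(sel) == 0)
    stop("no vertices within ", angleTol,
         " deg of the ", meridian, " meridian; increase angleTol")
  ecc <- eccentricities(retinotopy)[sel]
  edges <- exp(seq(log(max(min(ecc), 1e-6)), log(max(ecc)),
                   length.out = nBins + 1))
  bin <- findInterval(ecc, edges, rightmost.closed = TRUE)
  keep <- vapply(split(seq_along(sel), bin),
                 function(i) sel[i][which.min(off[sel[i]])], integer(1))
  sort(unname(keep))
}

#' Geodesic cortical distance map from seed vertices
#'
#' Multi-source shortest-path distance along mesh edges (edge weights are
#' Euclidean edge lengths in mm). Seed vertices have distance exactly 0;
#' vertices disconnected from every seed get `Inf`.
#'
#' @param mesh a [CorticalMesh-class].
#' @param seeds non-empty integer vector of seed vertex indices.
#' @param meridian label stored on the result.
#' @return A [DistanceMap-class].
#' @export
corticalDistanceMap <- function(mesh, seeds, meridian = "unspecified") {
  stopifnot(length(seeds) > 0)
  faces <- meshFaces(mesh)
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  edges <- unique(t(apply(edges, 1, sort)))
  v <- meshVertices(mesh)
  len <- sqrt(rowSums((v[edges[, 1], , drop = FALSE] -
                       v[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = len)
  d <- igraph::distances(g, v = seeds, to = seq_len(nVertices(mesh)))
  dist <- apply(d, 2, min)
  new("DistanceMap", distance = unname(dist), meridian = meridian)
}

#' Log-spaced eccentricity band edges
#'
#' @param eccMin,eccMax band range, deg (defaults 1 and 8).
#' @param nBands number of bands (default 10).
#' @return Numeric vector of `nBands + 1` geometrically spaced edges, first
#'   exactly `eccMin`, last exactly `eccMax`.
#' @examples
#' logSpacedBands()  # 11 edges, consecutive ratio 8^(1/10)
#' @export
logSpacedBands <- function(eccMin = 1, eccMax = 8, nBands = 10) {
  if (nBands < 1) stop("nBands must be >= 1")
  stopifnot(eccMin > 0, eccMax > eccMin)
  exp(seq(log(eccMin), log(eccMax), length.out = nBands + 1))
}

#' Cortical distance of the wedge boundary within one eccentricity band
#'
#' The boundary (iso-angle) distance is the mean geodesic distance of
#' included vertices whose pRF eccentricity falls in the band and whose
#' angular offset from the meridian lies within `boundaryAngle +/-
#' poolHalfWidth`. If the pool is empty it is widened once by +4 deg; if
#' still empty the band is invalid and `NA` is returned.
#'
#' @param band numeric `c(lo, hi)` eccentricity edges, deg.
#' @param dist a [DistanceMap-class] for the meridian.
#' @param retinotopy a [RetinotopyMap-class].
#' @param meridianAngleDeg visual-field angle of the meridian, deg.
#' @param boundaryAngle angular position of the wedge boundary, deg
#'   (default 15).
#' @param poolHalfWidth pooling half-width, deg (default 8).
#' @return Mean boundary distance in mm, or `NA_real_`.
#' @export
isoangleBoundaryDistance <- function(band, dist, retinotopy,
                                     meridianAngleDeg,
                                     boundaryAngle = 15, poolHalfWidth = 8) {
  off <- angularOffset(polarAngles(retinotopy), meridianAngleDeg)
  ecc <- eccentricities(retinotopy)
  inBand <- inclusionFlags(retinotopy) & ecc >= band[1] & ecc < band[2]
  for (hw in c(poolHalfWidth, poolHalfWidth + 4)) {
    pool <- inBand & off >= boundaryAngle - hw & off <= boundaryAngle + hw
    if (any(pool)) return(mean(dist@distance[pool]))
  }
  NA_real_
}

#' Build the wedge-ROI mask for one meridian in one hemisphere
#'
#' For each log-spaced eccentricity band, computes the iso-angle boundary
#' distance and selects included vertices whose pRF eccentricity lies in the
#' band and whose geodesic distance from the meridian is at most that
#' boundary; the per-band sub-wedges are unioned into the full mask. Bands
#' whose pool stays empty after widening are excluded (their boundary is
#' `NA`); if every band is invalid an error is raised.
#'
#' @param dist a [DistanceMap-class] seeded at the meridian line.
#' @param retinotopy a [RetinotopyMap-class].
#' @param mesh the [CorticalMesh-class] (for the hemisphere label).
#' @param meridian `"HM"`, `"UVM"` or `"LVM"`.
#' @param cfg a [WedgeConfig-class].
#' @return A [WedgeROIMask-class].
#' @export
buildWedgeMask <- function(dist, retinotopy, mesh, meridian,
                           cfg = wedgeConfig()) {
  target <- hemiMeridianAngle(meridian, hemisphere(mesh))
  edges <- logSpacedBands(cfg@eccRange[1], cfg@eccRange[2], cfg@nBands)
  ecc <- eccentricities(retinotopy)
  ok <- inclusionFlags(retinotopy)
  verts <- integer(0)
  bounds <- numeric(cfg@nBands)
  for (b in seq_len(cfg@nBands)) {
    band <- edges[b:(b + 1)]
    d <- isoangleBoundaryDistance(band, dist, retinotopy, target,
                                  cfg@halfWidth, cfg@poolHalfWidth)
    bounds[b] <- d
    if (is.na(d)) next
    hi <- if (b == cfg@nBands) ecc <= band[2] else ecc < band[2]
    verts <- c(verts, which(ok & ecc >= band[1] & hi &
                              dist@distance <= d))
  }
  if (all(is.na(bounds)))
    stop("all eccentricity bands invalid for the ", meridian, " wedge")
  new("WedgeROIMask", meridian = meridian, hemisphere = hemisphere(mesh),
      vertices = sort(unique(verts)), boundaryDistance = bounds)
}

#' Surface area of a wedge-ROI
#'
#' @param mask a [WedgeROIMask-class].
#' @param mesh the matching [CorticalMesh-class].
#' @return Sum of per-vertex surface areas over the mask, mm^2.
#' @export
wedgeSurfaceArea <- function(mask, mesh) {
  stopifnot(all(mask@vertices >= 1), all(mask@vertices <= nVertices(mesh)))
  sum(vertexAreas(mesh)[mask@vertices])
}

#' Combine per-hemisphere wedge areas into meridian totals
#'
#' The horizontal-meridian area sums the left- and right-hemisphere HM
#' wedges (one per visual hemifield); the upper and lower vertical meridian
#' areas each sum their two 15-deg hemifield halves; the full vertical
#' meridian is UVM + LVM.
#'
#' @param areas data.frame with columns `hemisphere` (`"left"`/`"right"`),
#'   `meridian` (`"HM"`, `"UVM"`, `"LVM"`) and `area` (mm^2).
#' @return Named numeric vector with `HM`, `UVM`, `LVM`, `VM`.
#' @export
combineMeridianAreas <- function(areas) {
  for (m in c("HM", "UVM", "LVM")) for (h in c("left", "right"))
    if (!any(areas$meridian == m & areas$hemisphere == h))
      stop("missing ", h, " hemisphere area for meridian ", m)
  tot <- function(m) sum(areas$area[areas$meridian == m])
  out <- c(HM = tot("HM"), UVM = tot("UVM"), LVM = tot("LVM"))
  c(out, VM = unname(out["UVM"] + out["LVM"]))
}

#' V1 surface area of a hemisphere up to an eccentricity limit
#'
#' @param mesh a [CorticalMesh-class].
#' @param retinotopy optional [RetinotopyMap-class]; defaults to the mesh's
#'   ground-truth retinotopy.
#' @param eccMax eccentricity limit, deg (default 8).
#' @return Summed vertex area, mm^2.
#' @export
v1TotalArea <- function(mesh, retinotopy = NULL, eccMax = 8) {
  ecc <- if (is.null(retinotopy)) eccentricities(mesh)
         else eccentricities(retinotopy)
  sum(vertexAreas(mesh)[ecc <= eccMax])
}

#' Measure wedge-ROI areas at all four locations on a pair of hemispheres
#'
#' Runs the full wedge-ROI algorithm (meridian line, distance map, per-band
#' iso-angle boundaries, mask, area) per hemisphere and meridian, and
#' returns both the per-location wedge areas (matching the contrast
#' sensitivity locations: the left/right visual field horizontal meridians
#' and the combined UVM/LVM wedges) and the meridian totals of
#' [combineMeridianAreas()].
#'
#' @param meshLeft,meshRight left and right hemisphere
#'   [CorticalMesh-class] objects.
#' @param retLeft,retRight matching [RetinotopyMap-class] objects (default:
#'   ground truth).
#' @param cfg a [WedgeConfig-class].
#' @param angleTol tolerance for the meridian line selection, deg.
#' @return List with `locations` (named vector `HM_left`, `HM_right`,
#'   `UVM`, `LVM` in mm^2), `combined` (from [combineMeridianAreas()]) and
#'   `perHemisphere` (the raw data.frame).
#' @export
wedgeAreasByMeridian <- function(meshLeft, meshRight,
                                 retLeft = groundTruthRetinotopy(meshLeft),
                                 retRight = groundTruthRetinotopy(meshRight),
                                 cfg = wedgeConfig(), angleTol = 3) {
  one <- function(mesh, ret, meridian) {
    seeds <- meridianLineVertices(ret, mesh, meridian, angleTol)
    dmap <- corticalDistanceMap(mesh, seeds, meridian)
    mask <- buildWedgeMask(dmap, ret, mesh, meridian, cfg)
    wedgeSurfaceArea(mask, mesh)
  }
  rows <- expand.grid(hemisphere = c("left", "right"),
                      meridian = c("HM", "UVM", "LVM"),
                      stringsAsFactors = FALSE)
  rows$area <- mapply(function(h, m)
    one(if (h == "left") meshLeft else meshRight,
        if (h == "left") retLeft else retRight, m),
    rows$hemisphere, rows$meridian)
  combined <- combineMeridianAreas(rows)
  locations <- c(
    # left hemisphere serves the right visual hemifield and vice versa
    HM_left = rows$area[rows$hemisphere == "right" & rows$meridian == "HM"],
    HM_right = rows$area[rows$hemisphere == "left" & rows$meridian == "HM"],
    UVM = unname(combined["UVM"]), LVM = unname(combined["LVM"]))
  list(locations = locations, combined = combined, perHemisphere = rows)
}
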