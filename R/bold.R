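#' @include AllClasses.R prf.R mesh.R
NULL

#' Simulate BOLD time series from a mesh's ground-truth retinotopy
#'
#' Each vertex's series is the pRF forward prediction
#' ([predictTimecourse()]) for its ground-truth (x, y, sigma), plus i.i.d.
#' Gaussian noise of SD `noiseSd`; units are percent signal change.
#' Reproducible under a fixed seed.
#'
#' @param mesh a [CorticalMesh-class].
#' @param aperture a [StimulusAperture-class] covering the mesh's mapped
#'   eccentricity range.
#' @param hrf HRF kernel at the frame duration (default canonical).
#' @param sigmaMap per-vertex pRF sigma, deg (recycled; default the linear
#'   size-eccentricity rule of [sigmaFromEccentricity()]). Must be positive.
#' @param noiseSd Gaussian noise SD (>= 0), percent signal units.
#' @param seed integer seed for the noise stream.
#' @return Numeric matrix, time x vertices.
#' @export
simulateBold <- function(mesh, aperture,
                         hrf = hrfDoubleGamma(dt = aperture@frameDuration),
                         sigmaMap = sigmaFromEccentricity(
                           eccentricities(mesh)),
                         noiseSd = 0, seed = 1L) {
  stopifnot(is(mesh, "CorticalMesh"), is(aperture, "StimulusAperture"),
            noiseSd >= 0)
  if (max(eccentricities(mesh)) > aperture@radius + 1e-9)
    stop("aperture grid does not cover the mesh's eccentricity range")
  n <- nVertices(mesh)
  sigmaMap <- rep_len(sigmaMap, n)
  if (any(sigmaMap <= 0))
    stop("sigmaMap must be positive at every vertex")

  ang <- polarAngles(mesh)
  ecc <- eccentricities(mesh)
  x <- ecc * cospi(ang / 180)
  y <- ecc * sinpi(ang / 180)

  px <- pixelCoords(aperture@gridSize, aperture@radius)
  lit <- px$x^2 + px$y^2 <= aperture@radius^2
  B <- convolveHRF(aperture@frames[, lit, drop = FALSE], hrf) *
       aperture@degPerPix^2
  G <- vapply(seq_len(n),
              function(v) gaussianField(x[v], y[v], sigmaMap[v],
                                        px$x[lit], px$y[lit]),
              numeric(sum(lit)))
  series <- B %*% G
  if (noiseSd > 0) {
    set.seed(childSeed(seed, "bold-noise"))
    series <- series + matrix(stats::rnorm(length(series), sd = noiseSd),
                              nrow = nrow(series))
  }
  series
}
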