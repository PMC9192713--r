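#' @include AllClasses.R utils.R
NULL

#' MagnificationModel: parametric areal cortical magnification
#'
#' Areal magnification (mm^2 of cortex per deg^2 of visual field) is
#' modelled as
#' \deqn{M(ecc, \theta) = M_0 \left(\frac{A}{ecc + e_2}\right)^2
#'   (1 + \alpha \cos 2\theta - \gamma \sin\theta)}
#' an inverse-linear eccentricity fall-off (the square of the classic linear
#' magnification m(ecc) = A / (ecc + e2)) with the minimal angular terms that
#' produce independent horizontal-vertical (alpha) and vertical-meridian
#' (gamma) asymmetries. alpha > 0 magnifies the horizontal meridian; gamma >
#' 0 magnifies the lower relative to the upper vertical meridian.
#'
#' @slot m0 dimensionless scale factor.
#' @slot A linear magnification scale, mm (default 17.3).
#' @slot e2 eccentricity at which magnification halves, deg (default 0.75).
#' @slot alpha HVA amplitude (dimensionless).
#' @slot gamma VMA amplitude (dimensionless).
#' @export
setClass("MagnificationModel",
  representation(m0 = "numeric", A = "numeric", e2 = "numeric",
                 alpha = "numeric", gamma = "numeric"))

setValidity("MagnificationModel", function(object) {
  msg <- character()
  if (object@m0 <= 0 || object@A <= 0 || object@e2 <= 0)
    msg <- c(msg, "m0, A and e2 must be positive")
  th <- seq(0, 360, by = 0.1)
  g <- angularModulation(object, th)
  if (min(g) <= 0) {
    bad <- th[which.min(g)]
    msg <- c(msg, sprintf(
      "angular modulation is non-positive at theta = %.1f deg; reduce alpha/gamma",
      bad))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MagnificationModel-class Constructor.
#' @param m0,A,e2,alpha,gamma see slots.
#' @export
magnificationModel <- function(m0 = 1, A = 17.3, e2 = 0.75,
                               alpha = 0, gamma = 0) {
  new("MagnificationModel", m0 = m0, A = A, e2 = e2,
      alpha = alpha, gamma = gamma)
}

angularModulation <- function(model, theta) {
  1 + model@alpha * cospi(2 * theta / 180) - model@gamma * sinpi(theta / 180)
}

#' Areal cortical magnification at a field position
#'
#' @param model a [MagnificationModel-class].
#' @param ecc eccentricity, deg.
#' @param theta polar angle, deg.
#' @return Areal magnification, mm^2 per deg^2 (vectorized).
#' @export
arealMagnification <- function(model, ecc, theta) {
  model@m0 * (model@A / (ecc + model@e2))^2 * angularModulation(model, theta)
}

#' Solve asymmetry amplitudes from target wedge-area indices
#'
#' Inverts the closed-form wedge integrals of the angular modulation to find
#' the amplitudes alpha and gamma at which +/-`halfWidth` deg wedge areas
#' centred on the meridians carry the requested HVA and VMA percentage
#' indices (difference over mean, times 100). The wedge mean of cos(2 theta)
#' over +/-15 deg is sin(30 deg) / (pi/6) = 0.9549.
#'
#' @param hva,vma target indices in percent.
#' @param halfWidth wedge half-width, deg (default 15).
#' @return List with `alpha` and `gamma`.
#' @export
solveAsymmetryAmplitudes <- function(hva, vma, halfWidth = 15) {
  w <- halfWidth * pi / 180
  kc <- sin(2 * w) / (2 * w)     # wedge mean of cos 2theta at the HM
  ks <- sin(w) / w               # |wedge mean of sin theta| at the VMs
  alpha <- hva / (200 * kc)
  gamma <- vma * (1 - kc * alpha) / (200 * ks)
  list(alpha = alpha, gamma = gamma)
}

## Closed-form eccentricity integral of M over [lo, hi]:
## integral of (A/(e+e2))^2 * e de.
eccIntegral <- function(model, lo, hi) {
  f <- function(e) log(e + model@e2) + model@e2 / (e + model@e2)
  model@A^2 * (f(hi) - f(lo))
}

## Closed-form angular integral of the modulation over [a, b] (deg),
## in radians.
angIntegral <- function(model, a, b) {
  ar <- a * pi / 180; br <- b * pi / 180
  (br - ar) +
    model@alpha * (sin(2 * br) - sin(2 * ar)) / 2 +
    model@gamma * (cos(br) - cos(ar))
}

#' Analytic surface area of a visual-field sector under the model
#'
#' Exact double integral of the areal magnification over a sector
#' (eccentricity range x polar-angle range), the oracle against which
#' mesh-measured wedge areas are compared.
#'
#' @param model a [MagnificationModel-class].
#' @param thetaRange polar-angle interval in deg, e.g. `c(-15, 15)`.
#' @param eccRange eccentricity interval in deg, e.g. `c(1, 8)`.
#' @return Area in mm^2.
#' @export
analyticSectorArea <- function(model, thetaRange, eccRange) {
  model@m0 * eccIntegral(model, eccRange[1], eccRange[2]) *
    angIntegral(model, thetaRange[1], thetaRange[2])
}

#' Generate a synthetic V1 hemisphere mesh
#'
#' Places a log-spaced-eccentricity by uniform-angle grid in the visual
#' hemifield served by the hemisphere (left hemisphere: right hemifield,
#' polar angles -90..90 deg; right hemisphere: 90..270 deg) and maps it to
#' flat cortical coordinates whose local areal expansion equals the
#' magnification model: the radial coordinate is the integral of the linear
#' magnification over eccentricity, and the tangential coordinate is scaled
#' by the local linear magnification times the integrated angular
#' modulation, so the mapping Jacobian is exactly `M(ecc, theta) * ecc`.
#' Triangle areas therefore converge to the analytic sector integrals as the
#' grid is refined. Per-vertex areas are one third of the incident triangle
#' areas. Depth (pial/white) is emulated by scaling cortical coordinates by
#' `sqrt(depthScale)` so all areas scale by `depthScale`.
#'
#' @param magnification a [MagnificationModel-class].
#' @param nEccRings number of eccentricity rings (>= 2).
#' @param nAngleSpokes number of angular spokes (>= 3).
#' @param eccRange eccentricity range, deg, within [0, 12.4]; the lower
#'   bound must be positive (log spacing).
#' @param depthScale areal scale factor relative to midgray (default 1).
#' @param hemisphere `"left"` or `"right"`.
#' @param depth depth label stored on the mesh.
#' @param jitterSD optional cortical-coordinate jitter SD in mm (default 0,
#'   a perfectly regular sheet); jitter is seeded.
#' @param seed integer RNG seed (used only for jitter).
#' @return A [CorticalMesh-class].
#' @examples
#' mesh <- makeSyntheticHemisphere(magnificationModel(), 40, 30)
#' sum(vertexAreas(mesh))
#' @export
makeSyntheticHemisphere <- function(magnification = magnificationModel(),
                                    nEccRings = 121, nAngleSpokes = 91,
                                    eccRange = c(0.2, 12.4),
                                    depthScale = 1,
                                    hemisphere = c("left", "right"),
                                    depth = "midgray",
                                    jitterSD = 0, seed = 1L) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(nEccRings >= 2, nAngleSpokes >= 3,
            eccRange[1] > 0, eccRange[2] <= 12.4,
            eccRange[1] < eccRange[2], depthScale > 0)

  thetaLim <- if (hemisphere == "left") c(-90, 90) else c(90, 270)
  ecc <- exp(seq(log(eccRange[1]), log(eccRange[2]),
                 length.out = nEccRings))
  theta <- seq(thetaLim[1], thetaLim[2], length.out = nAngleSpokes)

  g <- angularModulation(magnification, theta)
  if (min(g) <= 0)
    stop(sprintf(
      "non-positive magnification at (ecc = %.2f, theta = %.1f deg)",
      ecc[1], theta[which.min(g)]))

  s0 <- sqrt(magnification@m0 * depthScale)
  m <- function(e) magnification@A / (e + magnification@e2)
  ## radial cortical coordinate: integral of m(e) from ecc_min
  u <- s0 * magnification@A *
    log((ecc + magnification@e2) / (eccRange[1] + magnification@e2))
  ## tangential coordinate: m(ecc)*ecc times integrated angular modulation,
  ## centred on the hemifield midline to minimize shear
  thetaMid <- mean(thetaLim)
  G <- vapply(theta, function(t) angIntegral(magnification, thetaMid, t),
              numeric(1))
  grid <- expand.grid(r = seq_len(nEccRings), s = seq_len(nAngleSpokes))
  U <- u[grid$r]
  V <- s0 * m(ecc[grid$r]) * ecc[grid$r] * G[grid$s]
  vertices <- cbind(U, V)
  if (jitterSD > 0) {
    set.seed(childSeed(seed, "mesh-jitter"))
    vertices <- vertices + matrix(stats::rnorm(length(vertices),
                                               sd = jitterSD),
                                  ncol = 2)
  }

  ## faces: split each (ring, spoke) quad into two triangles
  id <- function(r, s) (s - 1L) * nEccRings + r
  r <- rep(seq_len(nEccRings - 1L), nAngleSpokes - 1L)
  s <- rep(seq_len(nAngleSpokes - 1L), each = nEccRings - 1L)
  faces <- rbind(
    cbind(id(r, s), id(r + 1L, s), id(r + 1L, s + 1L)),
    cbind(id(r, s), id(r + 1L, s + 1L), id(r, s + 1L))
  )
  storage.mode(faces) <- "integer"

  new("CorticalMesh",
      hemisphere = hemisphere, depth = depth,
      vertices = unname(vertices), faces = faces,
      vertexArea = vertexAreasFromFaces(vertices, faces),
      polarAngle = wrapAngle(theta[grid$s]),
      eccentricity = ecc[grid$r])
}
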