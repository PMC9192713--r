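## Shared fixtures, built once per test run.

ap64 <- makeBarAperture(gridSize = 64)
hrf1 <- hrfDoubleGamma(dt = 1)

## a small isotropic hemisphere pair for wedge tests
isoModel <- magnificationModel()
isoLeft <- makeSyntheticHemisphere(isoModel, 61, 45, hemisphere = "left")
isoRight <- makeSyntheticHemisphere(isoModel, 61, 45, hemisphere = "right")

## a regular flat grid mesh with a known geometry, for distance-map tests:
## nx x ny unit-spaced vertices, ecc/angle filled with valid placeholders
flatGridMesh <- function(nx, ny, spacing = 1) {
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  v <- cbind((grid$ix - 1) * spacing, (grid$iy - 1) * spacing)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  ix <- rep(seq_len(nx - 1), ny - 1)
  iy <- rep(seq_len(ny - 1), each = nx - 1)
  faces <- rbind(cbind(id(ix, iy), id(ix + 1, iy), id(ix + 1, iy + 1)),
                 cbind(id(ix, iy), id(ix + 1, iy + 1), id(ix, iy + 1)))
  storage.mode(faces) <- "integer"
  new("CorticalMesh", hemisphere = "left", depth = "midgray",
      vertices = v, faces = faces,
      vertexArea = cortmag:::vertexAreasFromFaces(v, faces),
      polarAngle = rep(0, nrow(v)),
      eccentricity = rep(1, nrow(v)))
}

## hand-built RetinotopyMap from explicit angle/ecc vectors (perfect fits)
fakeRetinotopy <- function(angle, ecc) {
  n <- length(angle)
  new("RetinotopyMap",
      x = ecc * cospi(angle / 180), y = ecc * sinpi(angle / 180),
      sigma = rep(1, n), gain = rep(1, n), r2 = rep(1, n),
      polarAngle = cortmag:::wrapAngle(angle), eccentricity = ecc,
      included = rep(TRUE, n))
}
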