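## Internal geometry / RNG helpers.

## Signed area is never needed; triangles may live in 2D (mm) coordinates.
triangleAreas <- function(vertices, faces) {
  if (nrow(faces) == 0) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c - a
  if (ncol(vertices) == 2L) {
    abs(ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]) / 2
  } else {
    cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
    cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
    cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
}

## Per-vertex area = one third of incident triangle areas; sums exactly to
## the total triangle area by construction.
vertexAreasFromFaces <- function(vertices, faces) {
  tri <- triangleAreas(vertices, faces)
  va <- numeric(nrow(vertices))
  for (k in 1:3) {
    acc <- tapply(tri / 3, faces[, k], sum)
    idx <- as.integer(names(acc))
    va[idx] <- va[idx] + as.numeric(acc)
  }
  va
}

## Wrap angles (deg) into [0, 360).
wrapAngle <- function(theta) ((theta %% 360) + 360) %% 360

## Smallest absolute angular difference (deg) in [0, 180].
angularOffset <- function(theta, ref) {
  d <- abs(wrapAngle(theta) - wrapAngle(ref))
  pmin(d, 360 - d)
}

## Deterministic per-component child seed from one root seed, so the mesh,
## cohort, BOLD-noise and trial streams are independently reproducible.
## Kept below 2^31 (R integers are 32-bit).
childSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

meridianAngle <- function(meridian) {
  switch(meridian,
    HM_right = 0, UVM = 90, HM_left = 180, LVM = 270,
    HM = 0,  # hemisphere-local horizontal; callers resolve left/right
    stop("unknown meridian label: ", meridian)
  )
}
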