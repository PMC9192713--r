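#' @include AllClasses.R
NULL

## Pixel-centre coordinates (deg) for the column-major pixel layout shared by
## the stimulus and the pRF forward model. Pixel p = (ix - 1) * gridSize + iy
## has x = xs[ix], y = ys[iy]; y increases upward.
pixelCoords <- function(gridSize, radius) {
  dpp <- 2 * radius / gridSize
  centres <- (seq_len(gridSize) - 0.5) * dpp - radius
  list(
    x = rep(centres, each = gridSize),
    y = rep(centres, times = gridSize),
    degPerPix = dpp
  )
}

#' Generate the retinotopic-mapping bar-aperture sequence
#'
#' Builds the binary contrast-aperture frame stack of a sweeping-bar
#' retinotopic mapping stimulus: a bar of width `barWidthFraction` times the
#' full stimulus extent sweeps across a circular aperture in
#' `nStepsPerSweep` equal steps of one TR each, for eight sweeps alternating
#' cardinal and diagonal directions. Cardinal sweeps traverse the full
#' diameter; for diagonal sweeps the second half of the steps are blank
#' (mean-luminance) frames. Generation is deterministic: the identical
#' sequence is produced on every call.
#'
#' @param radius aperture radius, deg of visual angle (default 12.4).
#' @param barWidthFraction bar width as a fraction of the full stimulus
#'   extent `2 * radius` (default 1/8, i.e. a 3.1 deg bar at the default
#'   radius).
#' @param nStepsPerSweep steps (frames) per sweep (default 24).
#' @param sweepDirections eight direction-of-travel angles in deg,
#'   alternating cardinal and diagonal. The default is
#'   `c(0, 45, 90, 135, 180, 225, 270, 315)`.
#' @param gridSize pixels per side of the square frame grid (>= 64).
#' @param tr frame duration in seconds (default 1).
#'
#' @return A [StimulusAperture-class].
#' @examples
#' ap <- makeBarAperture(gridSize = 64)
#' nFrames(ap)  # 192
#' @export
makeBarAperture <- function(radius = 12.4, barWidthFraction = 1 / 8,
                            nStepsPerSweep = 24,
                            sweepDirections = c(0, 45, 90, 135,
                                                180, 225, 270, 315),
                            gridSize = 128, tr = 1) {
  stopifnot(gridSize >= 64, nStepsPerSweep >= 2, radius > 0)
  if (length(sweepDirections) != 8)
    stop("sweepDirections must list eight sweep angles")
  cardinal <- angularOffset(sweepDirections, 0) %% 90 == 0
  if (!all(cardinal == rep(c(TRUE, FALSE), 4)))
    stop("sweepDirections must alternate cardinal and diagonal directions")

  px <- pixelCoords(gridSize, radius)
  barWidth <- barWidthFraction * 2 * radius
  if (barWidth < px$degPerPix)
    stop("bar width (", signif(barWidth, 3),
         " deg) is below one pixel; increase gridSize")
  inDisc <- px$x^2 + px$y^2 <= radius^2

  nFrames <- 8L * nStepsPerSweep
  frames <- matrix(0, nFrames, gridSize^2)
  schedule <- data.frame(
    sweep = rep(seq_len(8L), each = nStepsPerSweep),
    direction = rep(sweepDirections, each = nStepsPerSweep),
    step = rep(seq_len(nStepsPerSweep), 8L),
    blank = FALSE
  )
  stepSize <- 2 * radius / nStepsPerSweep
  for (f in seq_len(nFrames)) {
    dir <- schedule$direction[f]
    k <- schedule$step[f]
    if (!cardinal[schedule$sweep[f]] && k > nStepsPerSweep / 2) {
      schedule$blank[f] <- TRUE
      next
    }
    # bar centre position along the travel axis; sweeps start at the edge
    s <- -radius + (k - 0.5) * stepSize
    proj <- px$x * cospi(dir / 180) + px$y * sinpi(dir / 180)
    frames[f, inDisc & abs(proj - s) <= barWidth / 2] <- 1
  }

  new("StimulusAperture",
      frames = frames, gridSize = as.integer(gridSize),
      degPerPix = px$degPerPix, frameDuration = tr, radius = radius,
      schedule = schedule)
}

#' Visual-field area covered by one aperture frame
#'
#' @param aperture a [StimulusAperture-class].
#' @param frame 1-based frame index.
#' @return Covered area in deg^2 (number of lit pixels times pixel area).
#' @export
apertureMass <- function(aperture, frame) {
  stopifnot(is(aperture, "StimulusAperture"),
            frame >= 1, frame <= nFrames(aperture))
  sum(aperture@frames[frame, ] > 0) * aperture@degPerPix^2
}
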