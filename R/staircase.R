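#' @include AllClasses.R utils.R
NULL

#' Construct a Weibull 2AFC observer
#'
#' The psychometric function is
#' `p(c) = guess + (1 - guess - lapse) * (1 - exp(-(c / lambda)^slope))`,
#' with `lambda` solved per location so that `p(threshold) ==
#' staircaseConvergenceAccuracy(3)`, i.e. the threshold parameter is the
#' contrast at the 3-down-1-up convergence accuracy (about 79.4% correct).
#'
#' @param threshold threshold Michelson contrast c* per location; a single
#'   value is recycled over the four canonical locations.
#' @param slope Weibull slope (default 3.5, a typical contrast value).
#' @param guess guess rate (0.5 for 2AFC).
#' @param lapse lapse rate (default 0.01).
#' @return A [PsychometricObserver-class].
#' @export
psychometricObserver <- function(threshold = 0.02, slope = 3.5,
                                 guess = 0.5, lapse = 0.01) {
  th <- rep_len(threshold, 4)
  names(th) <- cortmagLocations()
  if (!is.null(names(threshold)) && length(threshold) == 4)
    th[names(threshold)] <- threshold
  new("PsychometricObserver", threshold = th, slope = slope,
      guess = guess, lapse = lapse)
}

#' Probability correct of a Weibull observer at a contrast
#'
#' @param observer a [PsychometricObserver-class].
#' @param location one of `cortmagLocations()`.
#' @param contrast Michelson contrast in (0, 1] (vectorized).
#' @return Probability correct in [guess, 1 - lapse].
#' @export
pCorrect <- function(observer, location, contrast) {
  stopifnot(all(contrast > 0), all(contrast <= 1))
  target <- staircaseConvergenceAccuracy(3)
  q <- (target - observer@guess) / (1 - observer@guess - observer@lapse)
  lambda <- observer@threshold[[location]] /
    (-log(1 - q))^(1 / observer@slope)
  observer@guess + (1 - observer@guess - observer@lapse) *
    (1 - exp(-(contrast / lambda)^observer@slope))
}

#' Simulate one 2AFC trial response
#'
#' Bernoulli draw from the observer's psychometric function; the caller
#' controls the RNG state (seed it before a sequence of trials).
#'
#' @inheritParams pCorrect
#' @return `TRUE` (correct) or `FALSE` (incorrect).
#' @export
respondTrial <- function(observer, location, contrast) {
  stats::runif(1) < pCorrect(observer, location, contrast)
}

#' StaircaseState: the running state of one 3-down-1-up PEST staircase
#'
#' Contrast is manipulated on a log10 scale. Three consecutive correct
#' responses step the contrast down by the current step size; any incorrect
#' response steps it up. Step size follows PEST rules: it halves at every
#' reversal and doubles on the third consecutive step in the same direction
#' (delayed to the fourth step when the run follows a reversal that was
#' preceded by a doubling), clamped to `[minStep, maxStep]`. Contrast is
#' clamped to `[minLevel, maxLevel]`.
#'
#' @slot level current Michelson contrast.
#' @slot step current step size, log10 units.
#' @slot nCorrect consecutive-correct counter.
#' @slot lastDirection -1 (down), +1 (up) or 0 (no step yet).
#' @slot sameDirCount consecutive steps taken in the current direction.
#' @slot doubledThisRun,doubledBeforeReversal bookkeeping for the
#'   post-reversal doubling delay.
#' @slot reversalLevels log10 contrast at each reversal, in order.
#' @slot levels,responses per-trial history (contrast shown, correctness).
#' @slot minStep,maxStep,minLevel,maxLevel bounds.
#' @export
setClass("StaircaseState",
  representation(
    level = "numeric", step = "numeric", nCorrect = "integer",
    lastDirection = "integer", sameDirCount = "integer",
    doubledThisRun = "logical", doubledBeforeReversal = "logical",
    reversalLevels = "numeric",
    levels = "numeric", responses = "logical",
    minStep = "numeric", maxStep = "numeric",
    minLevel = "numeric", maxLevel = "numeric"))

#' Initialize a staircase
#'
#' Defaults follow classical PEST practice: initial level 0.5 Michelson,
#' initial step 0.3 log10 units, step bounds [0.01, 0.6] log10 units,
#' contrast bounds [0.001, 1].
#'
#' @param initialLevel starting Michelson contrast.
#' @param initialStep starting step, log10 units.
#' @param minStep,maxStep step-size bounds, log10 units.
#' @param minLevel,maxLevel contrast bounds.
#' @return A [StaircaseState-class].
#' @export
staircaseInit <- function(initialLevel = 0.5, initialStep = 0.3,
                          minStep = 0.01, maxStep = 0.6,
                          minLevel = 0.001, maxLevel = 1) {
  new("StaircaseState",
      level = initialLevel, step = initialStep,
      nCorrect = 0L, lastDirection = 0L, sameDirCount = 0L,
      doubledThisRun = FALSE, doubledBeforeReversal = FALSE,
      reversalLevels = numeric(0),
      levels = numeric(0), responses = logical(0),
      minStep = minStep, maxStep = maxStep,
      minLevel = minLevel, maxLevel = maxLevel)
}

#' Advance a staircase by one response
#'
#' Applies the 3-down-1-up rule with PEST step-size adaptation (see
#' [StaircaseState-class]). The trial's contrast (the state's current
#' level) and the response are appended to the history.
#'
#' @param state a [StaircaseState-class].
#' @param correct logical response.
#' @return The updated [StaircaseState-class].
#' @export
staircaseUpdate <- function(state, correct) {
  state@levels <- c(state@levels, state@level)
  state@responses <- c(state@responses, correct)

  direction <- 0L
  if (correct) {
    state@nCorrect <- state@nCorrect + 1L
    if (state@nCorrect >= 3L) {
      direction <- -1L
      state@nCorrect <- 0L
    }
  } else {
    direction <- 1L
    state@nCorrect <- 0L
  }
  if (direction == 0L) return(state)

  if (state@lastDirection != 0L && direction != state@lastDirection) {
    # reversal: record level, halve the step
    state@reversalLevels <- c(state@reversalLevels, log10(state@level))
    state@step <- max(state@step / 2, state@minStep)
    state@doubledBeforeReversal <- state@doubledThisRun
    state@doubledThisRun <- FALSE
    state@sameDirCount <- 1L
  } else {
    state@sameDirCount <- state@sameDirCount + 1L
    needed <- 3L + as.integer(state@doubledBeforeReversal &&
                                !state@doubledThisRun)
    if (state@sameDirCount >= needed) {
      state@step <- min(state@step * 2, state@maxStep)
      state@doubledThisRun <- TRUE
    }
  }
  state@lastDirection <- direction

  newLog <- log10(state@level) + direction * state@step
  state@level <- min(max(10^newLog, state@minLevel), state@maxLevel)
  state
}

#' Threshold estimate from a finished staircase
#'
#' Mean of the log10 contrast levels at the last `nReversals` reversals,
#' falling back to the final level when fewer reversals occurred.
#'
#' @param state a [StaircaseState-class].
#' @param nReversals reversals to average (default 6).
#' @return Threshold Michelson contrast.
#' @export
staircaseThreshold <- function(state, nReversals = 6) {
  r <- state@reversalLevels
  if (length(r) >= nReversals)
    10^mean(utils::tail(r, nReversals))
  else
    state@level
}

#' Run one block of interleaved staircases
#'
#' One 200-trial block: four 3-down-1-up PEST staircases, one per location,
#' randomly interleaved across trials (50 trials per location by default),
#' run against a Weibull observer. Reproducible under the seed.
#'
#' @param observer a [PsychometricObserver-class].
#' @param nTrialsPerLocation scored trials per location (default 50).
#' @param seed integer seed.
#' @param blockIndex index stored in the result.
#' @param init a [StaircaseState-class] template for each staircase.
#' @return List with `threshold` (named per-location Michelson contrasts),
#'   `trials` (data.frame: trial, location, contrast, correct) and
#'   `blockIndex`.
#' @export
runBlock <- function(observer, nTrialsPerLocation = 50, seed = 1L,
                     blockIndex = 1L, init = staircaseInit()) {
  set.seed(childSeed(seed, paste0("block-", blockIndex)))
  locs <- cortmagLocations()
  order <- sample(rep(locs, nTrialsPerLocation))
  states <- stats::setNames(replicate(4, init, simplify = FALSE), locs)
  trials <- data.frame(trial = seq_along(order), location = order,
                       contrast = NA_real_, correct = NA)
  for (i in seq_along(order)) {
    loc <- order[i]
    ctr <- states[[loc]]@level
    ok <- respondTrial(observer, loc, ctr)
    states[[loc]] <- staircaseUpdate(states[[loc]], ok)
    trials$contrast[i] <- ctr
    trials$correct[i] <- ok
  }
  list(
    threshold = vapply(states, staircaseThreshold, numeric(1)),
    trials = trials,
    blockIndex = blockIndex
  )
}

#' Aggregate an observer's blocks into thresholds and sensitivities
#'
#' Thresholds at each location are averaged across the five independent
#' blocks; contrast sensitivity is the reciprocal of the across-block mean
#' threshold.
#'
#' @param blocks list of block results from [runBlock()].
#' @param nExpected expected number of blocks (default 5).
#' @param relax allow fewer than `nExpected` blocks (default FALSE).
#' @return List with named per-location `threshold` and `sensitivity`.
#' @export
aggregateObserver <- function(blocks, nExpected = 5, relax = FALSE) {
  if (length(blocks) != nExpected && !relax)
    stop("expected ", nExpected, " blocks, got ", length(blocks),
         " (set relax = TRUE to aggregate anyway)")
  th <- rowMeans(vapply(blocks, `[[`, numeric(4), "threshold"))
  list(threshold = th, sensitivity = 1 / th)
}

#' Convergence accuracy of an n-down-1-up staircase
#'
#' The staircase converges where the probabilities of a down-step and an
#' up-step balance: p^n = 0.5, so p = 0.5^(1/n). For the 3-down-1-up rule
#' this is 0.7937, i.e. 79.4% correct.
#'
#' @param nDown number of consecutive correct responses per down-step.
#' @return Proportion correct at convergence.
#' @examples
#' round(100 * staircaseConvergenceAccuracy(3), 1)  # 79.4
#' @export
staircaseConvergenceAccuracy <- function(nDown = 3) {
  0.5^(1 / nDown)
}

#' Measure staircase convergence accuracy by simulation
#'
#' Runs blocks of four randomly interleaved 3-down-1-up PEST staircases
#' against a Weibull observer and returns the mean accuracy over the
#' converged (second) half of each staircase's trials, in percent. With
#' enough trials this approaches the analytic balance point of
#' [staircaseConvergenceAccuracy()].
#'
#' @param nStaircases total staircases to simulate (multiple of 4).
#' @param nTrialsEach trials per staircase.
#' @param observer the simulated observer.
#' @param seed integer seed.
#' @return Mean percent correct over the converged portion.
#' @export
simulateConvergenceAccuracy <- function(nStaircases = 100,
                                        nTrialsEach = 200,
                                        observer = psychometricObserver(),
                                        seed = 1L) {
  nBlocks <- ceiling(nStaircases / 4)
  acc <- unlist(lapply(seq_len(nBlocks), function(b) {
    blk <- runBlock(observer, nTrialsPerLocation = nTrialsEach,
                    seed = childSeed(seed, paste0("conv-", b)),
                    blockIndex = b)
    vapply(split(blk$trials, blk$trials$location), function(tr) {
      half <- tr[tr$trial >= stats::median(tr$trial), ]
      mean(half$correct)
    }, numeric(1))
  }))
  100 * mean(acc[seq_len(nStaircases)])
}
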