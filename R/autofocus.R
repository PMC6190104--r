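# Two-phase autofocus: a coarse scan brackets the focal plane by detecting a
# rise-then-fall in the focus score, then a fine scan in the reverse
# direction pinpoints it.

#' Depth of field of the imaging optics
#'
#' Evaluates \eqn{DF = 10^{-3} \cdot 7/(A M) + \lambda/(2 A^2)} exactly as
#' stated, in millimetres (the first term carries the 10^-3 factor; the
#' wavelength must be supplied in millimetres). The depth of field
#' upper-bounds a useful fine focusing step: a step larger than DF can jump
#' clean over the in-focus region.
#'
#' @param optics an \linkS4class{OpticsParams}.
#' @return depth of field, millimetres.
#' @export
depthOfField <- function(optics) {
  validObject(optics)
  A <- optics@numericalAperture; M <- optics@magnification
  1e-3 * 7 / (A * M) + optics@wavelength / (2 * A^2)
}

#' Trend of three consecutive focus scores
#'
#' "increasing" iff s1 + eps < s2 and s2 + eps < s3; "decreasing" iff
#' s1 > s2 + eps and s2 > s3 + eps; otherwise "indeterminate". The tolerance
#' keeps flat, noise-jittered score runs from registering as a trend.
#'
#' @param scores numeric vector of three finite scores, in visit order.
#' @param epsilon absolute slack.
#' @return one of "increasing", "decreasing", "indeterminate".
#' @export
tripletTrend <- function(scores, epsilon = 0) {
  stopifnot(length(scores) == 3L, all(is.finite(scores)))
  if (scores[1] + epsilon < scores[2] && scores[2] + epsilon < scores[3])
    return("increasing")
  if (scores[1] > scores[2] + epsilon && scores[2] > scores[3] + epsilon)
    return("decreasing")
  "indeterminate"
}

#' Run the two-phase autofocus controller
#'
#' Coarse phase: step from `zStart` by `coarseStep`, scoring each capture
#' with the chosen criterion; once an increasing score trend has been seen,
#' the first decreasing trend signals that the stage has stepped past the
#' focal plane. If the very first trend is decreasing (the scan started
#' above focus), the direction is reversed once. Fine phase: from the coarse
#' stop position the stage moves back in steps of `fineStep`, stopping at
#' the first decreasing trend of fine-phase scores (bounded at three coarse
#' steps). The best-scoring position visited in either phase is returned.
#'
#' @param stage capture function `f(z)` returning an intensity matrix
#'   (see [simulatedStage()]); each call counts one evaluation.
#' @param config an \linkS4class{AutofocusConfig}.
#' @param measure focus criterion selector (see [computeFocusCurve()]).
#' @return an \linkS4class{AutofocusResult}. `converged` is FALSE when the
#'   range was exhausted without bracketing a peak or the evaluation budget
#'   ran out; `bestZ` is then still the best position visited.
#' @export
runAutofocus <- function(stage, config = AutofocusConfig(),
                         measure = "brenner") {
  validObject(config)
  scoreFun <- focusMeasureFun(measure)
  phase <- character(); zs <- numeric(); ss <- numeric()
  runMax <- -Inf
  capture <- function(z, ph) {
    s <- scoreFun(stage(z))
    phase[[length(phase) + 1L]] <<- ph
    zs[[length(zs) + 1L]] <<- z
    ss[[length(ss) + 1L]] <<- s
    runMax <<- max(runMax, s)
    s
  }
  budgetLeft <- function() length(zs) < config@maxEvaluations
  inRange <- function(z) z >= config@zMin - 1e-9 && z <= config@zMax + 1e-9

  dir <- 1
  reversed <- FALSE
  seenIncreasing <- FALSE
  bracketed <- FALSE
  z <- config@zStart
  coarse <- numeric()  # scores of the current coarse run
  while (inRange(z) && budgetLeft()) {
    coarse <- c(coarse, capture(z, "coarse"))
    n <- length(coarse)
    if (n >= 3L) {
      tr <- tripletTrend(coarse[(n - 2):n], config@epsilon * runMax)
      if (tr == "increasing") seenIncreasing <- TRUE
      if (tr == "decreasing") {
        if (seenIncreasing) { bracketed <- TRUE; break }
        if (!reversed && inRange(config@zStart - dir * config@coarseStep)) {
          # started above focus: reverse the scan once
          reversed <- TRUE
          dir <- -dir
          z <- config@zStart
          coarse <- numeric()
          next
        }
      }
    }
    z <- z + dir * config@coarseStep
  }

  fineConverged <- FALSE
  if (bracketed && budgetLeft()) {
    # move back from the coarse stop position in fine steps until the
    # fine-phase scores fall off their peak
    zStop <- z
    zLimit <- zStop - dir * (3 * config@coarseStep + 2 * config@fineStep)
    fz <- zStop - dir * config@fineStep
    fine <- numeric()
    while (inRange(fz) && budgetLeft() &&
           (dir > 0 && fz >= zLimit - 1e-9 || dir < 0 && fz <= zLimit + 1e-9)) {
      fine <- c(fine, capture(fz, "fine"))
      n <- length(fine)
      if (n >= 3L &&
          tripletTrend(fine[(n - 2):n], config@epsilon * runMax) == "decreasing") {
        fineConverged <- TRUE
        break
      }
      fz <- fz - dir * config@fineStep
    }
  }

  best <- which.max(ss)
  new("AutofocusResult", bestZ = zs[best], bestScore = ss[best],
      nEvaluations = length(zs),
      trace = data.frame(phase = phase, z = zs, score = ss),
      converged = bracketed && fineConverged)
}
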