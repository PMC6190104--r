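# Accessors and show methods. Slot access from user code should go through
# these, not @.

#' Accessors for pipeline result objects
#'
#' @param x an object of the documented class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
ellipseCenter <- function(x) {
  if (is(x, "EmbryoDetection")) x <- x@ellipse
  if (is.null(x)) return(c(NA_real_, NA_real_))
  stopifnot(is(x, "EllipseFit"))
  x@center
}

#' @rdname accessors
#' @export
majorAxisLength <- function(x) {
  if (is(x, "EmbryoDetection")) x <- x@ellipse
  if (is.null(x)) return(NA_real_)
  stopifnot(is(x, "EllipseFit"))
  x@majorAxis
}

#' @rdname accessors
#' @export
minorAxisLength <- function(x) {
  if (is(x, "EmbryoDetection")) x <- x@ellipse
  if (is.null(x)) return(NA_real_)
  stopifnot(is(x, "EllipseFit"))
  x@minorAxis
}

#' @rdname accessors
#' @export
ellipseAngle <- function(x) {
  if (is(x, "EmbryoDetection")) x <- x@ellipse
  if (is.null(x)) return(NA_real_)
  stopifnot(is(x, "EllipseFit"))
  x@angle
}

#' @rdname accessors
#' @export
isAccepted <- function(x) {
  stopifnot(is(x, "EmbryoDetection"))
  x@accepted
}

#' @rdname accessors
#' @export
thresholdParams <- function(x) {
  stopifnot(is(x, "EmbryoDetection"))
  c(b = x@b, param1 = x@param1)
}

#' @rdname accessors
#' @export
bestZ <- function(x) {
  stopifnot(is(x, "AutofocusResult"))
  x@bestZ
}

#' @rdname accessors
#' @export
nEvaluations <- function(x) {
  stopifnot(is(x, "AutofocusResult"))
  x@nEvaluations
}

#' @rdname accessors
#' @export
isConverged <- function(x) {
  stopifnot(is(x, "AutofocusResult"))
  x@converged
}

#' @rdname accessors
#' @export
focusTrace <- function(x) {
  stopifnot(is(x, "AutofocusResult"))
  x@trace
}

#' @rdname accessors
#' @export
tipXY <- function(x) {
  if (is(x, "MatchResult")) return(x@tipXY)
  if (is(x, "SceneTruth")) return(x@tipXY)
  stop("no tip coordinate in object of class ", class(x))
}

#' @rdname accessors
#' @export
matchOrigin <- function(x) {
  stopifnot(is(x, "MatchResult"))
  x@origin
}

#' @rdname accessors
#' @export
matchScore <- function(x) {
  stopifnot(is(x, "MatchResult"))
  x@score
}

#' @rdname accessors
#' @export
sceneTruth <- function(x) {
  stopifnot(is(x, "SyntheticScene"))
  x@truth
}

#' @rdname accessors
#' @export
sceneImage <- function(x) {
  stopifnot(is(x, "SyntheticScene"))
  x@image
}

#' @rdname accessors
#' @export
sceneParams <- function(x) {
  stopifnot(is(x, "SyntheticScene"))
  x@params
}

#' @rdname accessors
#' @export
suiteRecords <- function(x) {
  stopifnot(is(x, "ServoReport"))
  x@records
}

#' @rdname accessors
#' @export
successRate <- function(x) {
  stopifnot(is(x, "ServoReport"))
  x@successRate
}

#' @rdname accessors
#' @export
curvePositions <- function(x) {
  stopifnot(is(x, "FocusCurve"))
  x@z
}

#' @rdname accessors
#' @export
curveScores <- function(x) {
  stopifnot(is(x, "FocusCurve"))
  x@score
}

setMethod("show", "SceneParams", function(object) {
  cat("SceneParams:", object@imageWidth, "x", object@imageHeight, "px\n")
  if (object@embryoPresent)
    cat(sprintf("  embryo center (%.1f, %.1f), semi-axes (%.1f, %.1f), %.1f deg\n",
                object@embryoCenter[1], object@embryoCenter[2],
                object@embryoAxes[1], object@embryoAxes[2], object@embryoAngle))
  if (object@pipettePresent)
    cat(sprintf("  pipette tip (%.1f, %.1f) from %s edge\n",
                object@pipetteTip[1], object@pipetteTip[2],
                object@pipetteEntryEdge))
  cat(sprintf("  noise sigma %.2f, seed %d\n", object@noiseSigma, object@seed))
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene (", ncol(object@image), "x", nrow(object@image),
      "px, illumination:", object@illum@mode, ")\n", sep = " ")
  show(object@params)
})

setMethod("show", "FocusCurve", function(object) {
  cat(sprintf("FocusCurve [%s%s]: %d positions, z in [%g, %g] um\n",
              object@measure, if (object@normalized) ", normalized" else "",
              length(object@z), min(object@z), max(object@z)))
  if (length(object@score))
    cat(sprintf("  peak %.4g at z = %g um\n", max(object@score),
                object@z[which.max(object@score)]))
})

setMethod("show", "FocusStack", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1]]) else c(0L, 0L)
  cat(sprintf("FocusStack: %d frames (%d x %d px), z in [%g, %g] um\n",
              length(object@z), d[2], d[1],
              if (length(object@z)) min(object@z) else NA,
              if (length(object@z)) max(object@z) else NA))
})

setMethod("show", "AutofocusResult", function(object) {
  cat(sprintf("AutofocusResult: best z = %g um (score %.4g), %d evaluations, %s\n",
              object@bestZ, object@bestScore, object@nEvaluations,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf("EllipseFit: center (%.2f, %.2f), axes %.1f x %.1f px, %.1f deg\n",
              object@center[1], object@center[2], object@majorAxis,
              object@minorAxis, object@angle))
})

setMethod("show", "EmbryoDetection", function(object) {
  cat(sprintf("EmbryoDetection: %s after %d combinations",
              if (object@accepted) "ACCEPTED" else "not accepted",
              object@nCombinationsTried))
  if (!is.na(object@b))
    cat(sprintf(" [(b, param1) = (%g, %g)]", object@b, object@param1))
  cat("\n")
  if (!is.null(object@ellipse)) show(object@ellipse)
})

setMethod("show", "TipTemplate", function(object) {
  cat(sprintf("TipTemplate: %d x %d px patch, tip offsets (L = %g, H = %g)\n",
              nrow(object@patch), ncol(object@patch), object@offsetL,
              object@offsetH))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: origin (i, j) = (%g, %g), score %.4g, tip (%.1f, %.1f)\n",
              object@origin[1], object@origin[2], object@score,
              object@tipXY[1], object@tipXY[2]))
})

setMethod("show", "ServoReport", function(object) {
  cat(sprintf("ServoReport: %d scenes, %d successes (success rate %.1f%%)\n",
              object@nScenes, object@nSuccess, 100 * object@successRate))
})
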