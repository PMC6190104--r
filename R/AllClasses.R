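# S4 containers for the servoing pipeline. Images themselves are plain
# numeric matrices (rows = y, cols = x, 0-based pixel coordinates in the API);
# everything structured around them is a validated S4 object.

#' SceneParams: geometry and photometry of a synthetic micrograph
#'
#' Describes one bright-field scene: an elliptical embryo (dark chorion
#' membrane annulus around a slightly darker yolk disc on a bright
#' background), optionally a dark tapered injection pipette entering from an
#' image edge, plus sensor-noise level and the RNG seed that makes every
#' render bit-reproducible. All coordinates are 0-based pixels, x = column,
#' y = row; intensities are 8-bit levels.
#'
#' @slot imageWidth,imageHeight canvas size in pixels.
#' @slot embryoPresent render the embryo?
#' @slot embryoCenter (x, y) center of the chorion ellipse.
#' @slot embryoAxes (semi-major, semi-minor) of the chorion outer boundary.
#' @slot embryoAngle major-axis orientation, degrees counter-clockwise from x.
#' @slot membraneThickness radial thickness of the dark membrane annulus, px.
#' @slot membraneIntensity,yolkIntensity,backgroundIntensity 8-bit levels;
#'   the membrane must render darker than the background.
#' @slot pipettePresent render the pipette?
#' @slot pipetteTip (x, y) of the needle tip.
#' @slot pipetteEntryEdge one of "left", "right", "top", "bottom".
#' @slot pipetteTipWidth,pipetteBaseWidth needle width at the tip and at the
#'   fully tapered shank, px; the taper widens at a fixed slope so the
#'   near-tip shape is identical across scenes.
#' @slot pipetteIntensity 8-bit level of the needle.
#' @slot noiseSigma additive Gaussian sensor-noise standard deviation.
#' @slot seed integer RNG seed.
#' @export
setClass("SceneParams", representation(
  imageWidth = "integer", imageHeight = "integer",
  embryoPresent = "logical",
  embryoCenter = "numeric", embryoAxes = "numeric", embryoAngle = "numeric",
  membraneThickness = "numeric",
  membraneIntensity = "numeric", yolkIntensity = "numeric",
  backgroundIntensity = "numeric",
  pipettePresent = "logical", pipetteTip = "numeric",
  pipetteEntryEdge = "character",
  pipetteTipWidth = "numeric", pipetteBaseWidth = "numeric",
  pipetteIntensity = "numeric",
  noiseSigma = "numeric", seed = "integer"))

setValidity("SceneParams", function(object) {
  msg <- character()
  w <- object@imageWidth; h <- object@imageHeight
  if (w < 16L || h < 16L) msg <- c(msg, "image must be at least 16 x 16")
  if (object@embryoPresent) {
    c0 <- object@embryoCenter; ax <- object@embryoAxes
    if (ax[1] < ax[2]) msg <- c(msg, "embryoAxes must be (semi-major >= semi-minor)")
    r <- max(ax)
    if (c0[1] - r < 0 || c0[1] + r > w - 1 || c0[2] - r < 0 || c0[2] + r > h - 1)
      msg <- c(msg, "embryo ellipse must lie fully inside the image")
    if (object@membraneIntensity >= object@backgroundIntensity)
      msg <- c(msg, "membraneIntensity must be below backgroundIntensity")
  }
  if (object@pipettePresent) {
    tp <- object@pipetteTip
    if (tp[1] < 0 || tp[1] > w - 1 || tp[2] < 0 || tp[2] > h - 1)
      msg <- c(msg, "pipetteTip must lie inside the image")
    if (!object@pipetteEntryEdge %in% c("left", "right", "top", "bottom"))
      msg <- c(msg, "pipetteEntryEdge must be left/right/top/bottom")
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SceneParams constructor with defaults emulating a 4x
#'   bright-field view of a chorionated zebrafish embryo.
#' @param imageWidth,imageHeight,embryoPresent,embryoCenter,embryoAxes,embryoAngle,membraneThickness,membraneIntensity,yolkIntensity,backgroundIntensity,pipettePresent,pipetteTip,pipetteEntryEdge,pipetteTipWidth,pipetteBaseWidth,pipetteIntensity,noiseSigma,seed see slots.
#' @export
SceneParams <- function(imageWidth = 512L, imageHeight = 512L,
                        embryoPresent = TRUE,
                        embryoCenter = c(250, 260), embryoAxes = c(150, 128),
                        embryoAngle = 15, membraneThickness = 10,
                        membraneIntensity = 80, yolkIntensity = 150,
                        backgroundIntensity = 200,
                        pipettePresent = TRUE, pipetteTip = c(430, 180),
                        pipetteEntryEdge = "right",
                        pipetteTipWidth = 8, pipetteBaseWidth = 44,
                        pipetteIntensity = 40,
                        noiseSigma = 2, seed = 1L) {
  new("SceneParams",
      imageWidth = as.integer(imageWidth), imageHeight = as.integer(imageHeight),
      embryoPresent = embryoPresent,
      embryoCenter = as.numeric(embryoCenter), embryoAxes = as.numeric(embryoAxes),
      embryoAngle = as.numeric(embryoAngle),
      membraneThickness = as.numeric(membraneThickness),
      membraneIntensity = as.numeric(membraneIntensity),
      yolkIntensity = as.numeric(yolkIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      pipettePresent = pipettePresent, pipetteTip = as.numeric(pipetteTip),
      pipetteEntryEdge = pipetteEntryEdge,
      pipetteTipWidth = as.numeric(pipetteTipWidth),
      pipetteBaseWidth = as.numeric(pipetteBaseWidth),
      pipetteIntensity = as.numeric(pipetteIntensity),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' IlluminationField: multiplicative uneven-illumination model
#'
#' A smooth per-pixel gain plus an additive offset emulating shadows or a
#' tilted light source. `mode = "none"` is the identity; `"linear"`
#' interpolates the four corner gains bilinearly; `"radial"` interpolates
#' from `gains[1]` at the image center to `gains[3]` at the border.
#'
#' @slot mode "none", "linear" or "radial".
#' @slot gains four positive corner gains, ordered top-left, top-right,
#'   bottom-left, bottom-right.
#' @slot offset additive intensity offset.
#' @export
setClass("IlluminationField", representation(
  mode = "character", gains = "numeric", offset = "numeric"))

setValidity("IlluminationField", function(object) {
  msg <- character()
  if (!object@mode %in% c("none", "linear", "radial"))
    msg <- c(msg, "mode must be none/linear/radial")
  if (length(object@gains) != 4L) msg <- c(msg, "gains must have length 4")
  if (any(object@gains <= 0)) msg <- c(msg, "all gains must be > 0")
  if (object@mode == "none" && (any(object@gains != 1) || object@offset != 0))
    msg <- c(msg, "mode 'none' requires unit gains and zero offset")
  if (length(msg)) msg else TRUE
})

#' @describeIn IlluminationField constructor.
#' @param mode,gains,offset see slots.
#' @export
IlluminationField <- function(mode = "none",
                              gains = c(1, 1, 1, 1), offset = 0) {
  new("IlluminationField", mode = mode, gains = as.numeric(gains),
      offset = as.numeric(offset))
}

#' DefocusModel: blur as a function of stage position
#'
#' Defocus is modeled as an isotropic Gaussian point-spread function whose
#' standard deviation grows linearly with distance from the focal plane:
#' sigma(z) = sigmaAtFocus + blurSlope * |z - focalZ|. This yields the
#' unimodal focus curves a real through-focus stack produces.
#'
#' @slot focalZ focal-plane stage position, micrometres.
#' @slot sigmaAtFocus residual blur at best focus, pixels (>= 0).
#' @slot blurSlope blur growth, pixels per micrometre of defocus.
#' @export
setClass("DefocusModel", representation(
  focalZ = "numeric", sigmaAtFocus = "numeric", blurSlope = "numeric"))

setValidity("DefocusModel", function(object) {
  if (object@sigmaAtFocus < 0) return("sigmaAtFocus must be >= 0")
  if (object@blurSlope <= 0) return("blurSlope must be > 0")
  TRUE
})

#' @describeIn DefocusModel constructor.
#' @param focalZ,sigmaAtFocus,blurSlope see slots.
#' @export
DefocusModel <- function(focalZ = 3000, sigmaAtFocus = 0.5, blurSlope = 0.012) {
  new("DefocusModel", focalZ = as.numeric(focalZ),
      sigmaAtFocus = as.numeric(sigmaAtFocus), blurSlope = as.numeric(blurSlope))
}

#' @describeIn DefocusModel blur sigma (pixels) at stage position z.
#' @param model a \linkS4class{DefocusModel}.
#' @param z stage position(s), micrometres.
#' @export
blurSigma <- function(model, z) {
  model@sigmaAtFocus + model@blurSlope * abs(z - model@focalZ)
}

#' SceneTruth: ground truth emitted with every rendered scene
#'
#' @slot embryoCenter,embryoAxes,embryoAngle true chorion ellipse (px/deg).
#' @slot focalZ true focal plane, micrometres (NA for single renders).
#' @slot tipXY true needle-tip pixel (NA if no pipette).
#' @slot illumMode illumination mode used.
#' @slot seed RNG seed used.
#' @export
setClass("SceneTruth", representation(
  embryoCenter = "numeric", embryoAxes = "numeric", embryoAngle = "numeric",
  focalZ = "numeric", tipXY = "numeric", illumMode = "character",
  seed = "integer"))

#' SyntheticScene: a rendered scene bundled with its generating model
#'
#' Carries the in-focus render plus everything needed to re-render the scene
#' at any stage position or with the pipette translated: the
#' \linkS4class{SceneParams}, \linkS4class{IlluminationField} and
#' \linkS4class{DefocusModel}, and the \linkS4class{SceneTruth}.
#'
#' @slot image in-focus render (intensity matrix).
#' @slot params,illum,model generating objects.
#' @slot truth ground-truth record.
#' @export
setClass("SyntheticScene", representation(
  image = "matrix", params = "SceneParams", illum = "IlluminationField",
  model = "DefocusModel", truth = "SceneTruth"))

#' FocusCurve: sharpness score against stage position
#'
#' @slot z stage positions, micrometres, strictly increasing.
#' @slot score nonnegative focus scores, one per position.
#' @slot normalized TRUE if scores were divided by their maximum.
#' @slot measure which criterion produced the scores.
#' @export
setClass("FocusCurve", representation(
  z = "numeric", score = "numeric", normalized = "logical",
  measure = "character"))

setValidity("FocusCurve", function(object) {
  msg <- character()
  if (length(object@z) != length(object@score))
    msg <- c(msg, "z and score must have equal length")
  if (length(object@z) > 1 && any(diff(object@z) <= 0))
    msg <- c(msg, "z must be strictly increasing")
  if (any(object@score < 0)) msg <- c(msg, "scores must be nonnegative")
  if (isTRUE(object@normalized) && length(object@score) &&
      abs(max(object@score) - 1) > 1e-12)
    msg <- c(msg, "normalized curve must have max score 1")
  if (length(msg)) msg else TRUE
})

#' FocusStack: an ordered through-focus image stack
#'
#' @slot z strictly increasing stage positions, micrometres.
#' @slot frames list of intensity matrices, all the same size.
#' @export
setClass("FocusStack", representation(z = "numeric", frames = "list"))

setValidity("FocusStack", function(object) {
  msg <- character()
  if (length(object@z) != length(object@frames))
    msg <- c(msg, "one frame per z position required")
  if (length(object@z) > 1 && any(diff(object@z) <= 0))
    msg <- c(msg, "z must be strictly increasing")
  if (length(object@frames)) {
    d <- dim(object@frames[[1]])
    if (!all(vapply(object@frames, function(f) identical(dim(f), d), logical(1))))
      msg <- c(msg, "all frames must share dimensions")
  }
  if (length(msg)) msg else TRUE
})

#' OpticsParams: the quantities entering the depth-of-field formula
#'
#' @slot numericalAperture objective numerical aperture A (> 0).
#' @slot magnification total magnification M (> 0).
#' @slot wavelength illumination wavelength, millimetres (>= 0).
#' @export
setClass("OpticsParams", representation(
  numericalAperture = "numeric", magnification = "numeric",
  wavelength = "numeric"))

setValidity("OpticsParams", function(object) {
  if (object@numericalAperture <= 0) return("numericalAperture must be > 0")
  if (object@magnification <= 0) return("magnification must be > 0")
  if (object@wavelength < 0) return("wavelength must be >= 0")
  TRUE
})

#' @describeIn OpticsParams constructor; defaults match a 4x / NA 0.1
#'   objective with a 10x eyepiece and green illumination.
#' @param numericalAperture,magnification,wavelength see slots (wavelength in mm).
#' @export
OpticsParams <- function(numericalAperture = 0.1, magnification = 40,
                         wavelength = 550e-6) {
  new("OpticsParams", numericalAperture = as.numeric(numericalAperture),
      magnification = as.numeric(magnification),
      wavelength = as.numeric(wavelength))
}

#' AutofocusConfig: the two-phase search parameters
#'
#' @slot coarseStep,fineStep step lengths, micrometres (fine < coarse).
#' @slot zMin,zMax stage travel limits, micrometres.
#' @slot zStart starting position of the coarse scan (defaults to zMin).
#' @slot epsilon relative trend tolerance: score triplets are compared with a
#'   slack of epsilon times the running maximum score. Far from focus the
#'   score is dominated by sensor noise and jitters by about a percent of
#'   the running maximum while genuine near-peak steps are tens of percent;
#'   the default 0.02 separates the two scales.
#' @slot maxEvaluations hard cap on stage captures.
#' @export
setClass("AutofocusConfig", representation(
  coarseStep = "numeric", fineStep = "numeric", zMin = "numeric",
  zMax = "numeric", zStart = "numeric", epsilon = "numeric",
  maxEvaluations = "integer"))

setValidity("AutofocusConfig", function(object) {
  msg <- character()
  if (!(object@fineStep > 0 && object@fineStep < object@coarseStep))
    msg <- c(msg, "need 0 < fineStep < coarseStep")
  if (object@zMax - object@zMin < 3 * object@coarseStep)
    msg <- c(msg, "z range must span at least 3 coarse steps")
  if (object@zStart < object@zMin || object@zStart > object@zMax)
    msg <- c(msg, "zStart must lie in [zMin, zMax]")
  if (object@maxEvaluations < 5L) msg <- c(msg, "maxEvaluations too small")
  if (length(msg)) msg else TRUE
})

#' @describeIn AutofocusConfig constructor with the 200/50 micrometre
#'   coarse/fine step lengths.
#' @param coarseStep,fineStep,zMin,zMax,zStart,epsilon,maxEvaluations see slots.
#' @export
AutofocusConfig <- function(coarseStep = 200, fineStep = 50,
                            zMin = 0, zMax = 6000, zStart = zMin,
                            epsilon = 0.02, maxEvaluations = 500L) {
  new("AutofocusConfig", coarseStep = as.numeric(coarseStep),
      fineStep = as.numeric(fineStep), zMin = as.numeric(zMin),
      zMax = as.numeric(zMax), zStart = as.numeric(zStart),
      epsilon = as.numeric(epsilon),
      maxEvaluations = as.integer(maxEvaluations))
}

#' AutofocusResult: outcome of a two-phase focus search
#'
#' @slot bestZ stage position of the best score visited, micrometres.
#' @slot bestScore the best focus score.
#' @slot nEvaluations number of stage captures used.
#' @slot trace data.frame (phase, z, score) in visit order.
#' @slot converged TRUE if a rise-then-fall peak was bracketed and refined.
#' @export
setClass("AutofocusResult", representation(
  bestZ = "numeric", bestScore = "numeric", nEvaluations = "integer",
  trace = "data.frame", converged = "logical"))

#' EllipseFit: a fitted ellipse
#'
#' @slot center (cx, cy), 0-based pixels (sub-pixel).
#' @slot majorAxis,minorAxis full axis lengths, pixels (major >= minor).
#' @slot angle major-axis orientation, degrees counter-clockwise from x.
#' @export
setClass("EllipseFit", representation(
  center = "numeric", majorAxis = "numeric", minorAxis = "numeric",
  angle = "numeric"))

setValidity("EllipseFit", function(object) {
  if (!(object@majorAxis >= object@minorAxis && object@minorAxis > 0))
    return("need majorAxis >= minorAxis > 0")
  TRUE
})

setClassUnion("EllipseFitOrNULL", c("EllipseFit", "NULL"))

#' DetectionConfig: the (b, param1) circulation and acceptance band
#'
#' @slot bRange ascending odd block sizes to try.
#' @slot param1Range ascending intensity offsets to try (inner loop).
#' @slot weighting "gaussian" or "uniform" local mean.
#' @slot LMin,LMax acceptance band for the fitted major-axis length, pixels;
#'   NA means derive \[0.45, 0.95\] x the shorter image dimension at call time.
#' @slot minContourPoints smallest contour worth fitting (>= 5).
#' @export
setClass("DetectionConfig", representation(
  bRange = "integer", param1Range = "numeric", weighting = "character",
  LMin = "numeric", LMax = "numeric", minContourPoints = "integer"))

setValidity("DetectionConfig", function(object) {
  msg <- character()
  if (any(object@bRange %% 2L == 0L) || any(object@bRange < 3L))
    msg <- c(msg, "bRange must contain odd values >= 3")
  if (is.unsorted(object@bRange, strictly = TRUE))
    msg <- c(msg, "bRange must be strictly ascending")
  if (!object@weighting %in% c("gaussian", "uniform"))
    msg <- c(msg, "weighting must be gaussian or uniform")
  if (!is.na(object@LMin) && !is.na(object@LMax) && object@LMin >= object@LMax)
    msg <- c(msg, "need LMin < LMax")
  if (object@minContourPoints < 5L) msg <- c(msg, "minContourPoints must be >= 5")
  if (length(msg)) msg else TRUE
})

#' @describeIn DetectionConfig constructor; block sizes cover the range the
#'   circulation typically needs at a 512 px field.
#' @param bRange,param1Range,weighting,LMin,LMax,minContourPoints see slots.
#' @export
DetectionConfig <- function(bRange = seq(7L, 51L, by = 4L),
                            param1Range = c(5, 7),
                            weighting = "gaussian",
                            LMin = NA_real_, LMax = NA_real_,
                            minContourPoints = 50L) {
  new("DetectionConfig", bRange = as.integer(bRange),
      param1Range = as.numeric(param1Range), weighting = weighting,
      LMin = as.numeric(LMin), LMax = as.numeric(LMax),
      minContourPoints = as.integer(minContourPoints))
}

#' EmbryoDetection: result of the adaptive-threshold circulation
#'
#' @slot ellipse the fitted ellipse (NULL when no contour fit succeeded).
#' @slot b,param1 the adaptive-threshold parameters selected (NA if none).
#' @slot accepted TRUE when the major axis fell inside the acceptance band.
#' @slot nCombinationsTried (b, param1) pairs evaluated.
#' @export
setClass("EmbryoDetection", representation(
  ellipse = "EllipseFitOrNULL", b = "numeric", param1 = "numeric",
  accepted = "logical", nCombinationsTried = "integer"))

#' TipTemplate: a matching template with tip offsets
#'
#' The needle tip rarely sits at a template's origin, so the template stores
#' the pixel displacement from its top-left corner to the tip: a match at
#' origin (i, j) (row, col) puts the tip at x = j + offsetL, y = i + offsetH.
#'
#' @slot patch m x n intensity matrix.
#' @slot offsetL horizontal (column) displacement to the tip, pixels.
#' @slot offsetH vertical (row) displacement to the tip, pixels.
#' @export
setClass("TipTemplate", representation(
  patch = "matrix", offsetL = "numeric", offsetH = "numeric"))

setValidity("TipTemplate", function(object) {
  msg <- character()
  if (object@offsetL < 0 || object@offsetL > ncol(object@patch))
    msg <- c(msg, "offsetL must lie within the template width")
  if (object@offsetH < 0 || object@offsetH > nrow(object@patch))
    msg <- c(msg, "offsetH must lie within the template height")
  if (length(msg)) msg else TRUE
})

#' @describeIn TipTemplate constructor.
#' @param patch,offsetL,offsetH see slots.
#' @export
TipTemplate <- function(patch, offsetL, offsetH) {
  new("TipTemplate", patch = patch, offsetL = as.numeric(offsetL),
      offsetH = as.numeric(offsetH))
}

#' MatchResult: where a template matched and where that puts the tip
#'
#' @slot origin (i, j) = (row, col) of the matched window's top-left pixel,
#'   0-based.
#' @slot score the match measure at the origin.
#' @slot tipXY (x, y) = origin + template tip offsets, 0-based pixels.
#' @export
setClass("MatchResult", representation(
  origin = "numeric", score = "numeric", tipXY = "numeric"))

#' ServoConfig: everything the end-to-end injection pipeline needs
#'
#' @slot autofocus an \linkS4class{AutofocusConfig}.
#' @slot detection a \linkS4class{DetectionConfig}.
#' @slot template the \linkS4class{TipTemplate} used for tip localization.
#' @slot successTolerance final tip-to-center distance, pixels, counted as a
#'   successful injection (default 10 px, about half a 20 micrometre tip at
#'   the emulated magnification).
#' @slot tipScoreMin minimum normalized match quality (cosine between the
#'   template and the matched window, in \[0, 1\]) for the tip stage to count
#'   as found. A flat background window scores about 0.90 against the
#'   default template and windows of unrelated structure stay below about
#'   0.97, while genuine pipette matches exceed 0.99; the default 0.975
#'   sits between those scales.
#' @export
setClass("ServoConfig", representation(
  autofocus = "AutofocusConfig", detection = "DetectionConfig",
  template = "TipTemplate", successTolerance = "numeric",
  tipScoreMin = "numeric"))

setValidity("ServoConfig", function(object) {
  if (object@successTolerance <= 0) return("successTolerance must be > 0")
  if (object@tipScoreMin < 0 || object@tipScoreMin > 1)
    return("tipScoreMin must lie in [0, 1]")
  TRUE
})

#' ServoReport: per-scene records and suite summary
#'
#' @slot records one row per scene: autofocus outcome, detection outcome,
#'   tip location, displacement, final error, success flag.
#' @slot nScenes,nSuccess,successRate suite summary.
#' @export
setClass("ServoReport", representation(
  records = "data.frame", nScenes = "integer", nSuccess = "integer",
  successRate = "numeric"))
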