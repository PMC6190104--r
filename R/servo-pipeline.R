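# End-to-end simulated injection: autofocus -> embryo detection -> tip
# localization -> displacement -> simulated pipette move -> verification.

#' Pixel displacement that moves the tip onto the embryo center
#'
#' @param center (x, y) embryo center, pixels.
#' @param tip (x, y) needle tip, pixels.
#' @return (dx, dy) = center - tip.
#' @export
computeDisplacement <- function(center, tip) {
  stopifnot(length(center) == 2L, length(tip) == 2L)
  c(dx = center[[1]] - tip[[1]], dy = center[[2]] - tip[[2]])
}

#' Assemble a ServoConfig
#'
#' @param autofocus an \linkS4class{AutofocusConfig}.
#' @param detection a \linkS4class{DetectionConfig}.
#' @param template a \linkS4class{TipTemplate}.
#' @param successTolerance final tip-to-center distance (px) counted as a
#'   successful injection.
#' @param tipScoreMin minimum normalized match quality in \[0, 1\] for the
#'   tip stage to count as found.
#' @return a \linkS4class{ServoConfig}.
#' @export
ServoConfig <- function(autofocus = AutofocusConfig(),
                        detection = DetectionConfig(),
                        template = defaultTipTemplate(),
                        successTolerance = 10, tipScoreMin = 0.975) {
  new("ServoConfig", autofocus = autofocus, detection = detection,
      template = template, successTolerance = as.numeric(successTolerance),
      tipScoreMin = as.numeric(tipScoreMin))
}

# Normalized match quality in [0, 1]: the matched window's cosine against
# the template. 1 means the window is proportional to the template.
matchQuality <- function(match, tpl) {
  match@score / sqrt(sum(tpl@patch^2))
}

#' Run one simulated injection sequence
#'
#' Executes the full servo procedure on one scene: autofocus the simulated
#' stage, detect the embryo on the in-focus capture, locate the pipette
#' tip, compute the (dx, dy) displacement from tip to embryo center, apply
#' it by re-rendering the scene with the pipette translated, re-localize
#' the tip and measure the residual tip-to-center distance. Stage failures
#' are recorded, never raised; the axial penetration and deposit steps of a
#' physical injection are recorded as no-op events since no mechanics are
#' modeled.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param config a \linkS4class{ServoConfig}.
#' @param runAutofocusStage if FALSE, skip the focus search and image at
#'   the scene's true focal plane.
#' @return one-row data.frame: autofocus outcome, detection outcome
#'   (center, axes, b, param1), tip location, displacement, final error and
#'   success flag.
#' @export
runInjectionSequence <- function(scene, config = ServoConfig(),
                                 runAutofocusStage = TRUE) {
  stopifnot(is(scene, "SyntheticScene"))
  validObject(config)
  rec <- data.frame(
    autofocusConverged = NA, bestZ = NA_real_, autofocusEvaluations = NA_integer_,
    detectionAccepted = FALSE, b = NA_real_, param1 = NA_real_,
    centerX = NA_real_, centerY = NA_real_,
    majorAxis = NA_real_, minorAxis = NA_real_,
    tipFound = FALSE, tipX = NA_real_, tipY = NA_real_,
    dx = NA_real_, dy = NA_real_, finalError = NA_real_, success = FALSE)

  stage <- simulatedStage(scene)
  if (runAutofocusStage) {
    af <- runAutofocus(stage, config@autofocus, "brenner")
    rec$autofocusConverged <- af@converged
    rec$bestZ <- af@bestZ
    rec$autofocusEvaluations <- af@nEvaluations
    if (!af@converged) return(rec)
    img <- stage(af@bestZ)
  } else {
    rec$autofocusConverged <- TRUE
    rec$bestZ <- scene@model@focalZ
    img <- stage(scene@model@focalZ)
  }

  det <- detectEmbryo(img, config@detection)
  rec$detectionAccepted <- det@accepted
  if (!is.null(det@ellipse)) {
    ctr <- ellipseCenter(det)
    rec$centerX <- ctr[1]; rec$centerY <- ctr[2]
    rec$majorAxis <- majorAxisLength(det)
    rec$minorAxis <- minorAxisLength(det)
    rec$b <- det@b; rec$param1 <- det@param1
  }
  if (!det@accepted) return(rec)
  center <- ellipseCenter(det)

  match <- locateTemplate(img, config@template, "eq10_normalized")
  if (matchQuality(match, config@template) < config@tipScoreMin) return(rec)
  rec$tipFound <- TRUE
  tip <- match@tipXY
  rec$tipX <- tip[1]; rec$tipY <- tip[2]

  disp <- computeDisplacement(center, tip)
  rec$dx <- disp[1]; rec$dy <- disp[2]

  # simulated robot move: re-render with the pipette translated by (dx, dy)
  movedParams <- scene@params
  movedParams@pipetteTip <- scene@params@pipetteTip + disp
  moved <- new("SyntheticScene", image = scene@image, params = movedParams,
               illum = scene@illum, model = scene@model, truth = scene@truth)
  img2 <- simulatedStage(moved)(rec$bestZ)
  tip2 <- locateTip(img2, config@template)
  rec$finalError <- sqrt(sum((tip2 - center)^2))
  rec$success <- rec$finalError <= config@successTolerance
  rec
}

#' Run a suite of simulated injections
#'
#' @param scenes list of \linkS4class{SyntheticScene} (e.g. from
#'   [generateFixtureSuite()]).
#' @param config a \linkS4class{ServoConfig}.
#' @param runAutofocusStage passed through to [runInjectionSequence()].
#' @return a \linkS4class{ServoReport}.
#' @export
runSuite <- function(scenes, config = ServoConfig(),
                     runAutofocusStage = TRUE) {
  if (!length(scenes)) stop("empty scene suite")
  recs <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    r <- runInjectionSequence(scenes[[i]], config, runAutofocusStage)
    cbind(scene = i, r)
  }))
  n <- nrow(recs); ns <- sum(recs$success)
  new("ServoReport", records = recs, nScenes = as.integer(n),
      nSuccess = as.integer(ns), successRate = ns / n)
}

#' Write a servo report to disk
#'
#' JSON for the full report (summary + per-scene records) and CSV with one
#' row per scene.
#'
#' @param report a \linkS4class{ServoReport}.
#' @param jsonPath,csvPath output paths (either may be NULL to skip).
#' @return invisibly, the report.
#' @export
writeServoReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(report, "ServoReport"))
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(n_scenes = report@nScenes, n_success = report@nSuccess,
           success_rate = report@successRate, records = report@records),
      jsonPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(csvPath))
    utils::write.csv(report@records, csvPath, row.names = FALSE)
  invisible(report)
}
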