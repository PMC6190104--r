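# Pipette-tip localization by template matching. The template carries the
# pixel offsets from its origin to the needle tip, so a match position
# yields the tip coordinate directly.

checkWindow <- function(img, tpl, origin) {
  m <- nrow(tpl@patch); n <- ncol(tpl@patch)
  i <- origin[1]; j <- origin[2]
  if (i < 0 || j < 0 || i + m > nrow(img) || j + n > ncol(img))
    stop("template window overhangs the image at this origin")
  img[(i + 1):(i + m), (j + 1):(j + n), drop = FALSE]
}

#' Sum-of-squared-deviations match score at one origin
#'
#' \eqn{e = \sum (f - g)^2} over the m x n window with top-left at the
#' 0-based (row, col) `origin`; small means similar, 0 is a perfect match.
#'
#' @param img intensity matrix.
#' @param tpl a \linkS4class{TipTemplate}.
#' @param origin (i, j) = 0-based (row, col) of the window's top-left pixel.
#' @return nonnegative scalar.
#' @export
ssdScore <- function(img, tpl, origin) {
  checkGray(img)
  f <- checkWindow(img, tpl, origin)
  d <- f - tpl@patch
  sum(d * d)
}

#' Normalized match measure at one origin
#'
#' \eqn{M = \sum g f / \sqrt{\sum f^2}} over the window: the correlation of
#' template and window divided by the window's energy, which cancels any
#' multiplicative illumination gain on the image. An identically zero
#' window scores 0 by convention, so flat dark regions never win.
#'
#' @inheritParams ssdScore
#' @return nonnegative scalar (for nonnegative images).
#' @export
normalizedMatchScore <- function(img, tpl, origin) {
  checkGray(img)
  f <- checkWindow(img, tpl, origin)
  denom <- sqrt(sum(f * f))
  if (denom == 0) return(0)
  sum(tpl@patch * f) / denom
}

#' Locate a template by exhaustive search
#'
#' Evaluates the chosen match measure at every valid origin and returns the
#' first origin (in row-major order: top-to-bottom, then left-to-right)
#' attaining the maximum — the sequential compare-and-record rule, where
#' only a strictly larger value displaces the recorded best.
#'
#' Measures: `"eq10_normalized"` (default) is the gain-invariant
#' [normalizedMatchScore()]; `"eq9_unnormalized"` is the raw correlation
#' \eqn{\sum g f}, cheaper but fooled by bright regions when illumination
#' changes.
#'
#' @param img intensity matrix, at least as large as the template.
#' @param tpl a \linkS4class{TipTemplate}.
#' @param measure "eq10_normalized" or "eq9_unnormalized".
#' @return a \linkS4class{MatchResult}.
#' @export
locateTemplate <- function(img, tpl,
                           measure = c("eq10_normalized", "eq9_unnormalized")) {
  checkGray(img)
  measure <- match.arg(measure)
  g <- tpl@patch
  m <- nrow(g); n <- ncol(g)
  H <- nrow(img) - m + 1L; W <- ncol(img) - n + 1L
  if (H < 1L || W < 1L) stop("template larger than image")
  # correlation and window energy accumulated over template pixels so that
  # identical windows get bitwise-identical scores (exact tie-breaking)
  CC <- matrix(0, H, W)
  SS <- if (measure == "eq10_normalized") matrix(0, H, W) else NULL
  for (k in 1:m) {
    rows <- k:(k + H - 1L)
    for (l in 1:n) {
      sub <- img[rows, l:(l + W - 1L), drop = FALSE]
      CC <- CC + g[k, l] * sub
      if (!is.null(SS)) SS <- SS + sub * sub
    }
  }
  score <- if (is.null(SS)) CC else {
    out <- matrix(0, H, W)
    pos <- SS > 0
    out[pos] <- CC[pos] / sqrt(SS[pos])
    out
  }
  # first maximum in row-major order
  idx <- which(t(score) == max(score))[1] - 1L
  i <- idx %/% W
  j <- idx %% W
  new("MatchResult", origin = c(i, j), score = score[i + 1L, j + 1L],
      tipXY = c(j + tpl@offsetL, i + tpl@offsetH))
}

#' Locate the needle tip
#'
#' Runs [locateTemplate()] with the normalized measure and applies the
#' template's tip offsets: tip x = j + L, tip y = i + H for a match at
#' (i, j).
#'
#' @inheritParams locateTemplate
#' @return (x, y) tip pixel, 0-based.
#' @export
locateTip <- function(img, tpl) {
  locateTemplate(img, tpl, "eq10_normalized")@tipXY
}

#' Build a tip template from a reference image
#'
#' Crops the rectangle with top-left (x0, y0) and the given size from a
#' reference image and stores the displacement from the rectangle's origin
#' to the user-identified tip pixel.
#'
#' @param img reference intensity matrix.
#' @param x0,y0 0-based top-left corner of the crop.
#' @param width,height crop size in pixels.
#' @param tip (x, y) of the needle tip in the reference image.
#' @return a \linkS4class{TipTemplate}.
#' @export
makeTipTemplate <- function(img, x0, y0, width, height, tip) {
  checkGray(img)
  if (x0 < 0 || y0 < 0 || x0 + width > ncol(img) || y0 + height > nrow(img))
    stop("crop rectangle outside the image")
  patch <- img[(y0 + 1):(y0 + height), (x0 + 1):(x0 + width), drop = FALSE]
  TipTemplate(patch, offsetL = tip[1] - x0, offsetH = tip[2] - y0)
}

#' Default pipette-tip template
#'
#' Renders a clean reference scene containing only the pipette (no embryo,
#' even illumination, no sensor noise) at the model's in-focus blur and
#' crops a patch around the tip. Because the needle taper has a fixed
#' slope, this template matches the near-tip shape of every generated
#' scene with the same entry edge and widths.
#'
#' @param entryEdge pipette entry edge of the scenes to be matched.
#' @param tipWidth,baseWidth needle widths, px.
#' @param intensity needle 8-bit level.
#' @param sigmaAtFocus residual in-focus blur, px.
#' @param width,height template size, px.
#' @return a \linkS4class{TipTemplate}.
#' @export
defaultTipTemplate <- function(entryEdge = "right", tipWidth = 8,
                               baseWidth = 44, intensity = 40,
                               sigmaAtFocus = 0.5, width = 33L,
                               height = 25L) {
  sz <- 160L
  tip <- switch(entryEdge, right = c(40, sz / 2), left = c(sz - 40, sz / 2),
                top = c(sz / 2, sz - 40), bottom = c(sz / 2, 40))
  params <- SceneParams(imageWidth = sz, imageHeight = sz,
                        embryoPresent = FALSE, pipetteTip = tip,
                        pipetteEntryEdge = entryEdge,
                        pipetteTipWidth = tipWidth,
                        pipetteBaseWidth = baseWidth,
                        pipetteIntensity = intensity,
                        noiseSigma = 0, seed = 0L)
  ref <- renderScene(params, sigma = sigmaAtFocus)$image
  # place the tip a few pixels inside the patch on the approach side
  lead <- 6L
  x0 <- switch(entryEdge, right = tip[1] - lead, left = tip[1] + lead - width,
               top = tip[1] - width %/% 2L, bottom = tip[1] - width %/% 2L)
  y0 <- switch(entryEdge, right = tip[2] - height %/% 2L,
               left = tip[2] - height %/% 2L,
               top = tip[2] + lead - height, bottom = tip[2] - lead)
  makeTipTemplate(ref, x0, y0, width, height, tip)
}
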