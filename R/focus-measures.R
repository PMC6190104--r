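# Focus criterion functions and focus-curve diagnostics. All three scores
# are pure functions of the observed pixels: sums run only over pixels whose
# operands lie inside the image (no padding), accumulated in doubles.

#' Brenner gradient focus score
#'
#' Sum over all pixels of the squared intensity difference between a pixel
#' and its horizontal neighbor two columns away:
#' \eqn{\sum_{x,y} [I(x+2,y) - I(x,y)]^2}. Only the horizontal direction is
#' used. Large when fine horizontal detail is sharp; zero on a constant
#' image.
#'
#' @param img intensity matrix (rows = y, cols = x), width >= 3.
#' @return nonnegative scalar.
#' @export
brennerScore <- function(img) {
  img <- asGrayImage(img)
  checkGray(img, minW = 3L)
  w <- ncol(img)
  d <- img[, 3:w, drop = FALSE] - img[, 1:(w - 2), drop = FALSE]
  sum(d * d)
}

#' Tenengrad focus score
#'
#' Sum of squared horizontal and vertical Sobel responses,
#' \eqn{\sum_{x,y} S_x(x,y)^2 + S_y(x,y)^2}, over every pixel where the 3x3
#' Sobel stencils fit entirely inside the image. The standard +/-1, +/-2
#' kernels are used.
#'
#' @inheritParams brennerScore
#' @return nonnegative scalar.
#' @export
tenengradScore <- function(img) {
  img <- asGrayImage(img)
  checkGray(img, minH = 3L, minW = 3L)
  h <- nrow(img); w <- ncol(img)
  ir <- 2:(h - 1); ic <- 2:(w - 1)
  # window rows/cols relative to the interior
  tl <- img[ir - 1, ic - 1]; tc <- img[ir - 1, ic]; tr <- img[ir - 1, ic + 1]
  ml <- img[ir, ic - 1];                             mr <- img[ir, ic + 1]
  bl <- img[ir + 1, ic - 1]; bc <- img[ir + 1, ic]; br <- img[ir + 1, ic + 1]
  sx <- (tr + 2 * mr + br) - (tl + 2 * ml + bl)
  sy <- (bl + 2 * bc + br) - (tl + 2 * tc + tr)
  sum(sx * sx + sy * sy)
}

#' Normalized-variance focus score
#'
#' \eqn{(1/\mu) \sum_{x,y} (I(x,y) - \mu)^2} with \eqn{\mu} the mean
#' intensity. The formula is evaluated literally (no division by the pixel
#' count); only relative behavior across a stack matters for focusing.
#'
#' @inheritParams brennerScore
#' @return nonnegative scalar.
#' @export
normalizedVarianceScore <- function(img) {
  img <- asGrayImage(img)
  checkGray(img)
  mu <- mean(img)
  if (mu <= 0) stop("mean intensity is zero; score undefined")
  d <- img - mu
  sum(d * d) / mu
}

focusMeasureFun <- function(measure = c("brenner", "tenengrad",
                                        "normalized_variance")) {
  measure <- match.arg(measure)
  switch(measure, brenner = brennerScore, tenengrad = tenengradScore,
         normalized_variance = normalizedVarianceScore)
}

#' Compute a focus curve over a through-focus stack
#'
#' Scores every frame with the chosen criterion; optionally divides by the
#' maximum so curves from different criteria are comparable.
#'
#' @param stack a \linkS4class{FocusStack}.
#' @param measure "brenner", "tenengrad" or "normalized_variance".
#' @param normalize divide scores by their maximum?
#' @return a \linkS4class{FocusCurve}.
#' @export
computeFocusCurve <- function(stack, measure = "brenner", normalize = TRUE) {
  stopifnot(is(stack, "FocusStack"))
  if (!length(stack@frames)) stop("empty stack")
  f <- focusMeasureFun(measure)
  s <- vapply(stack@frames, f, numeric(1))
  if (normalize) s <- s / max(s)
  new("FocusCurve", z = stack@z, score = s, normalized = normalize,
      measure = measure)
}

#' Full width at half maximum of a normalized focus curve
#'
#' Operationalizes peak narrowness: the width of the region where the
#' normalized score is >= 0.5, with the two half-maximum crossings located
#' by linear interpolation between samples. A narrow peak means the
#' criterion discriminates the focal plane sharply.
#'
#' @param curve a normalized, unimodal-around-its-peak
#'   \linkS4class{FocusCurve}.
#' @return width in micrometres.
#' @export
curveFWHM <- function(curve) {
  stopifnot(is(curve, "FocusCurve"))
  if (!curve@normalized) stop("curve must be normalized")
  s <- curve@score; z <- curve@z
  p <- which.max(s)
  half <- 0.5
  # walk left from the peak to the first sample below half
  li <- p
  while (li > 1 && s[li - 1] >= half) li <- li - 1
  if (li == 1 && s[1] >= half)
    stop("curve never drops below half maximum on the left; width is open")
  xl <- z[li - 1] + (half - s[li - 1]) / (s[li] - s[li - 1]) * (z[li] - z[li - 1])
  ri <- p
  n <- length(s)
  while (ri < n && s[ri + 1] >= half) ri <- ri + 1
  if (ri == n && s[n] >= half)
    stop("curve never drops below half maximum on the right; width is open")
  xr <- z[ri] + (s[ri] - half) / (s[ri] - s[ri + 1]) * (z[ri + 1] - z[ri])
  xr - xl
}
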