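# Embryo detection: adaptive local-mean thresholding with a (b, param1)
# parameter circulation, boundary extraction, and direct least-squares
# ellipse fitting. The fitted major-axis length decides whether a parameter
# combination segmented the chorion plausibly.

#' Local weighted mean of every pixel's b x b neighborhood
#'
#' The adaptive threshold's reference value A: a Gaussian- (sigma tied to
#' b/6) or uniform-weighted mean over the b x b block around each pixel,
#' with replicate borders so A is well-defined at the image edge without
#' biasing toward zero. Computed separably.
#'
#' @param img intensity matrix.
#' @param b odd block size, 3 <= b <= min(dim).
#' @param weighting "gaussian" or "uniform".
#' @return real-valued matrix of the same size.
#' @export
localWeightedMean <- function(img, b, weighting = c("gaussian", "uniform")) {
  checkGray(img)
  weighting <- match.arg(weighting)
  b <- as.integer(b)
  if (b %% 2L == 0L || b < 3L || b > min(dim(img)))
    stop("'b' must be odd and within 3..min(height, width)")
  r <- (b - 1L) %/% 2L
  wts <- if (weighting == "uniform") rep(1 / b, b) else {
    k <- dnorm(-r:r, sd = b / 6)
    k / sum(k)
  }
  h <- nrow(img); w <- ncol(img)
  P <- img[c(rep(1L, r), 1:h, rep(h, r)), c(rep(1L, r), 1:w, rep(w, r))]
  tmp <- matrix(0, h + 2L * r, w)
  for (k in 0:(b - 1L)) tmp <- tmp + wts[k + 1L] * P[, (1L + k):(w + k)]
  A <- matrix(0, h, w)
  for (k in 0:(b - 1L)) A <- A + wts[k + 1L] * tmp[(1L + k):(h + k), ]
  A
}

#' Adaptive local-mean threshold
#'
#' Each pixel is compared against its own threshold T = A - param1, where A
#' is the local weighted mean: pixels brighter than T map to 255, all
#' others to 0. Because the threshold tracks the local mean, a smooth
#' illumination gradient shifts T along with the pixel values and the
#' segmentation survives uneven lighting that defeats any single global
#' threshold.
#'
#' @param img intensity matrix.
#' @param b odd block size.
#' @param param1 nonnegative intensity offset.
#' @param weighting "gaussian" or "uniform".
#' @param localMean optionally a precomputed [localWeightedMean()] raster
#'   for this (img, b, weighting), to avoid recomputation in the circulation.
#' @return binary matrix with values in {0, 255}.
#' @export
adaptiveThreshold <- function(img, b, param1, weighting = "gaussian",
                              localMean = NULL) {
  checkGray(img)
  if (param1 < 0) stop("param1 must be >= 0")
  A <- if (is.null(localMean)) localWeightedMean(img, b, weighting) else localMean
  out <- matrix(0, nrow(img), ncol(img))
  out[img > A - param1] <- 255
  out
}

# Otsu's threshold level: the integer cut t in 0..254 maximizing the
# between-class variance of the {<= t, > t} split, computed from the
# 256-bin histogram in closed form. First maximizing t wins ties.
otsuLevel <- function(img) {
  checkGray(img)
  if (max(img) == min(img)) stop("constant image: no threshold exists")
  counts <- tabulate(as.integer(round(img)) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * lev)
  muT <- mu[256]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  lev[which.max(sb[1:255])]
}

#' Global Otsu threshold (baseline)
#'
#' The classical single-threshold binarization maximizing between-class
#' variance, kept as the baseline the adaptive method is compared against:
#' it works on evenly illuminated bimodal images and breaks down under
#' strong illumination gradients. Same 0/255 encoding as
#' [adaptiveThreshold()] (pixels above the threshold map to 255).
#'
#' @param img non-constant intensity matrix.
#' @return binary matrix in {0, 255}, with the chosen level in
#'   `attr(, "threshold")`.
#' @export
otsuThreshold <- function(img) {
  t0 <- otsuLevel(img)
  out <- matrix(0, nrow(img), ncol(img))
  out[img > t0] <- 255
  attr(out, "threshold") <- t0
  out
}

#' Boundary of the largest dark connected region
#'
#' Labels the 0-valued (dark) phase of a binary image, traces each
#' component's boundary, and returns the boundary with the most points —
#' under the membrane-darker-than-local-mean threshold the chorion annulus
#' is the dominant dark structure, so its outline is what gets fitted.
#'
#' @param bin binary matrix in {0, 255}.
#' @param minPoints smallest acceptable boundary length.
#' @return n x 2 matrix of 0-based (x, y) boundary points, or NULL when no
#'   component has at least `minPoints` boundary points.
#' @export
largestDarkContour <- function(bin, minPoints = 5L) {
  checkGray(bin)
  if (!all(bin %in% c(0, 255))) stop("'bin' must be a 0/255 binary image")
  mask <- matrix(as.numeric(bin == 0), nrow(bin), ncol(bin))
  if (!any(mask > 0)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  oc <- EBImage::ocontour(lab)
  if (!length(oc)) return(NULL)
  len <- vapply(oc, nrow, integer(1))
  bestLen <- max(len)
  if (bestLen < minPoints) return(NULL)
  pts <- oc[[which.max(len)]]
  # ocontour reports 0-based (row, col) for a rows-by-cols matrix input
  cbind(x = pts[, 2], y = pts[, 1])
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic ax^2 + bxy + cy^2 + dx + ey + f = 0 to the points by the
#' numerically stable direct algebraic fit with the built-in ellipse
#' constraint 4ac - b^2 = 1 (Fitzgibbon's method in the Halir-Flusser
#' formulation), then converts to geometric parameters. Exact on
#' noise-free ellipse samples.
#'
#' @param points n x 2 matrix of (x, y) coordinates, n >= 5, not collinear.
#' @return an \linkS4class{EllipseFit} with full axis lengths.
#' @export
fitEllipseLSQ <- function(points) {
  if (!is.matrix(points) || ncol(points) != 2L)
    stop("'points' must be an n x 2 matrix")
  if (nrow(points) < 5L) stop("at least 5 points are required")
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  sc <- max(stats::sd(points[, 1]), stats::sd(points[, 2]))
  if (!is.finite(sc) || sc <= 0) stop("degenerate point configuration")
  x <- (points[, 1] - mx) / sc
  y <- (points[, 2] - my) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("no ellipse solution for these points")
  a1 <- Re(ev$vectors[, ok[1]])
  coef <- c(a1, as.vector(Tm %*% a1))   # (A, B, C, D, E, F) in scaled frame
  # undo the conditioning transform x' = (x - mx)/sc
  A <- coef[1] / sc^2
  B <- coef[2] / sc^2
  C <- coef[3] / sc^2
  D <- coef[4] / sc - 2 * A * mx - B * my
  E <- coef[5] / sc - 2 * C * my - B * mx
  F <- coef[6] + A * mx^2 + B * mx * my + C * my^2 -
    coef[4] * mx / sc - coef[5] * my / sc
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("fit did not yield an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  a2 <- num / (den * (s - (A + C)))
  b2 <- num / (den * (-s - (A + C)))
  if (!is.finite(a2) || !is.finite(b2) || a2 <= 0 || b2 <= 0)
    stop("fit did not yield an ellipse")
  semi <- sqrt(c(a2, b2))
  # the -s branch axis lies along theta; the +s branch perpendicular to it
  theta <- 0.5 * atan2(B, A - C) * 180 / pi
  angle <- if (semi[1] >= semi[2]) theta + 90 else theta
  if (semi[1] < semi[2]) semi <- rev(semi)
  angle <- ((angle + 90) %% 180) - 90
  new("EllipseFit", center = c(cx, cy), majorAxis = 2 * semi[1],
      minorAxis = 2 * semi[2], angle = angle)
}

#' Detect the embryo by the (b, param1) circulation
#'
#' Iterates over the block sizes in `bRange` (ascending, outer loop) and the
#' offsets in `param1Range` (inner loop). Each combination runs
#' [adaptiveThreshold()], takes the [largestDarkContour()], and fits an
#' ellipse; the first combination whose fitted major-axis length L falls in
#' the acceptance band wins. When the band is never hit, the result carries
#' the fit whose L came closest to the band, with `accepted = FALSE`.
#'
#' @param img intensity matrix.
#' @param config a \linkS4class{DetectionConfig}; NA band limits default to
#'   \[0.45, 0.95\] times the shorter image dimension.
#' @return an \linkS4class{EmbryoDetection}.
#' @export
detectEmbryo <- function(img, config = DetectionConfig()) {
  checkGray(img)
  validObject(config)
  LMin <- if (is.na(config@LMin)) 0.45 * min(dim(img)) else config@LMin
  LMax <- if (is.na(config@LMax)) 0.95 * min(dim(img)) else config@LMax
  nTried <- 0L
  bestFit <- NULL; bestB <- NA_real_; bestP <- NA_real_; bestDist <- Inf
  for (b in config@bRange) {
    if (b > min(dim(img))) break
    A <- localWeightedMean(img, b, config@weighting)
    for (p1 in config@param1Range) {
      nTried <- nTried + 1L
      bin <- adaptiveThreshold(img, b, p1, localMean = A)
      pts <- largestDarkContour(bin, config@minContourPoints)
      if (is.null(pts)) next
      fit <- tryCatch(fitEllipseLSQ(pts), error = function(e) NULL)
      if (is.null(fit)) next
      L <- fit@majorAxis
      if (L >= LMin && L <= LMax)
        return(new("EmbryoDetection", ellipse = fit, b = as.numeric(b),
                   param1 = p1, accepted = TRUE,
                   nCombinationsTried = nTried))
      d <- if (L < LMin) LMin - L else L - LMax
      if (d < bestDist) {
        bestDist <- d; bestFit <- fit; bestB <- b; bestP <- p1
      }
    }
  }
  new("EmbryoDetection", ellipse = bestFit, b = as.numeric(bestB),
      param1 = bestP, accepted = FALSE, nCombinationsTried = nTried)
}

#' Otsu-baseline embryo detection
#'
#' The comparison pipeline: global Otsu binarization, then the same contour
#' extraction and ellipse fit as [detectEmbryo()], with no parameter
#' circulation. Used to demonstrate the failure mode under uneven
#' illumination.
#'
#' @inheritParams detectEmbryo
#' @return an \linkS4class{EmbryoDetection} (`b`, `param1` are NA).
#' @export
detectEmbryoOtsu <- function(img, config = DetectionConfig()) {
  checkGray(img)
  LMin <- if (is.na(config@LMin)) 0.45 * min(dim(img)) else config@LMin
  LMax <- if (is.na(config@LMax)) 0.95 * min(dim(img)) else config@LMax
  bin <- tryCatch(otsuThreshold(img), error = function(e) NULL)
  fit <- NULL
  if (!is.null(bin)) {
    pts <- largestDarkContour(bin, config@minContourPoints)
    if (!is.null(pts))
      fit <- tryCatch(fitEllipseLSQ(pts), error = function(e) NULL)
  }
  accepted <- !is.null(fit) && fit@majorAxis >= LMin && fit@majorAxis <= LMax
  new("EmbryoDetection", ellipse = fit, b = NA_real_, param1 = NA_real_,
      accepted = accepted, nCombinationsTried = 1L)
}
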