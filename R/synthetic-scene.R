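# Synthetic bright-field scene generator. Every downstream stage is exercised
# against these renders, whose ground truth is known exactly.

# Squared normalized elliptical radius of every pixel: 1 on the ellipse
# boundary, < 1 inside. X, Y are 0-based coordinate matrices.
ellipseRadius2 <- function(X, Y, center, axes, angleDeg) {
  th <- angleDeg * pi / 180
  dx <- X - center[1]; dy <- Y - center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / axes[1])^2 + (v / axes[2])^2
}

# Length of the constant-slope taper behind the tip, px: beyond it the
# needle runs at base width. Fixed so the near-tip shape is scene-invariant.
.taperLength <- 250

# Gaussian optical blur. Sigma is capped at an eighth of the shorter image
# side: past that the field is featureless and a larger kernel would not
# fit the canvas.
opticalBlur <- function(img, sigma) {
  sigma <- min(sigma, min(dim(img)) / 8)
  if (sigma <= 0.05) return(img)
  EBImage::gblur(img, sigma = sigma)
}

pipetteMask <- function(params, X, Y) {
  tp <- params@pipetteTip
  halfTip <- params@pipetteTipWidth / 2
  halfBase <- params@pipetteBaseWidth / 2
  slope <- (halfBase - halfTip) / .taperLength
  # distance behind the tip along the needle axis, and across it
  switch(params@pipetteEntryEdge,
    left   = { d <- tp[1] - X; a <- abs(Y - tp[2]) },
    right  = { d <- X - tp[1]; a <- abs(Y - tp[2]) },
    top    = { d <- tp[2] - Y; a <- abs(X - tp[1]) },
    bottom = { d <- Y - tp[2]; a <- abs(X - tp[1]) })
  half <- pmin(halfTip + slope * pmax(d, 0), halfBase)
  d >= 0 & a <= half
}

# Noise-free scene at full sharpness (no illumination, no sensor noise);
# the interior texture is seeded from params@seed so it is identical in
# every frame of a through-focus stack.
renderIdeal <- function(params) {
  h <- params@imageHeight; w <- params@imageWidth
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  img <- matrix(params@backgroundIntensity, h, w)
  if (params@embryoPresent) {
    ax <- params@embryoAxes
    r2out <- ellipseRadius2(X, Y, params@embryoCenter, ax, params@embryoAngle)
    axIn <- pmax(ax - params@membraneThickness, 1)
    r2in <- ellipseRadius2(X, Y, params@embryoCenter, axIn, params@embryoAngle)
    inner <- r2in <= 1
    membrane <- r2out <= 1 & !inner
    # perivitelline space renders near background; the yolk disc fills
    # most of the interior and is distinctly darker
    axYolk <- pmax(0.78 * axIn, 1)
    yolk <- ellipseRadius2(X, Y, params@embryoCenter, axYolk,
                           params@embryoAngle) <= 1
    img[inner] <- params@backgroundIntensity - 15
    img[yolk] <- params@yolkIntensity
    img[membrane] <- params@membraneIntensity
    # low-amplitude seeded texture so focus criteria respond to defocus
    nIn <- sum(inner)
    if (nIn) {
      tex <- withSeed(params@seed, rnorm(nIn, sd = 6))
      img[inner] <- img[inner] + tex
    }
  }
  if (params@pipettePresent)
    img[pipetteMask(params, X, Y)] <- params@pipetteIntensity
  img
}

# Multiplicative gain field for an IlluminationField on an h x w canvas.
gainField <- function(illum, h, w) {
  if (illum@mode == "none") return(matrix(1, h, w))
  g <- illum@gains
  if (illum@mode == "linear") {
    top <- seq(g[1], g[2], length.out = w)
    bottom <- seq(g[3], g[4], length.out = w)
    v <- seq(0, 1, length.out = h)
    outer(1 - v, top) + outer(v, bottom)
  } else {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    X <- matrix(rep(0:(w - 1), each = h), h, w)
    Y <- matrix(rep(0:(h - 1), times = w), h, w)
    r <- sqrt(((X - cx) / cx)^2 + ((Y - cy) / cy)^2)
    r <- pmin(r, 1)
    g[1] + (g[3] - g[1]) * r
  }
}

#' Apply an uneven-illumination field to an image
#'
#' Multiplies each pixel by the field's smooth gain (bilinear between the
#' corner gains in linear mode, center-to-border in radial mode), adds the
#' offset, and clamps to \[0, 255\]. `mode = "none"` returns the input
#' unchanged.
#'
#' @param img intensity matrix.
#' @param illum an \linkS4class{IlluminationField}.
#' @return intensity matrix of the same size.
#' @export
applyIllumination <- function(img, illum) {
  checkGray(img)
  validObject(illum)
  if (illum@mode == "none") return(img)
  clamp8(img * gainField(illum, nrow(img), ncol(img)) + illum@offset)
}

sensorNoise <- function(img, sigma, seed) {
  if (sigma <= 0) return(img)
  img + withSeed(seed, matrix(rnorm(length(img), sd = sigma),
                              nrow(img), ncol(img)))
}

makeTruth <- function(params, illum, focalZ = NA_real_) {
  new("SceneTruth",
      embryoCenter = if (params@embryoPresent) params@embryoCenter else c(NA_real_, NA_real_),
      embryoAxes = if (params@embryoPresent) params@embryoAxes else c(NA_real_, NA_real_),
      embryoAngle = if (params@embryoPresent) params@embryoAngle else NA_real_,
      focalZ = as.numeric(focalZ),
      tipXY = if (params@pipettePresent) params@pipetteTip else c(NA_real_, NA_real_),
      illumMode = illum@mode, seed = params@seed)
}

#' Render a synthetic micrograph with known ground truth
#'
#' Renders the embryo (dark chorion annulus, interior yolk disc with seeded
#' low-amplitude texture) and the tapered pipette on a bright background,
#' optionally blurs with an isotropic Gaussian of standard deviation
#' `sigma`, applies the illumination field, adds seeded sensor noise, and
#' clamps/rounds to 8-bit levels. Identical `(params, illum, sigma)` always
#' produce byte-identical images.
#'
#' @param params a \linkS4class{SceneParams}.
#' @param illum an \linkS4class{IlluminationField}.
#' @param sigma optical blur sigma in pixels (0 = perfectly sharp render).
#' @param noiseSeed seed for the sensor noise draw; defaults to the scene
#'   seed. Through-focus stacks pass a distinct value per frame.
#' @return list with elements `image` (intensity matrix) and `truth`
#'   (\linkS4class{SceneTruth}).
#' @export
renderScene <- function(params, illum = IlluminationField(), sigma = 0,
                        noiseSeed = params@seed) {
  validObject(params); validObject(illum)
  img <- renderIdeal(params)
  img <- opticalBlur(img, sigma)
  img <- applyIllumination(img, illum)
  img <- sensorNoise(img, params@noiseSigma, noiseSeed)
  list(image = round(clamp8(img)), truth = makeTruth(params, illum))
}

#' Render a through-focus image stack
#'
#' One frame per stage position, blurred with the defocus model's
#' sigma(z) = sigmaAtFocus + blurSlope * |z - focalZ|; sensor noise is drawn
#' independently (but reproducibly) per frame.
#'
#' @param params a \linkS4class{SceneParams}.
#' @param model a \linkS4class{DefocusModel}.
#' @param z strictly increasing stage positions, micrometres (>= 3 of them).
#' @param illum an \linkS4class{IlluminationField}.
#' @return list with elements `stack` (\linkS4class{FocusStack}) and `truth`
#'   (\linkS4class{SceneTruth} carrying the focal plane).
#' @export
renderDefocusStack <- function(params, model, z, illum = IlluminationField()) {
  validObject(params); validObject(model)
  if (length(z) < 3L) stop("need at least 3 stage positions")
  if (any(diff(z) <= 0)) stop("z positions must be strictly increasing")
  ideal <- renderIdeal(params)
  frames <- vector("list", length(z))
  for (k in seq_along(z)) {
    img <- opticalBlur(ideal, blurSigma(model, z[k]))
    img <- applyIllumination(img, illum)
    img <- sensorNoise(img, params@noiseSigma, params@seed + 7L * k)
    frames[[k]] <- round(clamp8(img))
  }
  list(stack = new("FocusStack", z = as.numeric(z), frames = frames),
       truth = makeTruth(params, illum, focalZ = model@focalZ))
}

#' Simulated focusable stage
#'
#' Returns a capture function `f(z)` that renders the scene at stage
#' position `z` (micrometres) with the scene's defocus model — the software
#' stand-in for a motorized focus axis plus camera. Captures are
#' deterministic per z (the sensor-noise draw is seeded from z) and cached,
#' so repeated visits are free.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return function of z returning an intensity matrix.
#' @export
simulatedStage <- function(scene) {
  stopifnot(is(scene, "SyntheticScene"))
  params <- scene@params; illum <- scene@illum; model <- scene@model
  ideal <- renderIdeal(params)
  cache <- new.env(parent = emptyenv())
  function(z) {
    key <- sprintf("%.3f", z)
    if (!is.null(cache[[key]])) return(cache[[key]])
    img <- opticalBlur(ideal, blurSigma(model, z))
    img <- applyIllumination(img, illum)
    img <- sensorNoise(img, params@noiseSigma,
                       params@seed + (as.integer(round(z)) %% 100000L))
    img <- round(clamp8(img))
    cache[[key]] <- img
    img
  }
}

#' Assemble a SyntheticScene
#'
#' Bundles parameters, illumination and defocus model with the in-focus
#' render and its ground truth.
#'
#' @param params,illum,model generating objects.
#' @return a \linkS4class{SyntheticScene}.
#' @export
makeScene <- function(params, illum = IlluminationField(),
                      model = DefocusModel()) {
  r <- renderScene(params, illum, sigma = model@sigmaAtFocus)
  truth <- makeTruth(params, illum, focalZ = model@focalZ)
  new("SyntheticScene", image = r$image, params = params, illum = illum,
      model = model, truth = truth)
}

#' Generate a seeded suite of ground-truthed scenes
#'
#' Scene geometry (embryo center, axes, orientation, pipette pose) is
#' randomized per scene; illumination severity ramps linearly from perfectly
#' even (mode "none") to a strong linear gradient whose darkest corner gain
#' is 0.4, so the suite spans the even-to-uneven contrast the detection
#' stage is meant to survive.
#'
#' @param seed integer master seed; the suite is reproducible from it.
#' @param nScenes number of scenes (>= 1).
#' @param imageSize square canvas side, pixels.
#' @return list of \linkS4class{SyntheticScene}, with an
#'   `illuminationSeverity` attribute giving each scene's severity in
#'   \[0, 1\].
#' @export
generateFixtureSuite <- function(seed, nScenes = 14L, imageSize = 512L) {
  if (nScenes < 1L) stop("nScenes must be >= 1")
  seed <- as.integer(seed)
  severity <- if (nScenes == 1L) 0 else seq(0, 1, length.out = nScenes)
  draws <- withSeed(seed, lapply(seq_len(nScenes), function(i) {
    list(cx = runif(1, -25, 25), cy = runif(1, -25, 25),
         a = runif(1, 0.27, 0.32) * imageSize,
         ratio = runif(1, 0.82, 0.95),
         angle = runif(1, 0, 180),
         tipdx = runif(1, 40, 90), tipdy = runif(1, -90, 90),
         darkside = sample(c("bottom", "top"), 1),
         focalZ = runif(1, 2000, 4000))
  }))
  scenes <- vector("list", nScenes)
  for (i in seq_len(nScenes)) {
    d <- draws[[i]]
    ctr <- c(imageSize * 0.45 + d$cx, imageSize / 2 + d$cy)
    axes <- c(d$a, d$a * d$ratio)
    # keep the tip far enough from the border that a full tip-template
    # window (which extends past the tip toward the entry edge) fits
    tip <- c(min(ctr[1] + axes[1] + d$tipdx, imageSize - 40),
             max(min(ctr[2] + d$tipdy, imageSize - 40), 40))
    params <- SceneParams(imageWidth = imageSize, imageHeight = imageSize,
                          embryoCenter = ctr, embryoAxes = axes,
                          embryoAngle = d$angle, pipetteTip = tip,
                          seed = seed + 1000L * i)
    illum <- if (severity[i] == 0) IlluminationField() else {
      g <- 1 - 0.6 * severity[i]
      gains <- if (d$darkside == "bottom") c(1, 1, g, g) else c(g, g, 1, 1)
      IlluminationField("linear", gains = gains)
    }
    scenes[[i]] <- makeScene(params, illum,
                             DefocusModel(focalZ = d$focalZ))
  }
  attr(scenes, "illuminationSeverity") <- severity
  scenes
}

#' Write a scene to disk
#'
#' The image goes out as an 8-bit grayscale PNG or TIFF, the ground truth as
#' a JSON sidecar (keys center_x, center_y, semi_major, semi_minor,
#' angle_deg, focal_z, tip_x, tip_y, seed).
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param imagePath output image path (.png or .tif).
#' @param truthPath output JSON path; defaults to the image path with a
#'   .json extension.
#' @return `imagePath`, invisibly.
#' @export
writeScene <- function(scene, imagePath,
                       truthPath = sub("\\.[^.]+$", ".json", imagePath)) {
  stopifnot(is(scene, "SyntheticScene"))
  writeGrayImage(scene@image, imagePath)
  tr <- scene@truth
  jsonlite::write_json(
    list(center_x = tr@embryoCenter[1], center_y = tr@embryoCenter[2],
         semi_major = tr@embryoAxes[1], semi_minor = tr@embryoAxes[2],
         angle_deg = tr@embryoAngle, focal_z = tr@focalZ,
         tip_x = tr@tipXY[1], tip_y = tr@tipXY[2], seed = tr@seed),
    truthPath, auto_unbox = TRUE, digits = NA)
  invisible(imagePath)
}
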