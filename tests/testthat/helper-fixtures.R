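# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Standard 31-frame through-focus stack (200 um spacing, focal plane on the
# grid) used by the focus-measure concordance and narrowness checks.
standardStack <- function() memo("stack", {
  p <- SceneParams(imageWidth = 320L, imageHeight = 320L,
                   embryoCenter = c(150, 160), embryoAxes = c(95, 80),
                   embryoAngle = 25, pipetteTip = c(270, 110), seed = 11L)
  renderDefocusStack(p, DefocusModel(focalZ = 3000), seq(0, 6000, by = 200))
})

# Seeded 20-scene suite spanning even to strongly uneven illumination.
robustnessSuite <- function() memo("robustness", generateFixtureSuite(7, 20))

# Seeded 14-scene suite for the end-to-end injection experiment.
injectionSuite <- function() memo("injection", generateFixtureSuite(1, 14))

defaultServoConfig <- function() memo("servoConfig", ServoConfig())

# A small textured image with reproducible content.
textureImage <- function(h = 64L, w = 64L, seed = 5L) {
  set.seed(seed)
  round(matrix(runif(h * w, 0, 255), h, w))
}

# Random scene-free autofocus test stage: renders a small embryo scene whose
# sharpness peaks at focalZ.
smallSceneAt <- function(focalZ, seed) {
  set.seed(seed)
  a <- runif(1, 68, 80)
  p <- SceneParams(imageWidth = 256L, imageHeight = 256L,
                   embryoCenter = c(115 + runif(1, -10, 10),
                                    128 + runif(1, -10, 10)),
                   embryoAxes = c(a, a * runif(1, 0.85, 0.95)),
                   embryoAngle = runif(1, 0, 180),
                   pipetteTip = c(220, runif(1, 60, 200)),
                   seed = as.integer(seed))
  makeScene(p, model = DefocusModel(focalZ = focalZ))
}

centerError <- function(det, truth) {
  sqrt(sum((ellipseCenter(det) - truth@embryoCenter)^2))
}
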