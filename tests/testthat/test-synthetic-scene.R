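test_that("rendering is bit-reproducible and clamped to 8-bit", {
  p <- SceneParams(imageWidth = 128L, imageHeight = 128L,
                   embryoCenter = c(60, 64), embryoAxes = c(35, 30),
                   pipetteTip = c(105, 40), noiseSigma = 3, seed = 4L)
  r1 <- renderScene(p)
  r2 <- renderScene(p)
  expect_identical(r1$image, r2$image)
  expect_true(all(r1$image >= 0 & r1$image <= 255))
  expect_identical(dim(r1$image), c(128L, 128L))
})

test_that("background pixels away from the objects equal the set intensity", {
  p <- SceneParams(imageWidth = 160L, imageHeight = 160L,
                   embryoCenter = c(75, 85), embryoAxes = c(40, 34),
                   pipetteTip = c(135, 40), noiseSigma = 0)
  img <- renderScene(p)$image
  # top-left corner holds neither embryo nor pipette
  expect_true(all(img[1:20, 1:20] == p@backgroundIntensity))
})

test_that("invalid geometry is rejected", {
  expect_error(SceneParams(imageWidth = 128L, imageHeight = 128L,
                           embryoCenter = c(20, 64), embryoAxes = c(35, 30)),
               "inside the image")
  expect_error(SceneParams(imageWidth = 128L, imageHeight = 128L,
                           embryoCenter = c(64, 64), embryoAxes = c(30, 25),
                           pipetteTip = c(400, 20)), "inside the image")
  expect_error(SceneParams(imageWidth = 128L, imageHeight = 128L,
                           embryoCenter = c(64, 64), embryoAxes = c(30, 25),
                           membraneIntensity = 250), "below background")
  expect_error(IlluminationField("linear", gains = c(1, 1, -0.2, 1)),
               "> 0")
})

test_that("illumination: identity, uniform gain, and bilinear gradient", {
  img <- matrix(100, 40, 40)
  expect_identical(applyIllumination(img, IlluminationField()), img)
  half <- applyIllumination(img, IlluminationField("linear",
                                                   gains = rep(0.5, 4)))
  expect_true(all(abs(half - 50) < 1e-9))
  grad <- applyIllumination(matrix(200, 60, 60),
                            IlluminationField("linear", c(1, 1, 0.4, 0.4)))
  expect_true(all(abs(grad[1, ] - 200) < 1e-6))
  expect_true(all(abs(grad[60, ] - 80) < 1e-6))
  expect_true(all(diff(grad[, 30]) < 0))  # monotone down each column
})

test_that("defocus stacks blur away from the focal plane", {
  p <- SceneParams(imageWidth = 128L, imageHeight = 128L,
                   embryoCenter = c(60, 64), embryoAxes = c(35, 30),
                   pipetteTip = c(105, 40), noiseSigma = 0, seed = 2L)
  model <- DefocusModel(focalZ = 1000, sigmaAtFocus = 0, blurSlope = 0.012)
  z <- seq(0, 2000, by = 200)
  st <- renderDefocusStack(p, model, z)
  expect_equal(st$truth@focalZ, 1000)
  expect_length(st$stack@frames, length(z))
  # the in-focus frame with zero residual blur equals the sharp render
  expect_identical(st$stack@frames[[which(z == 1000)]],
                   renderScene(p)$image)
  # Brenner argmax over the stack sits at the focal plane
  cv <- computeFocusCurve(st$stack, "brenner")
  expect_equal(curvePositions(cv)[which.max(curveScores(cv))], 1000)
  # scores fall monotonically with defocus distance on a noiseless stack
  s <- curveScores(cv)
  pk <- which.max(s)
  expect_true(all(diff(s[pk:length(s)]) <= 0))
  expect_true(all(diff(s[1:pk]) >= 0))
  expect_error(renderDefocusStack(p, model, c(0, 400, 200)), "increasing")
  expect_error(renderDefocusStack(p, model, c(0, 200)), "at least 3")
})

test_that("fixture suites are seeded, distinct, and span illumination modes", {
  s1 <- generateFixtureSuite(3, 8, imageSize = 256L)
  s2 <- generateFixtureSuite(3, 8, imageSize = 256L)
  expect_length(s1, 8)
  ctrs <- t(vapply(s1, function(s) sceneTruth(s)@embryoCenter, numeric(2)))
  expect_equal(nrow(unique(ctrs)), 8)
  expect_identical(lapply(s1, sceneImage), lapply(s2, sceneImage))
  modes <- vapply(s1, function(s) sceneTruth(s)@illumMode, character(1))
  expect_true(any(modes == "none"))
  sev <- attr(s1, "illuminationSeverity")
  expect_true(any(sev >= 0.99))
  expect_error(generateFixtureSuite(3, 0), ">= 1")
})

test_that("scenes round-trip through PNG with JSON truth sidecars", {
  p <- SceneParams(imageWidth = 96L, imageHeight = 96L,
                   embryoCenter = c(45, 48), embryoAxes = c(25, 21),
                   pipetteTip = c(80, 30), noiseSigma = 0)
  sc <- makeScene(p)
  png <- tempfile(fileext = ".png")
  writeScene(sc, png)
  back <- readGrayImage(png)
  expect_equal(back, sceneImage(sc), tolerance = 1e-6,
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(sub("\\.png$", ".json", png))
  expect_equal(truth$center_x, 45)
  expect_equal(truth$semi_major, 25)
  unlink(c(png, sub("\\.png$", ".json", png)))
})
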