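test_that("local weighted mean: constants, hand case, near-global mean", {
  const <- matrix(42, 16, 16)
  for (wt in c("uniform", "gaussian"))
    expect_equal(localWeightedMean(const, 5, wt), const)
  spike <- matrix(0, 3, 3); spike[2, 2] <- 9
  expect_equal(localWeightedMean(spike, 3, "uniform")[2, 2], 1)
  img <- textureImage(64L, 64L, 8)
  A <- localWeightedMean(img, 63, "uniform")
  # interior pixels of a maximal block approach the global mean
  expect_lt(abs(A[32, 32] - mean(img)), 0.05 * mean(img))
  expect_error(localWeightedMean(img, 4), "odd")
  expect_error(localWeightedMean(img, 65), "odd|min")
})

test_that("adaptive threshold follows T = A - param1 with 0/255 output", {
  const <- matrix(100, 12, 12)
  expect_true(all(adaptiveThreshold(const, 3, 7) == 255))
  step <- cbind(matrix(0, 10, 5), matrix(200, 10, 5))
  bin <- adaptiveThreshold(step, 3, 7, weighting = "uniform")
  expect_true(all(bin %in% c(0, 255)))
  # dark pixels hugging the step see a local mean above 7 -> set to 0
  expect_true(all(bin[2:9, 5] == 0))
  # dark pixels far from the step keep T < 0 -> set to 255
  expect_true(all(bin[, 1:3] == 255))
  expect_true(all(bin[, 7:10] == 255))
})

test_that("Otsu splits a two-level image and matches the exhaustive oracle", {
  two <- matrix(c(rep(50, 50), rep(200, 50)), 10, 10)
  bin <- otsuThreshold(two)
  expect_true(all(bin[two == 50] == 0) && all(bin[two == 200] == 255))
  for (seed in 1:4) {
    img <- textureImage(24L, 24L, seed + 30L)
    expect_equal(attr(otsuThreshold(img), "threshold"), bruteOtsu(img))
  }
  expect_error(otsuThreshold(matrix(7, 5, 5)), "constant")
})

test_that("largest dark contour: emptiness, perimeter count, maximality", {
  expect_null(largestDarkContour(matrix(255, 20, 20)))
  rect <- matrix(255, 30, 30); rect[10:14, 8:17] <- 0
  pts <- largestDarkContour(rect, 5L)
  expect_equal(nrow(pts), 26)  # perimeter pixels of a 10 x 5 rectangle
  expect_true(all(pts[, "x"] >= 7 & pts[, "x"] <= 16))
  expect_true(all(pts[, "y"] >= 9 & pts[, "y"] <= 13))
  two <- matrix(255, 40, 40); two[5:8, 5:8] <- 0; two[20:29, 20:29] <- 0
  big <- largestDarkContour(two, 5L)
  expect_true(all(big[, "x"] >= 19))
  expect_null(largestDarkContour(two, 100L))
})

test_that("direct ellipse fit recovers exact parameters and rejects junk", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  f <- fitEllipseLSQ(cbind(60 + 30 * cos(th), 40 + 20 * sin(th)))
  expect_equal(f@center, c(60, 40), tolerance = 1e-6)
  expect_equal(f@majorAxis, 60, tolerance = 1e-6)
  expect_equal(f@minorAxis, 40, tolerance = 1e-6)
  expect_equal(f@angle, 0, tolerance = 1e-6)
  a <- 35 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  pts <- t(R %*% t(cbind(30 * cos(th), 20 * sin(th)))) +
    matrix(rep(c(100, 80), each = 12), ncol = 2)
  f2 <- fitEllipseLSQ(pts)
  expect_equal(f2@center, c(100, 80), tolerance = 1e-6)
  expect_equal(f2@angle, 35, tolerance = 1e-6)
  circ <- fitEllipseLSQ(cbind(10 + 5 * cos(th), 10 + 5 * sin(th)))
  expect_equal(circ@majorAxis, circ@minorAxis, tolerance = 1e-6)
  expect_error(fitEllipseLSQ(cbind(1:4, c(2, 3, 5, 7))), "5 points")
  expect_error(fitEllipseLSQ(cbind(1:9, 2 * (1:9))), "degenerate|ellipse")
})

test_that("the circulation recovers a clean embryo at the first valid pair", {
  p <- SceneParams()
  sc <- makeScene(p)
  det <- detectEmbryo(sceneImage(sc))
  expect_true(isAccepted(det))
  expect_lt(centerError(det, sceneTruth(sc)), 5)
  expect_lt(abs(majorAxisLength(det) - 2 * p@embryoAxes[1]) /
              (2 * p@embryoAxes[1]), 0.05)
  pars <- thresholdParams(det)
  expect_true(pars["b"] %in% DetectionConfig()@bRange)
  # deterministic re-run selects the same combination
  det2 <- detectEmbryo(sceneImage(sc))
  expect_equal(thresholdParams(det2), pars)
})

test_that("a blank image exhausts every combination without acceptance", {
  det <- detectEmbryo(matrix(180, 96, 96),
                      DetectionConfig(bRange = c(7L, 11L),
                                      param1Range = c(5, 7)))
  expect_false(isAccepted(det))
  expect_equal(det@nCombinationsTried, 4L)
})

test_that("adaptive and Otsu centers agree on an even bimodal scene", {
  p <- SceneParams(noiseSigma = 0)
  img <- sceneImage(makeScene(p))
  detA <- detectEmbryo(img)
  detO <- detectEmbryoOtsu(img)
  expect_true(isAccepted(detA))
  expect_false(is.null(detO@ellipse))
  expect_lt(sqrt(sum((ellipseCenter(detA) - ellipseCenter(detO))^2)), 2)
})

test_that("uneven illumination needs a block size no smaller than even", {
  p <- SceneParams()
  even <- detectEmbryo(sceneImage(makeScene(p)))
  uneven <- detectEmbryo(sceneImage(
    makeScene(p, IlluminationField("linear", c(1, 1, 0.4, 0.4)))))
  expect_true(isAccepted(even) && isAccepted(uneven))
  expect_gte(thresholdParams(uneven)["b"], thresholdParams(even)["b"])
})
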