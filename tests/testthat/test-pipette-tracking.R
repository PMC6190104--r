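test_that("SSD scores match hand evaluation and the expansion identity", {
  img <- rbind(c(1, 2), c(3, 4))
  tpl <- TipTemplate(matrix(1, 2, 2), 0, 0)
  expect_equal(ssdScore(img, tpl, c(0, 0)), 14)
  # sum f^2 + sum g^2 - 2 sum fg on the same window
  expect_equal(30 + 4 - 2 * 10, 14)
  big <- textureImage(20L, 20L, 12)
  tp2 <- cropTemplate(big, 4, 7, 5, 5)
  expect_equal(ssdScore(big, tp2, c(4, 7)), 0)  # self-match
  expect_error(ssdScore(big, tp2, c(18, 18)), "overhang")
})

test_that("the SSD expansion equals the direct form at every origin", {
  img <- textureImage(24L, 24L, 40)
  tpl <- cropTemplate(img, 5, 5, 6, 6)
  g <- tpl@patch
  for (i in c(0, 7, 18)) for (j in c(0, 9, 18)) {
    f <- img[(i + 1):(i + 6), (j + 1):(j + 6)]
    direct <- sum((f - g)^2)
    expanded <- sum(f^2) + sum(g^2) - 2 * sum(f * g)
    expect_equal(expanded, direct, tolerance = 1e-6)
  }
})

test_that("normalized match: hand value, zero window, gain cancellation", {
  tpl <- TipTemplate(matrix(c(1, 2), 1, 2), 0, 0)
  img <- matrix(c(2, 4), 1, 2)
  expect_equal(normalizedMatchScore(img, tpl, c(0, 0)), sqrt(5))
  expect_equal(normalizedMatchScore(matrix(0, 1, 2), tpl, c(0, 0)), 0)
  # proportional windows score identically
  expect_equal(normalizedMatchScore(img * 0.5, tpl, c(0, 0)),
               normalizedMatchScore(img, tpl, c(0, 0)))
})

test_that("exhaustive search agrees with the naive oracle on both measures", {
  for (seed in 1:3) {
    img <- textureImage(64L, 64L, seed + 50L)
    tpl <- cropTemplate(img, 11, 23, 9, 9)
    for (ms in c("eq9_unnormalized", "eq10_normalized")) {
      got <- locateTemplate(img, tpl, ms)
      ref <- naiveLocate(img, tpl, ms)
      expect_equal(matchOrigin(got), ref$origin)
      expect_equal(matchScore(got), ref$score, tolerance = 1e-9)
    }
  }
})

test_that("a cropped template self-matches exactly at its source", {
  img <- textureImage(48L, 48L, 77)
  tpl <- cropTemplate(img, 17, 9, 8, 10)
  got <- locateTemplate(img, tpl, "eq10_normalized")
  expect_equal(matchOrigin(got), c(17, 9))
  expect_equal(ssdScore(img, tpl, matchOrigin(got)), 0)
})

test_that("ties break to the first origin in row-major order", {
  img <- matrix(10, 40, 60)
  patch <- textureImage(6L, 6L, 91)
  img[5:10, 8:13] <- patch
  img[25:30, 40:45] <- patch
  tpl <- TipTemplate(patch, 0, 0)
  for (ms in c("eq9_unnormalized", "eq10_normalized"))
    expect_equal(matchOrigin(locateTemplate(img, tpl, ms)), c(4, 7))
})

test_that("the normalized measure survives illumination gain; raw may not", {
  base <- matrix(40, 50, 50)
  patch <- round(textureImage(7L, 7L, 13) * 0.4)  # moderate intensities
  base[21:27, 11:17] <- patch
  base[5:14, 35:44] <- 120  # bright distractor block
  tpl <- TipTemplate(patch, 0, 0)
  # global gain keeps the normalized argmax at the true origin
  for (gain in c(0.5, 1, 2)) {
    got <- locateTemplate(base * gain, tpl, "eq10_normalized")
    expect_equal(matchOrigin(got), c(20, 10))
  }
  # the unnormalized correlation chases the bright block instead
  raw <- matchOrigin(locateTemplate(base * 1.5, tpl, "eq9_unnormalized"))
  expect_false(identical(raw, c(20, 10)))
})

test_that("tip offsets translate the match origin as printed", {
  img <- textureImage(64L, 64L, 3)
  tpl <- cropTemplate(img, 30, 12, 7, 9, L = 4, H = 2)
  got <- locateTemplate(img, tpl, "eq10_normalized")
  expect_equal(tipXY(got), c(12 + 4, 30 + 2))
  tpl0 <- cropTemplate(img, 30, 12, 7, 9, L = 0, H = 0)
  expect_equal(locateTip(img, tpl0), c(12, 30))
})

test_that("the rendered pipette tip is recovered within 1 px under noise", {
  p <- SceneParams(imageWidth = 256L, imageHeight = 256L,
                   embryoCenter = c(110, 128), embryoAxes = c(70, 60),
                   pipetteTip = c(205, 85), noiseSigma = 5, seed = 17L)
  img <- sceneImage(makeScene(p))
  tip <- locateTip(img, defaultTipTemplate())
  expect_lte(max(abs(tip - c(205, 85))), 1)
})

test_that("template construction validates its crop rectangle", {
  img <- textureImage(32L, 32L, 2)
  tpl <- makeTipTemplate(img, 4, 6, 10, 8, tip = c(9, 10))
  expect_equal(tpl@offsetL, 5)
  expect_equal(tpl@offsetH, 4)
  expect_identical(dim(tpl@patch), c(8L, 10L))
  expect_error(makeTipTemplate(img, 28, 28, 10, 8, tip = c(30, 30)),
               "outside")
})
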