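test_that("depth of field evaluates the printed formula", {
  expect_equal(depthOfField(OpticsParams(0.1, 40, 0)), 1.75e-3)
  expect_equal(depthOfField(OpticsParams(0.1, 40, 5.5e-4)), 0.02925)
  # both terms shrink when the aperture grows
  expect_lt(depthOfField(OpticsParams(0.2, 40, 5.5e-4)),
            depthOfField(OpticsParams(0.1, 40, 5.5e-4)))
  expect_error(OpticsParams(0, 40, 5.5e-4), "> 0")
})

test_that("triplet trends classify rise, fall, and ties", {
  expect_equal(tripletTrend(c(1, 2, 3)), "increasing")
  expect_equal(tripletTrend(c(3, 2, 1)), "decreasing")
  expect_equal(tripletTrend(c(2, 2, 2), 1e-9), "indeterminate")
  expect_equal(tripletTrend(c(1, 3, 2)), "indeterminate")
  # slack larger than the step suppresses the trend
  expect_equal(tripletTrend(c(1, 1.5, 2), epsilon = 1), "indeterminate")
})

# An analytic stage: sharpness is injected through a tiny synthetic image
# whose Brenner score follows a known unimodal profile.
profileStage <- function(scoreFun) {
  function(z) {
    s <- scoreFun(z)
    matrix(c(rep(100, 4), 100 + sqrt(s / 2), 100, 100 + sqrt(s / 2),
             rep(100, 5)), nrow = 1)
  }
}

test_that("the controller finds an interior peak within one fine step", {
  stage <- profileStage(function(z) 1e4 * exp(-((z - 5000) / 600)^2) + 1)
  cfg <- AutofocusConfig(zMin = 0, zMax = 10000, maxEvaluations = 500L)
  af <- runAutofocus(stage, cfg)
  expect_true(isConverged(af))
  # oracle: exhaustive fine-grid scan of the same stage
  zg <- seq(0, 10000, by = 50)
  sc <- vapply(zg, function(z) brennerScore(stage(z)), numeric(1))
  expect_lte(abs(bestZ(af) - zg[which.max(sc)]), 50)
  expect_lt(nEvaluations(af), length(zg))
  tr <- focusTrace(af)
  expect_true(all(tr$z >= 0 & tr$z <= 10000))
  expect_equal(nrow(tr), nEvaluations(af))
  expect_equal(max(tr$score), af@bestScore)
})

test_that("a monotone score over the range reports non-convergence", {
  inc <- profileStage(function(z) z + 1)
  af <- runAutofocus(inc, AutofocusConfig(zMin = 0, zMax = 3000))
  expect_false(isConverged(af))
  dec <- profileStage(function(z) 3001 - z)
  af2 <- runAutofocus(dec, AutofocusConfig(zMin = 0, zMax = 3000))
  expect_false(isConverged(af2))
})

test_that("a scan starting above focus reverses direction once", {
  stage <- profileStage(function(z) 1e4 * exp(-((z - 1000) / 500)^2) + 1)
  # start on the falling flank, where the downhill trend is measurable
  cfg <- AutofocusConfig(zMin = 0, zMax = 8000, zStart = 2000)
  af <- runAutofocus(stage, cfg)
  expect_true(isConverged(af))
  expect_lte(abs(bestZ(af) - 1000), 50)
})

test_that("evaluation count respects the efficiency bound", {
  stage <- profileStage(function(z) 1e4 * exp(-((z - 2600) / 600)^2) + 1)
  cfg <- AutofocusConfig(zMin = 0, zMax = 6000)
  af <- runAutofocus(stage, cfg)
  bound <- (6000 / 200) + 2 * (200 / 50) + 10
  expect_lte(nEvaluations(af), bound)
})

test_that("the evaluation budget caps the search", {
  stage <- profileStage(function(z) 1e4 * exp(-((z - 5000) / 600)^2) + 1)
  af <- runAutofocus(stage, AutofocusConfig(zMin = 0, zMax = 10000,
                                            maxEvaluations = 8L))
  expect_false(isConverged(af))
  expect_lte(nEvaluations(af), 8L)
})

test_that("a simulated embryo stage focuses to the model's focal plane", {
  sc <- smallSceneAt(2350, seed = 21)
  af <- runAutofocus(simulatedStage(sc), AutofocusConfig())
  expect_true(isConverged(af))
  expect_lte(abs(bestZ(af) - 2350), 50)
})
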