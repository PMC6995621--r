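test_that("the log-log baseline recovers generating coefficients exactly on noise-free data", {
  d <- generateBiomassDataset(n = 400, alpha = 0.01, beta = 2, gamma = 1,
                              noiseCv = 0, seed = 3)
  cf <- fitAllometricBaseline(d)
  expect_equal(cf[["log_alpha"]], log(0.01), tolerance = 1e-10)
  expect_equal(cf[["beta"]], 2, tolerance = 1e-10)
  expect_equal(cf[["gamma"]], 1, tolerance = 1e-10)
})

test_that("a rank-deficient design raises a degenerate-fit error", {
  flat <- data.frame(length_cm = rep(30, 10), width_cm = rep(12, 10),
                     weight_g = stats::runif(10, 500, 600))
  expect_error(fitAllometricBaseline(flat), "degenerate")
  expect_error(fitAllometricBaseline(flat[1:2, ]), "at least 3")
})

test_that("noisy data recovers the length exponent within its sampling error", {
  d <- generateBiomassDataset(n = 400, noiseCv = 0.05, seed = 11)
  cf <- fitAllometricBaseline(d)
  # oracle: the same OLS through lm, with its standard error
  oracle <- stats::lm(log(weight_g) ~ log(length_cm) + log(width_cm),
                      data = d)
  se <- summary(oracle)$coefficients["log(length_cm)", "Std. Error"]
  expect_equal(cf[["beta"]], unname(stats::coef(oracle)[2]), tolerance = 1e-12)
  expect_lt(abs(cf[["beta"]] - 2), 3 * se)
})

test_that("R-squared follows its definition and conventions", {
  expect_identical(evaluateR2(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(1, 2, 3)
  expect_equal(evaluateR2(rep(mean(obs), 3), obs), 0)
  expect_equal(evaluateR2(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_identical(evaluateR2(c(5, 5), c(5, 5)), 1)   # perfect constant fit
  expect_identical(evaluateR2(c(5, 6), c(5, 5)), 0)   # SS_tot = 0 convention
  expect_error(evaluateR2(1:3, 1:4), "equal length")
})

test_that("baseline prediction evaluates the power law and validates inputs", {
  m <- allometricBiomassModel(log(0.01), 2, 1)
  expect_equal(predictWeight(m, 20, 8), 32)
  expect_error(predictWeight(m, -1, 5), "positive")
  untrained <- new("BiomassModel", type = "mlp", architecture = integer(),
                   activation = "relu", weights = list(), biases = list(),
                   xCenter = numeric(2), xScale = c(1, 1), yCenter = 0,
                   yScale = 1, baseline = numeric(3),
                   trainingRange = matrix(0, 2, 2), trained = FALSE,
                   metadata = list())
  expect_error(predictWeight(untrained, 20, 8), "not trained")
})

test_that("the trained network reproduces noise-free weights and the baseline", {
  fit <- cachedNoiseFreeFit()
  expect_identical(length(fit$model@architecture), 9L)
  expect_gte(fit$report@testR2, 0.9997)
  rec <- generateBiomassDataset(n = 400, noiseCv = 0, seed = 7)
  pred <- predictWeight(fit$model, rec$length_cm, rec$width_cm, warn = FALSE)
  expect_lt(max(abs(pred - rec$weight_g) / rec$weight_g), 0.01)
  # agreement with the closed-form baseline across the training range
  g <- expand.grid(L = seq(20, 40, 2), a = seq(0.3, 0.5, 0.05))
  g$W <- g$L * g$a
  base <- allometricBiomassModel()
  relDiff <- abs(predictWeight(fit$model, g$L, g$W, warn = FALSE) -
                 predictWeight(base, g$L, g$W)) / predictWeight(base, g$L, g$W)
  expect_lt(max(relDiff), 0.01)
})

test_that("training is deterministic in the seed", {
  rec <- generateBiomassDataset(n = 60, noiseCv = 0.05, seed = 2)
  a <- fitBiomassMlp(rec, epochs = 30L, seed = 5)
  b <- fitBiomassMlp(rec, epochs = 30L, seed = 5)
  expect_identical(a$model@weights, b$model@weights)
  expect_identical(a$model@biases, b$model@biases)
  c <- fitBiomassMlp(rec, epochs = 30L, seed = 6)
  expect_false(identical(a$model@weights, c$model@weights))
})

test_that("degenerate targets are handled by convention", {
  rec <- generateBiomassDataset(n = 40, noiseCv = 0, seed = 2)
  rec$weight_g <- 500
  fit <- fitBiomassMlp(rec, epochs = 400L, seed = 1)
  pred <- predictWeight(fit$model, rec$length_cm[1:5], rec$width_cm[1:5],
                        warn = FALSE)
  expect_equal(pred, rep(500, 5), tolerance = 0.02)
  bad <- rec
  bad$weight_g[1] <- -1
  expect_error(fitBiomassMlp(bad, seed = 1), "positive")
  expect_error(fitBiomassMlp(rec[1:10, ], seed = 1), "at least 20")
})

test_that("predicted weight increases with each body dimension", {
  base <- allometricBiomassModel()
  L <- seq(20, 40, 1)
  expect_true(all(diff(predictWeight(base, L, rep(10, length(L)))) > 0))
  W <- seq(6, 20, 0.5)
  expect_true(all(diff(predictWeight(base, rep(30, length(W)), W)) > 0))
  # empirical check for the network, with a small slack for fit wiggle
  fit <- cachedNoiseFreeFit()
  pL <- predictWeight(fit$model, L, rep(10, length(L)), warn = FALSE)
  expect_true(all(diff(pL) > -0.002 * pL[-1]))
  pW <- predictWeight(fit$model, rep(30, length(W)), W, warn = FALSE)
  expect_true(all(diff(pW) > -0.002 * pW[-1]))
})

test_that("a saved model predicts bit-identically after reloading", {
  fit <- fitBiomassMlp(generateBiomassDataset(n = 50, seed = 8),
                       epochs = 40L, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  writeBiomassModel(fit$model, path)
  re <- readBiomassModel(path)
  L <- c(21.5, 30.25, 39.9)
  W <- c(7.1, 12.5, 19.2)
  expect_identical(predictWeight(re, L, W, warn = FALSE),
                   predictWeight(fit$model, L, W, warn = FALSE))
  base <- allometricBiomassModel()
  writeBiomassModel(base, path)
  expect_identical(predictWeight(readBiomassModel(path), L, W),
                   predictWeight(base, L, W))
})

test_that("extrapolation far outside the training range warns", {
  fit <- cachedNoiseFreeFit()
  expect_warning(predictWeight(fit$model, 60, 25), "extrapolation")
  expect_silent(predictWeight(fit$model, 30, 12))
})
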