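test_that("R-squared is the squared Pearson correlation", {
  t <- c(1, 2, 3, 5)
  expect_equal(rSquared(t, t), 1.0)
  expect_equal(rSquared(-t, t), 1.0)          # sign is squared away
  expect_equal(rSquared(c(1, 2, 3, 4), c(1, 2, 3, 5)), 169 / 175,
               tolerance = 1e-12)
  expect_warning(r0 <- rSquared(rep(1, 4), t), "zero variance")
  expect_true(is.nan(r0))
  expect_error(rSquared(1:3, 1:4), "mismatch")
  expect_error(rSquared(1, 1), "at least 2")
})

test_that("calibration draws are stratified, disjoint and sized", {
  d <- experimentDesign(nGenotypes = 50)    # 400 plots per environment
  tab <- generatePlotTable(d, seed = 1)
  split <- drawCalibrationSet(tab, "DUN15", fraction = 0.05, seed = 3)
  expect_length(split$calibration, 20)
  trt <- table(tab$treatment[split$calibration])
  expect_equal(as.vector(trt), c(10L, 10L))
  expect_length(intersect(split$calibration, split$test), 0)
  expect_true(all(tab$environment[split$calibration] == "DUN15"))
  expect_equal(length(split$test), nrow(tab) - 20)
  expect_error(drawCalibrationSet(tab, "DUN15", fraction = 1.0, seed = 1),
               "no test samples")
})

test_that("odd counts alternate the treatment receiving the extra sample", {
  tab <- defaultTableFixture()
  s1 <- drawCalibrationSet(tab, "HAL15", count = 21, seed = 1, flip = FALSE)
  s2 <- drawCalibrationSet(tab, "HAL15", count = 21, seed = 1, flip = TRUE)
  t1 <- table(tab$treatment[s1$calibration])
  t2 <- table(tab$treatment[s2$calibration])
  expect_equal(sort(unname(as.vector(t1))), c(10L, 11L))
  expect_equal(sort(unname(as.vector(t2))), c(10L, 11L))
  expect_false(identical(as.vector(t1), as.vector(t2)))
})

test_that("draw invariants hold across many rounds", {
  tab <- defaultTableFixture()
  for (r in 1:20) {
    split <- drawCalibrationSet(tab, c("DUN15", "DUN16"), count = 15,
                                seed = 100 + r, flip = r %% 2 == 0)
    expect_length(split$calibration, 30)
    expect_length(intersect(split$calibration, split$test), 0)
    for (env in c("DUN15", "DUN16")) {
      calEnv <- split$calibration[tab$environment[split$calibration] == env]
      expect_length(calEnv, 15)
      trt <- table(tab$treatment[calEnv])
      expect_lte(abs(trt[1] - trt[2]), 1)
    }
  }
})

test_that("compositions expand the calibration set n, 2n, 4n", {
  se <- defaultSpectraFixture()
  res <- lapply(c("within_environment", "across_years",
                  "across_environments"), function(mode)
    runValidationScheme(se, "N", "pls", compositionDesign(mode, "HAL15"),
                        count = 80, rounds = 1, baseSeed = 1))
  expect_equal(vapply(res, function(r) r$nCal[1], numeric(1)),
               c(80, 160, 320))
})

test_that("validation schemes are deterministic given the base seed", {
  se <- defaultSpectraFixture()
  comp <- compositionDesign("within_environment", "DUN15")
  r1 <- runValidationScheme(se, "N", "pls", comp, fraction = 0.1,
                            rounds = 2, baseSeed = 7)
  r2 <- runValidationScheme(se, "N", "pls", comp, fraction = 0.1,
                            rounds = 2, baseSeed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$seed, c(7L, 8L))
})

test_that("mean R2 grows from small to moderate calibration fractions", {
  se <- defaultSpectraFixture()
  comp <- compositionDesign("within_environment", "DUN16")
  small <- meanR2(runValidationScheme(se, "P", "pls", comp,
                                      fraction = 0.05, rounds = 15,
                                      baseSeed = 3))
  large <- meanR2(runValidationScheme(se, "P", "pls", comp,
                                      fraction = 0.4, rounds = 15,
                                      baseSeed = 3))
  expect_gt(large, small)
})

test_that("leave-one-out pools held-out predictions", {
  se <- linearSpectraFixture(n = 10)
  res <- runLOOScheme(se, "Y", "pls", environment = "DUN15")
  expect_equal(nrow(res), 1)
  expect_equal(res$nModels, 10)
  expect_gt(res$r2, 1 - 1e-6)                 # noise-free linear target
  ## n = 3: pooled result equals three independent held-out fits
  se3 <- linearSpectraFixture(n = 3)
  X <- spectraMatrix(se3)
  y <- plotData(se3)$Y
  manual <- vapply(1:3, function(i) {
    m <- fitPLS(X[-i, , drop = FALSE], y[-i], nComponents = 20)
    predict(m, X[i, , drop = FALSE])
  }, numeric(1))
  res3 <- runLOOScheme(se3, "Y", "pls", environment = "DUN15")
  expect_equal(res3$r2, rSquared(manual, y), tolerance = 1e-10)
})

test_that("the transferability matrix has the contracted layout", {
  se <- defaultSpectraFixture()
  tm <- transferabilityMatrix(se, "Fe", fraction = 0.2, rounds = 2,
                              baseSeed = 5)
  expect_equal(dim(tm), c(7L, 4L))
  expect_equal(rownames(tm), c("DUN15", "DUN16", "HAL15", "HAL16",
                               "DUN1516", "HAL1516", "DUNHAL1516"))
  expect_true(all(is.nan(tm) | (tm >= 0 & tm <= 1)))
})

test_that("transfer succeeds when environment effects are absent", {
  d <- experimentDesign(nGenotypes = 24)
  tab <- generatePlotTable(d, seed = 41)
  se0 <- generateSpectra(tab, spectralModel(d, envEffects = FALSE),
                         seed = 42)
  tm <- transferabilityMatrix(se0, "N", fraction = 0.4, rounds = 4,
                              baseSeed = 2)
  single <- tm[1:4, ]
  offdiag <- mean(single[row(single) != col(single)])
  ondiag <- mean(diag(single))
  expect_lt(abs(ondiag - offdiag), 0.05)
})

test_that("cost-benefit ratios follow the difference quotient", {
  cb <- costBenefit(c(20, 40), c(0.30, 0.40))
  expect_equal(cb$ratio, 0.005)
  cb2 <- costBenefit(c(20, 40, 80), c(0.4, 0.4, 0.4))
  expect_equal(cb2$ratio, c(0, 0))
  expect_error(costBenefit(c(20, 20), c(0.1, 0.2)), "increasing")
  expect_error(costBenefit(20, 0.1), "two sizes")
})

test_that("the log learning curve recovers exact coefficients", {
  n <- c(20, 40, 80, 160, 240, 320)
  r2 <- 0.1 + 0.12 * log(n)
  fit <- fitLogCurve(n, r2)
  expect_equal(fit$a, 0.1, tolerance = 1e-10)
  expect_equal(fit$b, 0.12, tolerance = 1e-10)
  expect_equal(fit$fitR2, 1, tolerance = 1e-10)
  expect_error(fitLogCurve(c(10, 20), c(0.1, 0.2)), "at least 3")
  expect_error(fitLogCurve(c(-1, 2, 3), c(0.1, 0.2, 0.3)), "positive")
})

test_that("failed rounds are recorded as NaN rather than dropped", {
  se <- linearSpectraFixture(n = 8)
  tab <- plotData(se)
  tab$Y <- 1  # constant target: PLS cannot fit
  seBad <- SpectraExperiment(spectraMatrix(se), wavelengths(se), tab,
                             samplesInRows = TRUE)
  res <- suppressWarnings(
    runValidationScheme(seBad, "Y", "pls",
                        compositionDesign("within_environment", "DUN15"),
                        count = 4, rounds = 2, baseSeed = 1))
  expect_warning(
    runValidationScheme(seBad, "Y", "pls",
                        compositionDesign("within_environment", "DUN15"),
                        count = 4, rounds = 1, baseSeed = 1),
    "model failure")
  expect_equal(nrow(res), 2)
  expect_true(all(is.nan(res$r2)))
  expect_equal(attr(meanR2(res), "nExcluded"), 2)
})
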