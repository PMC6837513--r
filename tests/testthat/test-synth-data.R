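test_that("plot table has the designed dimensions and balance", {
  tab <- defaultTableFixture()
  expect_equal(nrow(tab), 48 * 2 * 2 * 2 * 4)
  expect_false(anyDuplicated(tab$plot_id) > 0)
  expect_true(all(c("N", "P", "K", "Mg", "Fe", "Zn") %in% colnames(tab)))
  expect_false(anyNA(tab[, c("N", "P", "K", "Mg", "Fe", "Zn")]))
  ## treatments balanced 1:1 within each environment
  counts <- table(tab$environment, tab$treatment)
  expect_true(all(counts[, 1] == counts[, 2]))
  ## optional check entries extend the genotype set
  d2 <- experimentDesign(nChecks = 2)
  expect_equal(nPlots(d2), (48 + 2) * 2 * 2 * 2 * 4)
  expect_equal(nrow(generatePlotTable(d2, seed = 1)), nPlots(d2))
})

test_that("zero variances collapse every plot to the grand mean", {
  cvs0 <- setNames(rep(0, 6), c("N", "P", "K", "Mg", "Fe", "Zn"))
  d <- experimentDesign(traitCVs = cvs0,
                        envFactors = matrix(1, 6, 4))
  tab <- generatePlotTable(d, seed = 5)
  means <- designVariances(d)$mean
  for (i in seq_along(designTraits(d)))
    expect_equal(tab[[designTraits(d)[i]]], rep(means[i], nrow(tab)))
})

test_that("seeds control the residual draw, not the table shape", {
  d <- experimentDesign(nGenotypes = 6)
  t1 <- generatePlotTable(d, seed = 1)
  t2 <- generatePlotTable(d, seed = 2)
  t3 <- generatePlotTable(d, seed = 1)
  expect_identical(dim(t1), dim(t2))
  expect_identical(t1$plot_id, t2$plot_id)
  expect_false(isTRUE(all.equal(t1$N, t2$N)))
  expect_identical(t1, t3)
})

test_that("invalid designs are rejected", {
  expect_error(experimentDesign(nReplicates = 1), "nReplicates")
  expect_error(experimentDesign(traits = character()), "empty")
})

test_that("variance of genotype means matches Vg + Vge/nEnv", {
  d <- experimentDesign(nGenotypes = 300, nReplicates = 50,
                        traits = "N", traitMeans = c(N = 20),
                        traitCVs = c(N = 11),
                        envFactors = matrix(1, 1, 4))
  tab <- generatePlotTable(d, seed = 31)
  gm <- tapply(tab$N, tab$genotype_id, mean)
  vars <- designVariances(d)
  expected <- vars$Vg + vars$Vge / 4
  expect_lt(abs(var(gm) - expected) / expected, 0.15)
})

test_that("repeatability approaches 1 as residual variance vanishes", {
  d <- experimentDesign(traitVg = c(N = 4), traitVge = c(N = 0),
                        traitVr = c(N = 1e-8), traits = "N",
                        traitMeans = c(N = 20),
                        envFactors = matrix(1, 1, 4))
  tab <- generatePlotTable(d, seed = 8)
  sub <- tab[tab$environment == "DUN15", ]
  vc <- varianceComponents(sub$N, sub$genotype_id, R = 4)
  expect_gt(repeatability(vc), 0.999)
})

test_that("spectra generation is linear in concentrations without noise", {
  d <- defaultDesignFixture()
  m <- spectralModel(d, bandNoiseSd = 0, structureAmp = 0,
                     sampleScatterSd = 0,
                     proxyFrac = setNames(rep(0, 6), designTraits(d)))
  mkTab <- function(conc) {
    tab <- defaultTableFixture()[1, , drop = FALSE]
    for (tr in designTraits(d)) tab[[tr]] <- conc[tr]
    tab
  }
  c0 <- setNames(rep(0, 6), designTraits(d))
  c1 <- c(N = 18, P = 4, K = 5, Mg = 1.2, Fe = 40, Zn = 30)
  c2 <- c(N = 3, P = 1, K = 0.7, Mg = 0.2, Fe = 8, Zn = 6)
  s <- function(conc) spectraMatrix(generateSpectra(mkTab(conc), m, 1))[1, ]
  base <- s(c0)
  expect_equal(s(c1 + c2) - base, (s(c1) - base) + (s(c2) - base),
               tolerance = 1e-12)
})

test_that("without signal and noise each spectrum is scatter*baseline+offset", {
  d <- defaultDesignFixture()
  m <- spectralModel(d, signalAmp = setNames(rep(0, 6), designTraits(d)),
                     bandNoiseSd = 0, structureAmp = 0, sampleScatterSd = 0,
                     proxyFrac = setNames(rep(0, 6), designTraits(d)))
  tab <- defaultTableFixture()[c(1, 400), ]
  X <- spectraMatrix(generateSpectra(tab, m, 1))
  for (i in 1:2) {
    env <- tab$environment[i]
    expect_equal(unname(X[i, ]),
                 m@envScatter[[env]] * m@baseline + m@envOffset[[env]],
                 tolerance = 1e-12)
  }
})

test_that("a concentration difference moves the spectrum along the signature", {
  d <- defaultDesignFixture()
  m <- spectralModel(d, bandNoiseSd = 0, structureAmp = 0,
                     sampleScatterSd = 0,
                     proxyFrac = setNames(rep(0, 6), designTraits(d)))
  tab <- defaultTableFixture()[c(1, 1), ]
  tab$plot_id <- c("A", "B")
  tab$N[2] <- tab$N[1] + 2.5
  X <- spectraMatrix(generateSpectra(tab, m, 1))
  env <- tab$environment[1]
  sig <- signatureMatrix(m, env)[, "N"]
  sensN <- m@sensitivities[["N"]] * m@envSensitivity["N", env]
  expected <- -m@envScatter[[env]] * sensN * 2.5 * sig
  expect_equal(unname(X[2, ] - X[1, ]), expected, tolerance = 1e-12)
})

test_that("same seed gives bit-identical spectra, different seed does not", {
  d <- experimentDesign(nGenotypes = 4)
  tab <- generatePlotTable(d, seed = 3)
  m <- spectralModel(d)
  s1 <- generateSpectra(tab, m, seed = 9)
  s2 <- generateSpectra(tab, m, seed = 9)
  s3 <- generateSpectra(tab, m, seed = 10)
  expect_identical(spectraMatrix(s1), spectraMatrix(s2))
  expect_false(identical(spectraMatrix(s1), spectraMatrix(s3)))
})

test_that("plot table and spectra survive CSV round trips", {
  d <- experimentDesign(nGenotypes = 3)
  tab <- generatePlotTable(d, seed = 2)
  f <- tempfile(fileext = ".csv")
  writePlotTable(tab, f)
  back <- readPlotTable(f)
  expect_equal(back$N, tab$N)
  se <- generateSpectra(tab[1:4, ], spectralModel(d), seed = 2)
  f2 <- tempfile(fileext = ".csv")
  writeSpectra(se, f2)
  se2 <- readSpectra(f2, table = tab[1:4, ])
  expect_equal(spectraMatrix(se2), spectraMatrix(se), tolerance = 1e-12)
  expect_equal(wavelengths(se2), wavelengths(se), tolerance = 1e-9)
})

test_that("synthetic cubes round-trip through reflectance correction", {
  fx <- cubeFixture(noise = FALSE)
  avg <- averageForegroundSpectrum(fx$reflectance, fx$mask)
  expect_equal(avg, fx$spectrum, tolerance = 1e-10)
})

test_that("cube layout respects the white panel and grain count", {
  fx <- cubeFixture()
  expect_false(any(fx$mask[1:12, ]))          # panel rows are background
  g0 <- generateCube(fx$spectrum, fx$model,
                     imageParams = list(height = 40, width = 40,
                                        nGrains = 0, grainRadius = 3),
                     seed = 1)
  expect_false(any(g0$mask))
  expect_error(generateCube(fx$spectrum, fx$model,
                            imageParams = list(height = 20, width = 20,
                                               nGrains = 3,
                                               grainRadius = 15),
                            seed = 1),
               "fit|panel")
})
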