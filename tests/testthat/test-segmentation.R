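twoClusterPixels <- function(n = 200, seed = 4, sdc = 0.05) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n * 3, 0, sdc), n, 3)
    a <- sweep(a, 2, c(0.2, 0.2, 0.2), `+`)
    b <- matrix(rnorm(n * 3, 0, sdc), n, 3)
    b <- sweep(b, 2, c(0.8, 0.7, 0.9), `+`)
    rbind(a, b)
  })
}

test_that("a single Neural Gas prototype converges to the data mean", {
  px <- twoClusterPixels()
  ps <- fitNeuralGas(px, k = 1, seed = 1)
  expect_lt(sqrt(sum((prototypes(ps)[1, ] - colMeans(px))^2)), 0.05)
})

test_that("two prototypes land on the cluster centroids (k-means oracle)", {
  px <- twoClusterPixels()
  ## anneal the neighbourhood fully so the rank-1 pull vanishes
  ps <- fitNeuralGas(px, k = 2, seed = 1,
                     schedule = ngSchedule(iterations = 20000,
                                           lambdaEnd = 0.01,
                                           epsEnd = 1e-3))
  km <- withr::with_seed(2, kmeans(px, centers = 2, nstart = 5))
  W <- prototypes(ps)
  ## match each prototype to its nearest k-means centroid
  for (j in 1:2) {
    dists <- sqrt(rowSums(sweep(km$centers, 2, W[j, ])^2))
    expect_lt(min(dists), 0.05)   # well under the cluster sd
  }
  ## the two prototypes pick different centroids
  asn <- apply(W, 1, function(w)
    which.min(rowSums(sweep(km$centers, 2, w)^2)))
  expect_equal(sort(asn), c(1, 2))
})

test_that("quantisation error does not increase over training", {
  px <- twoClusterPixels()
  ps <- fitNeuralGas(px, k = 3, seed = 5)
  expect_lte(ps@quantisationError[2], ps@quantisationError[1])
})

test_that("duplicated data leaves converged prototypes essentially unchanged", {
  px <- twoClusterPixels(n = 150)
  sch <- ngSchedule(iterations = 20000, epsEnd = 1e-3)
  p1 <- fitNeuralGas(px, k = 2, schedule = sch, seed = 9)
  p2 <- fitNeuralGas(rbind(px, px), k = 2, schedule = sch, seed = 9)
  m1 <- prototypes(p1)[order(prototypes(p1)[, 1]), ]
  m2 <- prototypes(p2)[order(prototypes(p2)[, 1]), ]
  expect_equal(m1, m2, tolerance = 0.15, ignore_attr = TRUE)
})

test_that("cluster assignment matches a brute-force nearest-neighbour scan", {
  px <- withr::with_seed(6, matrix(runif(50 * 4), 50, 4))
  W <- withr::with_seed(7, matrix(runif(3 * 4), 3, 4))
  labels <- assignClusters(px, W)
  brute <- apply(px, 1, function(x)
    which.min(colSums((t(W) - x)^2)))
  expect_equal(labels, brute)
  ## a pixel equal to a prototype gets that prototype's label
  expect_equal(assignClusters(W, W), 1:3)
  ## equidistant pixels resolve to the lowest prototype index
  W2 <- rbind(c(0, 0), c(2, 0), c(0, 2))
  expect_equal(assignClusters(matrix(c(1, 1), 1), W2[c(1, 3), ]), 1L)
  expect_error(assignClusters(px, matrix(numeric(0), 0, 4)), "empty")
})

test_that("cluster labelling follows majority vote or the manual map", {
  labels <- c(1, 1, 1, 2, 2)
  gt <- c(TRUE, TRUE, FALSE, FALSE, FALSE)     # cluster 1 is 2/3 grain
  expect_equal(labelClusters(labels, groundTruth = gt),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(labelClusters(labels, manualMap = c("1" = FALSE, "2" = TRUE)),
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(labelClusters(labels, manualMap = c("1" = TRUE)), "unmapped")
  expect_error(labelClusters(labels), "manual cluster map")
})

test_that("the RBF pixel classifier separates separable classes", {
  px <- twoClusterPixels(sdc = 0.03)
  y <- rep(c(FALSE, TRUE), each = 200)
  clf <- trainPixelClassifier(px, y, nCenters = 4, seed = 1)
  expect_equal(clf@trainAccuracy, 1.0)
  expect_true(all(clf@widths > 0))
  expect_error(trainPixelClassifier(px, rep(TRUE, 400)), "both classes")
})

test_that("shuffled labels reduce the classifier to the class prior", {
  px <- twoClusterPixels()
  yShuf <- withr::with_seed(3, sample(rep(c(FALSE, TRUE), c(280, 120))))
  clf <- trainPixelClassifier(px, yShuf, nCenters = 4, seed = 1)
  expect_lt(abs(clf@trainAccuracy - 0.7), 0.1)
})

test_that("segmentation masks have the cube shape and classify pixels", {
  fx <- cubeFixture()
  clf <- trainSegmentation(fx$reflectance, groundTruth = fx$mask,
                           maxPixels = 5000, seed = 2)
  m <- segmentCube(fx$reflectance, clf)
  expect_equal(dim(maskMatrix(m)), dim(fx$mask))
  expect_gt(mean(maskMatrix(m) == fx$mask), 0.98)
  ## an all-background cube yields an empty mask
  g0 <- generateCube(fx$spectrum, fx$model,
                     imageParams = list(height = 40, width = 40,
                                        nGrains = 0, grainRadius = 3),
                     seed = 3)
  m0 <- segmentCube(correctReflectance(g0$cube), clf)
  expect_false(any(maskMatrix(m0)[13:40, ]))   # below the panel: background
  untrained <- new("PixelClassifier", centers = matrix(0, 1, 2),
                   widths = 1, weights = c(0, 0), threshold = 0.5,
                   trained = FALSE, trainAccuracy = NA_real_)
  expect_error(segmentCube(fx$reflectance, untrained), "not trained")
})

test_that("classifier scores are equivariant under pixel permutation", {
  px <- twoClusterPixels()
  y <- rep(c(FALSE, TRUE), each = 200)
  clf <- trainPixelClassifier(px, y, nCenters = 4, seed = 1)
  perm <- withr::with_seed(8, sample(nrow(px)))
  expect_equal(classifierScores(clf, px[perm, ]),
               classifierScores(clf, px)[perm])
})

test_that("foreground averaging reduces to the pixel mean", {
  arr <- array(0, dim = c(2, 2, 2))
  arr[1, 1, ] <- c(0.2, 0.5)
  arr[2, 1, ] <- c(0.4, 0.7)
  rc <- new("ReflectanceCube", values = arr, wavelengths = c(1, 2),
            clipMax = 1.1, nClipped = 0L, source = "t")
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(averageForegroundSpectrum(rc, m1), c(0.2, 0.5))
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(averageForegroundSpectrum(rc, m2), c(0.3, 0.6))
  expect_error(averageForegroundSpectrum(rc, m2 & FALSE), "empty mask")
})

test_that("masks survive PNG and CSV round trips", {
  fx <- cubeFixture()
  f <- tempfile(fileext = ".png")
  writeMaskPNG(fx$mask, f)
  expect_equal(readMaskPNG(f), fx$mask, ignore_attr = TRUE)
  f2 <- tempfile(fileext = ".csv")
  writeMaskCSV(fx$mask, f2)
  back <- as.matrix(read.csv(f2, header = FALSE)) == 1
  expect_equal(unname(back), unname(fx$mask))
})

test_that("pixel classifiers survive the JSON round trip", {
  px <- twoClusterPixels()
  y <- rep(c(FALSE, TRUE), each = 200)
  clf <- trainPixelClassifier(px, y, nCenters = 4, seed = 1)
  f <- tempfile(fileext = ".json")
  savePixelClassifier(clf, f)
  back <- loadPixelClassifier(f)
  expect_equal(classifierScores(back, px), classifierScores(clf, px),
               tolerance = 1e-12)
})
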