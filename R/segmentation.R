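## Grain/background segmentation: Neural Gas clustering of pixel spectra
## into material groups, cluster labelling, and an RBF pixel classifier
## applied per cube.

#' Default Neural Gas annealing schedule
#'
#' Martinetz-style exponential decay over a fixed number of single-sample
#' presentations: the neighbourhood range lambda 10 -> 0.5 and the step
#' size epsilon 0.5 -> 0.005.
#'
#' @param iterations number of sample presentations
#' @param lambdaStart,lambdaEnd neighbourhood range decay endpoints
#' @param epsStart,epsEnd learning-rate decay endpoints
#' @return schedule list
#' @export
ngSchedule <- function(iterations = 10000, lambdaStart = 10,
                       lambdaEnd = 0.5, epsStart = 0.5, epsEnd = 0.005) {
  stopifnot(iterations >= 1, lambdaStart >= lambdaEnd, lambdaEnd > 0,
            epsStart >= epsEnd, epsEnd > 0)
  list(iterations = as.integer(iterations), lambdaStart = lambdaStart,
       lambdaEnd = lambdaEnd, epsStart = epsStart, epsEnd = epsEnd)
}

#' Cluster pixel spectra with the Neural Gas algorithm
#'
#' Classic Neural Gas: for each randomly presented pixel spectrum all k
#' prototypes are ranked by Euclidean distance and prototype of rank r
#' (0-based) moves toward the input by `eps * exp(-r / lambda)`, with
#' `eps` and `lambda` decayed exponentially from their start to end values
#' over the schedule.
#'
#' @param pixels pixels x bands matrix
#' @param k number of prototypes (default 3: grain, table surface, white
#'   panel)
#' @param schedule see [ngSchedule()]
#' @param seed integer seed (prototype init and presentation order)
#' @return a [PrototypeSet-class]
#' @export
fitNeuralGas <- function(pixels, k = 3, schedule = ngSchedule(), seed = 1) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (k > n) stop("k must not exceed the number of pixels")
  if (schedule$iterations < 1) stop("schedule needs at least one iteration")
  Tmax <- schedule$iterations
  quantErr <- function(W) {
    idx <- if (n > 5000) seq(1, n, length.out = 5000) else seq_len(n)
    D <- prototypeDistances(pixels[idx, , drop = FALSE], W)
    mean(sqrt(apply(D, 1, min)))
  }
  withr::with_seed(as.integer(seed), {
    W <- pixels[sample.int(n, k), , drop = FALSE]
    e0 <- quantErr(W)
    present <- sample.int(n, Tmax, replace = TRUE)
    frac <- (seq_len(Tmax) - 1) / max(Tmax - 1, 1)
    lambda <- schedule$lambdaStart *
      (schedule$lambdaEnd / schedule$lambdaStart)^frac
    eps <- schedule$epsStart * (schedule$epsEnd / schedule$epsStart)^frac
    for (t in seq_len(Tmax)) {
      x <- pixels[present[t], ]
      diffs <- sweep(W, 2, x)                 # k x p
      d2 <- rowSums(diffs^2)
      rank0 <- rank(d2, ties.method = "first") - 1
      W <- W - (eps[t] * exp(-rank0 / lambda[t])) * diffs
    }
  })
  new("PrototypeSet", prototypes = W, schedule = schedule,
      quantisationError = c(e0, quantErr(W)))
}

## squared Euclidean distances, rows of X to rows of W
prototypeDistances <- function(X, W) {
  D <- outer(rowSums(X^2), rowSums(W^2), `+`) - 2 * X %*% t(W)
  pmax(D, 0)
}

#' Assign pixels to their nearest prototype
#'
#' Euclidean nearest-prototype labels; ties resolved toward the lowest
#' prototype index.
#'
#' @param pixels pixels x bands matrix
#' @param prototypes a [PrototypeSet-class] or k x bands matrix
#' @return integer label vector (1-based prototype indices)
#' @export
assignClusters <- function(pixels, prototypes) {
  W <- if (is(prototypes, "PrototypeSet")) prototypes@prototypes
  else as.matrix(prototypes)
  if (nrow(W) == 0) stop("empty prototype set")
  D <- prototypeDistances(as.matrix(pixels), W)
  max.col(-D, ties.method = "first")
}

#' Map cluster labels to foreground/background pixel labels
#'
#' In synthetic mode each cluster is labelled by majority vote against the
#' ground-truth grain mask; in real mode a manual cluster -> class map is
#' supplied (mirroring the manual selection of the grain cluster in the
#' original workflow).
#'
#' @param labels integer cluster labels per pixel
#' @param groundTruth logical vector (or matrix) of true grain pixels
#' @param manualMap named logical vector, `TRUE` = grain, names = cluster
#'   indices
#' @return logical foreground label per pixel
#' @export
labelClusters <- function(labels, groundTruth = NULL, manualMap = NULL) {
  ids <- sort(unique(labels))
  if (!is.null(groundTruth)) {
    gt <- as.vector(groundTruth)
    stopifnot(length(gt) == length(labels))
    fg <- vapply(ids, function(id) mean(gt[labels == id]) > 0.5, logical(1))
    names(fg) <- ids
  } else {
    if (is.null(manualMap) || length(manualMap) == 0)
      stop("manual cluster map required when no ground truth is given")
    missing <- setdiff(as.character(ids), names(manualMap))
    if (length(missing))
      stop("unmapped cluster id(s): ", paste(missing, collapse = ", "))
    fg <- manualMap
  }
  unname(fg[as.character(labels)])
}

#' Train the RBF pixel classifier
#'
#' Radial-basis-function network for binary grain/background pixel
#' classification: centers initialised by k-means run within each class,
#' a shared Gaussian width set to the median inter-center distance, and
#' output weights solved by ridge-regularised least squares on the
#' Gaussian activations against 0/1 targets.
#'
#' @param pixels pixels x bands matrix
#' @param labels logical (or 0/1) foreground labels
#' @param nCenters total number of RBF centers (split between the classes)
#' @param seed integer seed for the k-means initialisation
#' @param ridge ridge penalty on the output weights
#' @param threshold decision threshold on the continuous output
#' @return a [PixelClassifier-class]
#' @export
trainPixelClassifier <- function(pixels, labels, nCenters = 10, seed = 1,
                                 ridge = 1e-6, threshold = 0.5) {
  pixels <- as.matrix(pixels)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2)
    stop("both classes must be present to train the classifier")
  perClass <- c(floor(nCenters / 2), ceiling(nCenters / 2))
  centers <- withr::with_seed(as.integer(seed), {
    rbind(classCenters(pixels[y == 0, , drop = FALSE], perClass[1]),
          classCenters(pixels[y == 1, , drop = FALSE], perClass[2]))
  })
  d <- dist(centers)
  width <- if (length(d)) median(d) else 1
  if (width <= 0) width <- 1
  Phi <- rbfActivations(pixels, centers, width)
  A <- cbind(1, Phi)
  wts <- solve(crossprod(A) + ridge * diag(ncol(A)), crossprod(A, y))
  pred <- as.vector(A %*% wts) >= threshold
  new("PixelClassifier", centers = centers,
      widths = rep(width, nrow(centers)), weights = as.vector(wts),
      threshold = threshold, trained = TRUE,
      trainAccuracy = mean(pred == (y >= 0.5)))
}

classCenters <- function(X, k) {
  k <- min(k, nrow(unique(X)))
  if (k <= 1) return(matrix(colMeans(X), 1))
  kmeans(X, centers = k, nstart = 1, iter.max = 100,
         algorithm = "Lloyd")$centers
}

rbfActivations <- function(X, centers, width) {
  D <- prototypeDistances(as.matrix(X), centers)
  exp(-D / (2 * width^2))
}

#' Continuous classifier output for a pixel matrix
#' @param clf a [PixelClassifier-class]
#' @param pixels pixels x bands matrix
#' @return numeric scores; compare against `clf@threshold`
#' @export
classifierScores <- function(clf, pixels) {
  if (!clf@trained) stop("classifier is not trained")
  Phi <- rbfActivations(pixels, clf@centers, clf@widths[1])
  as.vector(cbind(1, Phi) %*% clf@weights)
}

#' Segment a reflectance cube into grain and background
#'
#' @param cube a [ReflectanceCube-class]
#' @param clf a trained [PixelClassifier-class]
#' @return a [SegmentationMask-class]
#' @export
segmentCube <- function(cube, clf) {
  if (!clf@trained) stop("classifier is not trained")
  if (ncol(clf@centers) != length(cube@wavelengths))
    stop("band count differs between cube and classifier")
  scores <- classifierScores(clf, pixelMatrix(cube))
  d <- dim(cube@values)
  new("SegmentationMask",
      mask = matrix(scores >= clf@threshold, d[1], d[2]),
      provenance = sprintf("RBF classifier on '%s'", cube@source))
}

#' Average spectrum over the foreground pixels of a cube
#'
#' The per-sample regression input: per-band mean reflectance over grain
#' pixels.
#'
#' @param cube a [ReflectanceCube-class]
#' @param mask a [SegmentationMask-class] or logical matrix
#' @return per-band mean foreground spectrum
#' @export
averageForegroundSpectrum <- function(cube, mask) {
  m <- if (is(mask, "SegmentationMask")) mask@mask else mask
  d <- dim(cube@values)
  stopifnot(all(dim(m) == d[1:2]))
  if (!any(m)) stop("empty mask: sample is unusable")
  px <- pixelMatrix(cube)
  colMeans(px[as.vector(m), , drop = FALSE])
}

#' Train the full segmentation stage on one cube
#'
#' Convenience wrapper: subsample pixels, cluster them with Neural Gas,
#' label clusters (ground truth or manual map), and train the RBF pixel
#' classifier.
#'
#' @param cube a [ReflectanceCube-class]
#' @param groundTruth logical grain matrix (synthetic mode), or NULL
#' @param manualMap manual cluster map (real mode), see [labelClusters()]
#' @param k number of material clusters; the default 4 gives the grain
#'   material two prototypes (bright and dark grain pixels under
#'   per-pixel brightness variation) next to table surface and white
#'   panel
#' @param maxPixels pixel subsample bound for training
#' @param schedule Neural Gas schedule
#' @param nCenters RBF centers of the classifier
#' @param seed integer seed
#' @return a [PixelClassifier-class]
#' @export
trainSegmentation <- function(cube, groundTruth = NULL, manualMap = NULL,
                              k = 4, maxPixels = 20000,
                              schedule = ngSchedule(), nCenters = 10,
                              seed = 1) {
  px <- pixelMatrix(cube)
  idx <- if (nrow(px) > maxPixels)
    withr::with_seed(as.integer(seed), sample.int(nrow(px), maxPixels))
  else seq_len(nrow(px))
  sub <- px[idx, , drop = FALSE]
  protos <- fitNeuralGas(sub, k = k, schedule = schedule, seed = seed)
  cl <- assignClusters(sub, protos)
  gt <- if (is.null(groundTruth)) NULL else as.vector(groundTruth)[idx]
  fg <- labelClusters(cl, groundTruth = gt, manualMap = manualMap)
  trainPixelClassifier(sub, fg, nCenters = nCenters, seed = seed)
}

#' Write / read a segmentation mask
#'
#' PNG masks are written as 0/255 grayscale; CSV masks as a 0/1 matrix.
#'
#' @param mask a [SegmentationMask-class] or logical matrix
#' @param path file path
#' @return `readMaskPNG` returns a logical matrix
#' @export
writeMaskPNG <- function(mask, path) {
  m <- if (is(mask, "SegmentationMask")) mask@mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img >= 0.5
}

#' @rdname writeMaskPNG
#' @export
writeMaskCSV <- function(mask, path) {
  m <- if (is(mask, "SegmentationMask")) mask@mask else mask
  write.table(m * 1, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Save / load a pixel classifier as JSON
#'
#' @param clf a [PixelClassifier-class]
#' @param path JSON file path
#' @return `loadPixelClassifier` returns a [PixelClassifier-class]
#' @export
savePixelClassifier <- function(clf, path) {
  obj <- list(type = "pixel-classifier", bands = ncol(clf@centers),
              nCenters = nrow(clf@centers),
              centers = as.vector(clf@centers), widths = clf@widths,
              weights = clf@weights, threshold = clf@threshold,
              trainAccuracy = clf@trainAccuracy)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname savePixelClassifier
#' @export
loadPixelClassifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PixelClassifier",
      centers = matrix(as.numeric(obj$centers), obj$nCenters, obj$bands),
      widths = as.numeric(obj$widths), weights = as.numeric(obj$weights),
      threshold = as.numeric(obj$threshold), trained = TRUE,
      trainAccuracy = as.numeric(obj$trainAccuracy))
}
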