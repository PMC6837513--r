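## Multi-layer perceptron regression trained by Levenberg-Marquardt.
## Two tanh hidden layers (30 and 10 units by default), linear output.
## The Jacobian of the per-sample outputs with respect to all weights is
## assembled by backpropagation; the damping factor is divided by 10 on
## accepted steps and multiplied by 10 on rejected ones.

mlpForward <- function(layers, Xc) {
  Z1 <- tanh(sweep(Xc %*% layers[[1]]$W, 2, layers[[1]]$b, `+`))
  Z2 <- tanh(sweep(Z1 %*% layers[[2]]$W, 2, layers[[2]]$b, `+`))
  f <- as.vector(Z2 %*% layers[[3]]$W) + layers[[3]]$b
  list(Z1 = Z1, Z2 = Z2, f = f)
}

mlpPack <- function(layers) {
  c(as.vector(layers[[1]]$W), layers[[1]]$b,
    as.vector(layers[[2]]$W), layers[[2]]$b,
    as.vector(layers[[3]]$W), layers[[3]]$b)
}

mlpUnpack <- function(theta, p, h) {
  i <- 0
  take <- function(k) { v <- theta[(i + 1):(i + k)]; i <<- i + k; v }
  l1 <- list(W = matrix(take(p * h[1]), p, h[1]), b = take(h[1]))
  l2 <- list(W = matrix(take(h[1] * h[2]), h[1], h[2]), b = take(h[2]))
  l3 <- list(W = matrix(take(h[2]), h[2], 1), b = take(1))
  list(l1, l2, l3)
}

## Jacobian d f_i / d theta by backprop; columns ordered as mlpPack.
mlpJacobian <- function(layers, Xc, fw) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  h1 <- ncol(fw$Z1)
  h2 <- ncol(fw$Z2)
  w3 <- as.vector(layers[[3]]$W)
  d2 <- (1 - fw$Z2^2) * matrix(w3, n, h2, byrow = TRUE)      # n x h2
  d1 <- (d2 %*% t(layers[[2]]$W)) * (1 - fw$Z1^2)            # n x h1
  JW1 <- Xc[, rep(seq_len(p), times = h1), drop = FALSE] *
    d1[, rep(seq_len(h1), each = p), drop = FALSE]
  JW2 <- fw$Z1[, rep(seq_len(h1), times = h2), drop = FALSE] *
    d2[, rep(seq_len(h2), each = h1), drop = FALSE]
  cbind(JW1, d1, JW2, d2, fw$Z2, rep(1, n))
}

#' Fit a multi-layer perceptron regressor
#'
#' Two hidden layers with hyperbolic-tangent activations and a linear
#' output unit, trained by Levenberg-Marquardt minimisation of the
#' training MSE: at each epoch the update solves
#' `(J'J + lambda I) delta = -J'e`; `lambda` shrinks tenfold on accepted
#' steps and grows tenfold on rejections. Accepted steps never increase
#' the training MSE; training stops at the policy's epoch budget, when the
#' MSE improvement falls below the policy tolerance, or when `lambda`
#' overflows. Weights are initialised from a scaled uniform distribution
#' (Nguyen-Widrow-style range), so runs are reproducible given the seed.
#'
#' @param X calibration spectra, samples x bands
#' @param y trait concentrations
#' @param hidden hidden layer sizes (default c(30, 10))
#' @param policy a [trainingPolicy()]
#' @param seed integer seed (overrides the policy seed when given)
#' @return an [MLPRegressor-class]
#' @export
fitMLP <- function(X, y, hidden = c(30L, 10L), policy = trainingPolicy(),
                   seed = policy$seed) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("need at least 2 training samples")
  h <- as.integer(hidden)
  stopifnot(length(h) == 2, all(h >= 1))
  xMean <- colMeans(X)
  yMean <- mean(y)
  Xc <- sweep(X, 2, xMean)
  yc <- y - yMean
  layers <- withr::with_seed(as.integer(seed), {
    rng <- function(fanIn, nUnits) {
      s <- 0.7 * nUnits^(1 / fanIn) / sqrt(fanIn)
      matrix(runif(fanIn * nUnits, -s, s), fanIn, nUnits)
    }
    list(list(W = rng(p, h[1]), b = runif(h[1], -0.1, 0.1)),
         list(W = rng(h[1], h[2]), b = runif(h[2], -0.1, 0.1)),
         list(W = rng(h[2], 1), b = runif(1, -0.1, 0.1)))
  })
  theta <- mlpPack(layers)
  fw <- mlpForward(layers, Xc)
  e <- fw$f - yc
  mse <- mean(e^2)
  if (!is.finite(mse)) stop("non-finite loss at initialisation")
  trace <- mse
  lambda <- 1e-3
  nTheta <- length(theta)
  for (epoch in seq_len(policy$maxEpochs)) {
    J <- mlpJacobian(layers, Xc, fw)
    JtJ <- crossprod(J)
    Jte <- crossprod(J, e)
    accepted <- FALSE
    while (lambda <= 1e10) {
      delta <- tryCatch(
        solve(JtJ + lambda * diag(nTheta), -Jte),
        error = function(err) NULL)
      if (!is.null(delta)) {
        thetaNew <- theta + as.vector(delta)
        layersNew <- mlpUnpack(thetaNew, p, h)
        fwNew <- mlpForward(layersNew, Xc)
        eNew <- fwNew$f - yc
        mseNew <- mean(eNew^2)
        if (!is.finite(mseNew))
          stop("non-finite loss during training (diverged)")
        if (mseNew <= mse) {
          theta <- thetaNew
          layers <- layersNew
          fw <- fwNew
          e <- eNew
          improved <- mse - mseNew
          mse <- mseNew
          trace <- c(trace, mse)
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) break
    if (improved < policy$mseDeltaTol) break
  }
  new("MLPRegressor", layers = layers, hidden = h, xMean = xMean,
      yMean = yMean, trace = trace, seed = as.integer(seed))
}

#' @rdname predict-methods
#' @export
setMethod("predict", "MLPRegressor", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(numeric(0))
  if (ncol(newdata) != length(object@xMean))
    stop("band count differs from the training data")
  Xc <- sweep(newdata, 2, object@xMean)
  object@yMean + mlpForward(object@layers, Xc)$f
})
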