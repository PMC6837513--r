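## RBF network regression: Gaussian kernel mixture over learned prototype
## spectra, refined by nonlinear conjugate gradient on the training MSE.

#' Training policy for the iterative regressors
#'
#' Shared stopping rule of the neural back-ends: optimisation halts after
#' `maxEpochs` accepted steps or when the decrease in training MSE falls
#' below `mseDeltaTol`.
#'
#' @param maxEpochs epoch budget (default 1000)
#' @param mseDeltaTol MSE convergence threshold (default 1e-5)
#' @param optimizer optimiser tag, informational ("cg" or "lm")
#' @param seed integer seed for parameter initialisation
#' @return a policy list
#' @export
trainingPolicy <- function(maxEpochs = 1000, mseDeltaTol = 1e-5,
                           optimizer = "cg", seed = 1L) {
  stopifnot(maxEpochs >= 1, mseDeltaTol > 0)
  list(maxEpochs = as.integer(maxEpochs), mseDeltaTol = mseDeltaTol,
       optimizer = optimizer, seed = as.integer(seed))
}

rbfPack <- function(C, logw, w) c(as.vector(C), logw, w)
rbfUnpack <- function(theta, m, p) {
  list(C = matrix(theta[seq_len(m * p)], m, p),
       logw = theta[m * p + seq_len(m)],
       w = theta[m * p + m + seq_len(m + 1)])
}

#' Fit an RBF network regressor
#'
#' Models the response as a weighted mixture of Gaussian kernels around
#' prototype spectra (Euclidean metric). Centers are initialised by
#' k-means on the calibration spectra, widths from nearest-center
#' distances and output weights by ridge-regularised least squares; all
#' parameters are then refined jointly by Polak-Ribiere conjugate-gradient
#' descent with Armijo backtracking on the training MSE until the policy's
#' stopping rule fires. The per-epoch MSE trace is stored and is
#' non-increasing over accepted steps.
#'
#' @param X calibration spectra, samples x bands
#' @param y trait concentrations
#' @param nBasis number of Gaussian basis centers (default 20; capped at
#'   the number of training samples)
#' @param policy a [trainingPolicy()]
#' @param seed integer seed (overrides the policy seed when given)
#' @return an [RBFRegressor-class]
#' @export
fitRBFRegressor <- function(X, y, nBasis = 20, policy = trainingPolicy(),
                            seed = policy$seed) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("need at least 2 training samples")
  if (all(apply(X, 2, sd) == 0)) stop("degenerate X: zero variance")
  xMean <- colMeans(X)
  yMean <- mean(y)
  Xc <- sweep(X, 2, xMean)
  if (sd(y) == 0) {
    ## constant response: the mixture degenerates to the intercept
    return(new("RBFRegressor", centers = matrix(0, 1, p),
               widths = 1, weights = c(0, 0), xMean = xMean, yMean = yMean,
               trace = 0, seed = as.integer(seed)))
  }
  yc <- y - yMean
  m <- min(nBasis, max(2, n - 1), nrow(unique(Xc)))
  C <- withr::with_seed(as.integer(seed), {
    if (m > 1) kmeans(Xc, centers = m, nstart = 1, iter.max = 50)$centers
    else matrix(colMeans(Xc), 1)
  })
  m <- nrow(C)
  if (m > 1) {
    D0 <- as.matrix(dist(C))
    diag(D0) <- Inf
    widths <- apply(D0, 1, min)
    widths[widths <= 0] <- median(widths[widths > 0])
    if (all(widths <= 0 | !is.finite(widths))) widths <- rep(1, m)
  } else widths <- max(sd(as.vector(Xc)), 1e-3)
  logw <- log(pmax(widths, 1e-6))
  Phi <- exp(-sweep(prototypeDistances(Xc, C), 2, 2 * exp(2 * logw), `/`))
  A <- cbind(1, Phi)
  w0 <- as.vector(solve(crossprod(A) + 1e-6 * diag(m + 1),
                        crossprod(A, yc)))
  theta <- rbfPack(C, logw, w0)
  objective <- function(th) {
    par <- rbfUnpack(th, m, p)
    sig2 <- exp(2 * par$logw)
    D <- prototypeDistances(Xc, par$C)
    Phi <- exp(-sweep(D, 2, 2 * sig2, `/`))
    f <- par$w[1] + as.vector(Phi %*% par$w[-1])
    mean((f - yc)^2)
  }
  gradient <- function(th) {
    par <- rbfUnpack(th, m, p)
    sig2 <- exp(2 * par$logw)
    D <- prototypeDistances(Xc, par$C)
    Phi <- exp(-sweep(D, 2, 2 * sig2, `/`))
    f <- par$w[1] + as.vector(Phi %*% par$w[-1])
    r <- 2 * (f - yc) / length(yc)
    gw <- c(sum(r), as.vector(crossprod(Phi, r)))
    wphiR <- sweep(Phi * r, 2, par$w[-1], `*`)          # n x m
    colR <- colSums(wphiR)
    ## d phi_ij / d c_j = phi_ij (x_i - c_j) / sig_j^2, hence
    ## d mse / d c_j = (1/sig_j^2) (sum_i wphiR_ij x_i - colR_j c_j)
    gC <- crossprod(Xc, wphiR) - sweep(t(par$C), 2, colR, `*`)
    gC <- sweep(gC, 2, sig2, `/`)                        # p x m
    glogw <- colSums(wphiR * D) / sig2
    rbfPack(t(gC), glogw, gw)
  }
  res <- cgMinimize(theta, objective, gradient,
                    maxEpochs = policy$maxEpochs,
                    tol = policy$mseDeltaTol)
  par <- rbfUnpack(res$theta, m, p)
  new("RBFRegressor", centers = par$C, widths = exp(par$logw),
      weights = par$w, xMean = xMean, yMean = yMean,
      trace = res$trace, seed = as.integer(seed))
}

## Polak-Ribiere+ nonlinear conjugate gradient with Armijo backtracking.
## Returns the parameter vector and the MSE trace over accepted steps.
cgMinimize <- function(theta, fn, gr, maxEpochs, tol, c1 = 1e-4) {
  f0 <- fn(theta)
  trace <- f0
  g <- gr(theta)
  d <- -g
  alpha <- 1 / (1 + sqrt(sum(g^2)))
  for (epoch in seq_len(maxEpochs)) {
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- -sum(g^2) }
    if (-gd < 1e-18) break
    a <- alpha * 2
    fNew <- Inf
    for (ls in 1:40) {
      cand <- theta + a * d
      fNew <- fn(cand)
      if (is.finite(fNew) && fNew <= f0 + c1 * a * gd) break
      a <- a / 2
    }
    if (!is.finite(fNew) || fNew > f0 + c1 * a * gd) break  # no step found
    alpha <- a
    theta <- theta + a * d
    gNew <- gr(theta)
    betaPR <- max(0, sum(gNew * (gNew - g)) / max(sum(g^2), 1e-30))
    d <- -gNew + betaPR * d
    g <- gNew
    improved <- f0 - fNew
    f0 <- fNew
    trace <- c(trace, f0)
    if (improved < tol) break
  }
  list(theta = theta, trace = trace)
}

#' @rdname predict-methods
#' @export
setMethod("predict", "RBFRegressor", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(numeric(0))
  if (ncol(newdata) != length(object@xMean))
    stop("band count differs from the training data")
  Xc <- sweep(newdata, 2, object@xMean)
  D <- prototypeDistances(Xc, object@centers)
  Phi <- exp(-sweep(D, 2, 2 * object@widths^2, `/`))
  object@yMean + object@weights[1] +
    as.vector(Phi %*% object@weights[-1])
})
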