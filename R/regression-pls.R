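## NIPALS partial least squares, single response.
##
## Predictors are mean-centered but not variance-scaled (reflectance bands
## share units); the response is mean-centered. Both X and y are deflated
## after each component.

#' Fit a PLS regression model by NIPALS
#'
#' Single-response partial least squares: components are extracted by the
#' NIPALS iteration on centered X and y, deflating both after each
#' component. The number of components actually used is capped at
#' `min(nComponents, n - 1, n_bands)` and extraction stops early when the
#' residual covariance collapses (rank bound). Prediction uses the
#' equivalent coefficient vector `beta = W (P'W)^{-1} q`.
#'
#' @param X calibration spectra, samples x bands
#' @param y trait concentrations, length nrow(X)
#' @param nComponents requested number of latent components (default 20)
#' @param tol NIPALS convergence / rank tolerance (default 1e-10)
#' @param maxInner maximum inner NIPALS iterations per component (relevant
#'   only for multi-response extensions; the single-response iteration
#'   converges in one pass)
#' @return a [PLSModel-class]
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' y <- X[, 1] - 2 * X[, 5] + rnorm(20, 0, 0.1)
#' m <- fitPLS(X, y, nComponents = 5)
#' cor(predict(m, X), y)
#' @export
fitPLS <- function(X, y, nComponents = 20, tol = 1e-10, maxInner = 500) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("need at least 2 training samples")
  if (anyNA(X) || anyNA(y)) stop("NA values in the training data")
  if (sd(y) == 0) stop("constant response: nothing to regress on")
  A <- min(nComponents, n - 1, p)
  xMean <- colMeans(X)
  yMean <- mean(y)
  Xc <- sweep(X, 2, xMean)
  yc <- y - yMean
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  aUsed <- 0
  for (a in seq_len(A)) {
    ## NIPALS inner iteration with u = deflated y; for a single response
    ## the score direction is fixed after the first pass, so the loop
    ## exits on the convergence check at the second iteration.
    u <- yc
    w <- NULL
    tscore <- tOld <- NULL
    for (it in seq_len(maxInner)) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tscore <- Xc %*% w
      if (!is.null(tOld) && sqrt(sum((tscore - tOld)^2)) < tol) break
      tOld <- tscore
    }
    if (is.null(tscore) || sqrt(sum(w^2)) == 0) break
    tt <- sum(tscore^2)
    if (tt < tol) break
    pLoad <- crossprod(Xc, tscore) / tt
    qa <- sum(yc * tscore) / tt
    Xc <- Xc - tscore %*% t(pLoad)
    yc <- yc - as.vector(tscore) * qa
    W[, a] <- w
    P[, a] <- pLoad
    Tm[, a] <- tscore
    q[a] <- qa
    aUsed <- a
  }
  if (aUsed == 0) stop("no PLS component could be extracted")
  W <- W[, seq_len(aUsed), drop = FALSE]
  P <- P[, seq_len(aUsed), drop = FALSE]
  Tm <- Tm[, seq_len(aUsed), drop = FALSE]
  q <- q[seq_len(aUsed)]
  beta <- as.vector(W %*% solve(t(P) %*% W, q))
  fitted <- yMean + as.vector(sweep(X, 2, xMean) %*% beta)
  new("PLSModel", nComponents = as.integer(aUsed), weights = W,
      loadings = P, yLoadings = q, coefficients = beta, scores = Tm,
      xMean = xMean, yMean = yMean,
      trace = mean((fitted - y)^2), seed = NA_integer_)
}

#' Predict trait values from spectra
#'
#' @param object a fitted [PLSModel-class], [RBFRegressor-class] or
#'   [MLPRegressor-class]
#' @param newdata samples x bands matrix with the training band count
#' @param ... ignored
#' @return numeric predictions, one per row of `newdata`
#' @rdname predict-methods
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(numeric(0))
  if (ncol(newdata) != length(object@xMean))
    stop("band count differs from the training data")
  object@yMean +
    as.vector(sweep(newdata, 2, object@xMean) %*% object@coefficients)
})

#' Training score matrix of a PLS model
#' @param model a [PLSModel-class]
#' @return n x A matrix of component scores
#' @export
plsScores <- function(model) model@scores
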