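## Shared regression plumbing: a tag-based dispatcher used by the
## evaluation layer and JSON (de)serialisation of fitted models.

#' Fit a regression back-end by tag
#'
#' Dispatches to [fitPLS()], [fitRBFRegressor()] or [fitMLP()]. The PLS
#' component count is capped at `n - 1` for small calibration sets.
#'
#' @param X calibration spectra, samples x bands
#' @param y trait concentrations
#' @param model back-end tag: "pls", "rbf" or "mlp"
#' @param nComponents PLS component request (default 20)
#' @param nBasis RBF basis count (default 20)
#' @param hidden MLP hidden layer sizes (default c(30, 10))
#' @param policy training policy for the iterative back-ends
#' @param seed integer seed for the stochastic back-ends
#' @return a fitted model object
#' @export
fitModel <- function(X, y, model = c("pls", "rbf", "mlp"),
                     nComponents = 20, nBasis = 20, hidden = c(30L, 10L),
                     policy = trainingPolicy(), seed = 1L) {
  model <- match.arg(model)
  switch(model,
         pls = fitPLS(X, y, nComponents = nComponents),
         rbf = fitRBFRegressor(X, y, nBasis = nBasis, policy = policy,
                               seed = seed),
         mlp = fitMLP(X, y, hidden = hidden, policy = policy, seed = seed))
}

#' Serialise a fitted model to JSON
#'
#' Writes a documented JSON schema: a `type` tag, array shapes, flattened
#' parameter arrays, the centering vectors and the seed. [loadModel()]
#' reconstructs an equivalent model object.
#'
#' @param model a fitted [PLSModel-class], [RBFRegressor-class] or
#'   [MLPRegressor-class]
#' @param path output JSON path
#' @return invisibly, the path
#' @export
saveModel <- function(model, path) {
  obj <- if (is(model, "PLSModel")) {
    list(type = "pls", nComponents = model@nComponents,
         bands = length(model@xMean),
         weights = as.vector(model@weights),
         loadings = as.vector(model@loadings),
         yLoadings = model@yLoadings,
         coefficients = model@coefficients)
  } else if (is(model, "RBFRegressor")) {
    list(type = "rbf", nBasis = nrow(model@centers),
         bands = ncol(model@centers),
         centers = as.vector(model@centers), widths = model@widths,
         weights = model@weights)
  } else if (is(model, "MLPRegressor")) {
    list(type = "mlp", hidden = model@hidden,
         bands = length(model@xMean), theta = mlpPack(model@layers))
  } else stop("unsupported model class: ", class(model))
  obj$xMean <- model@xMean
  obj$yMean <- model@yMean
  if (!is.na(model@seed)) obj$seed <- model@seed
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nb <- obj$bands
  common <- list(xMean = as.numeric(obj$xMean), yMean = as.numeric(obj$yMean),
                 trace = NA_real_,
                 seed = if (is.null(obj$seed) || is.na(obj$seed))
                   NA_integer_ else as.integer(obj$seed))
  switch(obj$type,
    pls = {
      A <- obj$nComponents
      new("PLSModel", nComponents = as.integer(A),
          weights = matrix(obj$weights, nb, A),
          loadings = matrix(obj$loadings, nb, A),
          yLoadings = as.numeric(obj$yLoadings),
          coefficients = as.numeric(obj$coefficients),
          scores = matrix(numeric(0), 0, 0),
          xMean = common$xMean, yMean = common$yMean,
          trace = common$trace, seed = common$seed)
    },
    rbf = new("RBFRegressor",
              centers = matrix(obj$centers, obj$nBasis, nb),
              widths = as.numeric(obj$widths),
              weights = as.numeric(obj$weights),
              xMean = common$xMean, yMean = common$yMean,
              trace = common$trace, seed = common$seed),
    mlp = new("MLPRegressor",
              layers = mlpUnpack(as.numeric(obj$theta), nb,
                                 as.integer(obj$hidden)),
              hidden = as.integer(obj$hidden),
              xMean = common$xMean, yMean = common$yMean,
              trace = common$trace, seed = common$seed),
    stop("unknown model type in ", path))
}
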