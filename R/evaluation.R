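## Resampling-based evaluation of calibration designs: random calibration
## draws stratified by N treatment, validation rounds over a grid of
## calibration fractions, multi-environment composition designs,
## leave-one-out, the transferability matrix, cost-benefit ratios and the
## logarithmic learning-curve fit.

#' Squared Pearson correlation between predictions and targets
#'
#' The prediction-performance measure: the square of the Pearson
#' correlation coefficient between predicted and true trait values. A
#' perfect prediction gives 1.0. If either vector has zero variance the
#' correlation is undefined and NaN is returned with a warning (the NaN
#' sentinel is excluded from means downstream rather than conflated with
#' an R-squared of 0).
#'
#' @param pred predicted values
#' @param target true values
#' @return squared correlation in `[0, 1]`, or NaN
#' @export
rSquared <- function(pred, target) {
  if (length(pred) != length(target)) stop("length mismatch")
  if (length(pred) < 2) stop("need at least 2 pairs")
  if (sd(pred) == 0 || sd(target) == 0) {
    warning("zero variance in predictions or targets; R^2 undefined")
    return(NaN)
  }
  cor(pred, target)^2
}

#' Describe a calibration-set composition
#'
#' Three composition modes for drawing a calibration set aimed at a
#' target environment: `within_environment` draws only from the target
#' environment (n samples), `across_years` adds the other year of the
#' same location with equal counts (2n), and `across_environments` draws
#' equally from all environments (4n).
#'
#' @param mode composition mode
#' @param target target environment label (e.g. "HAL15")
#' @return composition object
#' @export
compositionDesign <- function(mode = c("within_environment", "across_years",
                                       "across_environments"),
                              target) {
  structure(list(mode = match.arg(mode), target = target),
            class = "compositionDesign")
}

## Resolve the contributing environments of a composition from the table.
compositionEnvironments <- function(composition, table) {
  envs <- unique(table$environment)
  target <- composition$target
  if (!target %in% envs) stop("unknown target environment: ", target)
  switch(composition$mode,
         within_environment = target,
         across_years = {
           loc <- table$location[match(target, table$environment)]
           sort(unique(table$environment[table$location == loc]))
         },
         across_environments = sort(envs))
}

#' Draw a calibration / test split
#'
#' Random calibration draw stratified 1:1 by treatment within each
#' contributing environment, ignoring genotype replication. With an odd
#' per-environment count the extra sample goes to the first treatment, or
#' to the second when `flip` is TRUE (validation rounds alternate the
#' flip so neither treatment is favoured). All remaining rows form the
#' test set.
#'
#' @param table plot table
#' @param environments contributing environment labels
#' @param fraction calibration fraction of each environment's samples
#'   (exclusive with `count`)
#' @param count per-environment calibration count
#' @param seed integer seed
#' @param flip whether the second treatment receives the odd extra sample
#' @return list with integer row indices `calibration` and `test`
#' @export
drawCalibrationSet <- function(table, environments, fraction = NULL,
                               count = NULL, seed = 1, flip = FALSE) {
  if (is.null(fraction) == is.null(count))
    stop("give exactly one of fraction or count")
  cal <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (env in environments) {
      rows <- which(table$environment == env)
      trt <- table$treatment[rows]
      lv <- sort(unique(trt))
      if (length(lv) < 2)
        stop("environment ", env, " has a single treatment; ",
             "1:1 stratification impossible")
      nEnv <- if (is.null(count)) round(fraction * length(rows)) else count
      if (nEnv < 2) stop("calibration count below 2 in ", env)
      if (nEnv >= length(rows))
        stop("calibration would leave no test samples in ", env)
      nPer <- c(floor(nEnv / 2), ceiling(nEnv / 2))
      if (!flip) nPer <- rev(nPer)
      for (k in 1:2) {
        pool <- rows[trt == lv[k]]
        if (nPer[k] > length(pool))
          stop("treatment ", lv[k], " in ", env,
               " has too few samples for the requested draw")
        cal <- c(cal, sample(pool, nPer[k]))
      }
    }
  })
  cal <- sort(cal)
  list(calibration = cal, test = setdiff(seq_len(nrow(table)), cal))
}

## Fit + predict one validation round; NaN R^2 on model failure.
evaluateRound <- function(X, y, calIdx, testIdx, model, modelArgs, seed) {
  fit <- tryCatch(
    do.call(fitModel, c(list(X = X[calIdx, , drop = FALSE], y = y[calIdx],
                             model = model, seed = seed), modelArgs)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("model failure in round (seed ", seed, "): ",
            conditionMessage(fit))
    return(list(r2 = NaN, fit = NULL))
  }
  pred <- predict(fit, X[testIdx, , drop = FALSE])
  list(r2 = suppressWarnings(rSquared(pred, y[testIdx])), fit = fit)
}

#' Run a randomised validation scheme
#'
#' For each round a calibration set is drawn per the composition (equal
#' stratified counts from every contributing environment), the model is
#' fitted, and the target environment's non-calibration samples are
#' predicted. Each round records the R-squared and the trait value range
#' covered by the calibration set. Round seeds are `baseSeed + round - 1`,
#' so schemes are reproducible and individual rounds re-runnable. A model
#' failure in a round is recorded as NaN, not dropped.
#'
#' @param spectra a [SpectraExperiment]
#' @param trait trait column name
#' @param model back-end tag ("pls", "rbf", "mlp")
#' @param composition a [compositionDesign()]
#' @param fraction per-environment calibration fraction (exclusive with
#'   `count`)
#' @param count per-environment calibration count
#' @param rounds validation rounds (default 100)
#' @param baseSeed base integer seed
#' @param modelArgs extra arguments passed to [fitModel()]
#' @return data.frame with one row per round (trait, model, composition,
#'   target, fraction, nCal, round, seed, r2, calRange)
#' @export
runValidationScheme <- function(spectra, trait, model = "pls",
                                composition, fraction = NULL, count = NULL,
                                rounds = 100, baseSeed = 1,
                                modelArgs = list()) {
  table <- plotData(spectra)
  stopifnot(trait %in% colnames(table))
  X <- spectraMatrix(spectra)
  y <- table[[trait]]
  envs <- compositionEnvironments(composition, table)
  targetRows <- which(table$environment == composition$target)
  out <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    seed <- as.integer(baseSeed + r - 1)
    split <- drawCalibrationSet(table, envs, fraction = fraction,
                                count = count, seed = seed,
                                flip = r %% 2 == 0)
    testIdx <- intersect(split$test, targetRows)
    res <- evaluateRound(X, y, split$calibration, testIdx, model,
                         modelArgs, seed)
    out[[r]] <- data.frame(
      trait = trait, model = model, composition = composition$mode,
      target = composition$target,
      fraction = if (is.null(fraction)) NA_real_ else fraction,
      nCal = length(split$calibration), round = r, seed = seed,
      r2 = res$r2, calRange = diff(range(y[split$calibration])))
  }
  do.call(rbind, out)
}

#' Leave-one-out validation within one environment
#'
#' Trains n models, each on n - 1 samples of the environment, predicting
#' the held-out sample; reports a single R-squared pooled over the n
#' (prediction, target) pairs. No random drawing is involved. (In
#' reporting, this scheme is conventionally labelled "99%".)
#'
#' @param spectra a [SpectraExperiment]
#' @param trait trait column name
#' @param model back-end tag
#' @param environment environment to evaluate
#' @param modelArgs extra arguments passed to [fitModel()]
#' @return data.frame with one row: pooled r2 and nModels = n
#' @export
runLOOScheme <- function(spectra, trait, model = "pls", environment,
                         modelArgs = list()) {
  table <- plotData(spectra)
  rows <- which(table$environment == environment)
  n <- length(rows)
  if (n < 3) stop("need at least 3 samples for leave-one-out")
  X <- spectraMatrix(spectra)
  y <- table[[trait]]
  preds <- numeric(n)
  for (i in seq_len(n)) {
    cal <- rows[-i]
    fit <- do.call(fitModel, c(list(X = X[cal, , drop = FALSE], y = y[cal],
                                    model = model, seed = 1L), modelArgs))
    preds[i] <- predict(fit, X[rows[i], , drop = FALSE])
  }
  data.frame(trait = trait, model = model, composition = "loo",
             target = environment, fraction = NA_real_, nCal = n - 1,
             round = NA_integer_, seed = NA_integer_,
             r2 = rSquared(preds, y[rows]), calRange = diff(range(y[rows])),
             nModels = n)
}

#' Transferability matrix over seven calibration models
#'
#' Trains the seven standard calibration compositions (four single
#' environments, two across-years per location, one across all four
#' environments) and evaluates each against every environment's
#' out-of-training samples, averaging the R-squared over rounds. Row
#' order: the four single environments, the two across-years models, the
#' across-environments model.
#'
#' @param spectra a [SpectraExperiment] covering four environments
#' @param trait trait column name
#' @param model back-end tag
#' @param fraction per-environment calibration fraction
#' @param rounds validation rounds (default 100)
#' @param baseSeed base seed
#' @param modelArgs extra arguments passed to [fitModel()]
#' @return 7 x 4 matrix of mean R-squared (training model x predicted
#'   environment)
#' @export
transferabilityMatrix <- function(spectra, trait, model = "pls",
                                  fraction = 0.4, rounds = 100,
                                  baseSeed = 1, modelArgs = list()) {
  table <- plotData(spectra)
  envs <- sort(unique(table$environment))
  if (length(envs) != 4) stop("expected exactly four environments")
  locs <- vapply(envs, function(e)
    table$location[match(e, table$environment)], character(1))
  byLoc <- split(envs, locs)
  if (length(byLoc) != 2) stop("expected exactly two locations")
  trainingSets <- c(as.list(envs),
                    unname(byLoc),
                    list(envs))
  labels <- c(envs,
              vapply(byLoc, function(e)
                paste0(substr(e[1], 1, 3),
                       paste(substr(e, 4, 5), collapse = "")),
                character(1)),
              paste0(paste(sort(unique(substr(envs, 1, 3))), collapse = ""),
                     paste(sort(unique(substr(envs, 4, 5))), collapse = "")))
  X <- spectraMatrix(spectra)
  y <- table[[trait]]
  acc <- matrix(0, length(trainingSets), length(envs),
                dimnames = list(unname(labels), unname(envs)))
  cnt <- acc
  for (r in seq_len(rounds)) {
    seed <- as.integer(baseSeed + r - 1)
    for (m in seq_along(trainingSets)) {
      split <- drawCalibrationSet(table, trainingSets[[m]],
                                  fraction = fraction, seed = seed,
                                  flip = r %% 2 == 0)
      fit <- tryCatch(
        do.call(fitModel,
                c(list(X = X[split$calibration, , drop = FALSE],
                       y = y[split$calibration], model = model,
                       seed = seed), modelArgs)),
        error = function(e) NULL)
      for (e in seq_along(envs)) {
        testIdx <- intersect(split$test,
                             which(table$environment == envs[e]))
        r2 <- if (is.null(fit)) NaN
        else suppressWarnings(
          rSquared(predict(fit, X[testIdx, , drop = FALSE]), y[testIdx]))
        if (is.finite(r2)) {
          acc[m, e] <- acc[m, e] + r2
          cnt[m, e] <- cnt[m, e] + 1
        }
      }
    }
  }
  acc / pmax(cnt, 1)
}

#' Cost-benefit ratios between consecutive calibration set sizes
#'
#' Per consecutive size pair, the gain in mean prediction performance per
#' added calibration sample:
#' `(meanR2_larger - meanR2_smaller) / (n_larger - n_smaller)`.
#'
#' @param sizes strictly increasing calibration sizes
#' @param meanR2 mean R-squared at each size
#' @return data.frame with columns nFrom, nTo, deltaR2, deltaN, ratio
#' @export
costBenefit <- function(sizes, meanR2) {
  stopifnot(length(sizes) == length(meanR2))
  if (length(sizes) < 2) stop("need at least two sizes")
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  i <- seq_len(length(sizes) - 1)
  data.frame(nFrom = sizes[i], nTo = sizes[i + 1],
             deltaR2 = meanR2[i + 1] - meanR2[i],
             deltaN = sizes[i + 1] - sizes[i],
             ratio = (meanR2[i + 1] - meanR2[i]) / (sizes[i + 1] - sizes[i]))
}

#' Logarithmic learning-curve fit
#'
#' Least-squares fit of `meanR2 = a + b * ln(n)` describing the gain in
#' prediction performance with calibration set size, plus the squared
#' correlation between fitted and observed values.
#'
#' @param sizes calibration sizes (> 0, at least 3)
#' @param meanR2 mean R-squared at each size
#' @return list with a, b and fitR2
#' @export
fitLogCurve <- function(sizes, meanR2) {
  if (length(sizes) < 3) stop("need at least 3 sizes")
  if (any(sizes <= 0)) stop("sizes must be positive")
  fit <- lm(meanR2 ~ log(sizes))
  list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
       fitR2 = suppressWarnings(rSquared(fitted(fit), meanR2)))
}

#' Mean R-squared of an evaluation result, excluding NaN sentinels
#'
#' @param result data.frame from [runValidationScheme()]
#' @return mean of the finite per-round R-squared values; the number of
#'   excluded rounds is attached as attribute `nExcluded`
#' @export
meanR2 <- function(result) {
  v <- result$r2
  structure(mean(v[is.finite(v)]), nExcluded = sum(!is.finite(v)))
}
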