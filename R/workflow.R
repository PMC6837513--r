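## Configuration-driven orchestration: run the full evaluation grid from a
## YAML config, write tidy CSVs, summaries and a manifest.

RUNCONFIG_KEYS <- c("mode", "design", "spectralModel", "table", "spectra",
                    "traits", "models", "fractions", "compositions",
                    "targets", "rounds", "baseSeed", "outputDir",
                    "transferability", "transferabilityFraction")

#' Read and validate a run configuration
#'
#' YAML with keys: `mode` (synthetic | real), `design` (synthetic-mode
#' arguments for [experimentDesign()] plus `seed`), `spectralModel`
#' (noise arguments for [spectralModel()]), `table`/`spectra` (real-mode
#' CSV paths), `traits`, `models`, `fractions` (numeric, may include the
#' string "loo"), `compositions`, `targets` (target environments;
#' default all), `rounds`, `baseSeed`, `outputDir`, `transferability`
#' (logical), `transferabilityFraction`.
#'
#' @param path YAML file path
#' @return validated config list
#' @export
readRunConfig <- function(path) {
  config <- yaml::read_yaml(path)
  validateRunConfig(config)
}

validateRunConfig <- function(config) {
  unknown <- setdiff(names(config), RUNCONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config$mode <- if (is.null(config$mode)) "synthetic" else config$mode
  if (!config$mode %in% c("synthetic", "real"))
    stop("mode must be 'synthetic' or 'real'")
  if (is.null(config$traits) || !length(config$traits))
    stop("at least one trait is required")
  if (is.null(config$models) || !length(config$models))
    stop("at least one model is required")
  bad <- setdiff(unlist(config$models), c("pls", "rbf", "mlp"))
  if (length(bad))
    stop("unknown model tag(s): ", paste(bad, collapse = ", "))
  if (is.null(config$fractions) || !length(config$fractions))
    stop("at least one calibration fraction is required")
  if (is.null(config$compositions))
    config$compositions <- "within_environment"
  badC <- setdiff(unlist(config$compositions),
                  c("within_environment", "across_years",
                    "across_environments"))
  if (length(badC))
    stop("unknown composition(s): ", paste(badC, collapse = ", "))
  if (is.null(config$rounds)) config$rounds <- 100L
  if (is.null(config$baseSeed)) config$baseSeed <- 1L
  if (is.null(config$outputDir)) stop("outputDir is required")
  if (is.null(config$transferability)) config$transferability <- FALSE
  config
}

## Polynomial rolling hash over the serialised config, for the manifest.
configHash <- function(config) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(config, auto_unbox = TRUE)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

loadExperimentData <- function(config) {
  if (config$mode == "synthetic") {
    dArgs <- config$design
    seed <- if (!is.null(dArgs$seed)) dArgs$seed else config$baseSeed
    dArgs$seed <- NULL
    design <- do.call(experimentDesign, if (is.null(dArgs)) list()
                      else dArgs)
    table <- generatePlotTable(design, seed = seed)
    smArgs <- c(list(design = design), config$spectralModel)
    model <- do.call(spectralModel, smArgs)
    generateSpectra(table, model, seed = seed + 1)
  } else {
    if (is.null(config$table) || is.null(config$spectra))
      stop("real mode requires 'table' and 'spectra' paths")
    table <- readPlotTable(config$table)
    readSpectra(config$spectra, table = table)
  }
}

#' Run the full evaluation experiment described by a config
#'
#' Generates (or loads) the sample table and spectra, runs every
#' combination of trait, model, composition, target environment and
#' calibration fraction through [runValidationScheme()] (or
#' [runLOOScheme()] for the "loo" entry), and writes per-combination tidy
#' CSVs, a summary table, optional transferability matrices, cost-benefit
#' and log-curve fits per learning curve, model comparison reports, a
#' JSON manifest (config, hash, seeds, package version) and a run log
#' under `outputDir`. Failing combinations are logged and skipped, not
#' fatal.
#'
#' @param config config list from [readRunConfig()] (or an equivalent
#'   list, which is validated first)
#' @return invisibly, the output directory
#' @export
runExperiment <- function(config) {
  config <- validateRunConfig(config)
  out <- config$outputDir
  dir.create(file.path(out, "results"), recursive = TRUE,
             showWarnings = FALSE)
  logLines <- c(sprintf("speccal run %s", format(Sys.time())),
                sprintf("config hash %s", configHash(config)))
  note <- function(...) logLines <<- c(logLines, sprintf(...))
  spectra <- loadExperimentData(config)
  table <- plotData(spectra)
  targets <- if (!is.null(config$targets)) unlist(config$targets)
  else sort(unique(table$environment))
  allRes <- list()
  for (trait in unlist(config$traits))
    for (model in unlist(config$models))
      for (comp in unlist(config$compositions))
        for (target in targets)
          for (fr in unlist(config$fractions)) {
            tag <- sprintf("%s_%s_%s_%s_%s", trait, model, comp, target,
                           fr)
            res <- tryCatch({
              if (identical(fr, "loo"))
                runLOOScheme(spectra, trait, model, environment = target)
              else
                runValidationScheme(spectra, trait, model,
                                    composition =
                                      compositionDesign(comp, target),
                                    fraction = as.numeric(fr),
                                    rounds = config$rounds,
                                    baseSeed = config$baseSeed)
            }, error = function(e) {
              note("FAILED %s: %s", tag, conditionMessage(e))
              NULL
            })
            if (!is.null(res)) {
              f <- file.path(out, "results", paste0(tag, ".csv"))
              write.csv(res, f, row.names = FALSE)
              note("wrote %s (%d rounds, mean R2 %.3f)", basename(f),
                   nrow(res), meanR2(res))
              allRes[[tag]] <- res
            }
          }
  if (length(allRes)) {
    combined <- do.call(rbind, lapply(allRes, function(r)
      r[, setdiff(colnames(r), "nModels"), drop = FALSE]))
    write.csv(combined, file.path(out, "results", "all_rounds.csv"),
              row.names = FALSE)
    summary <- summarizeRounds(combined)
    write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)
    ## learning-curve and cost-benefit analysis per within-environment curve
    curves <- split(summary, list(summary$trait, summary$model,
                                  summary$target, summary$composition),
                    drop = TRUE)
    lcRows <- list()
    for (cu in curves) {
      cu <- cu[is.finite(cu$fraction) & is.finite(cu$meanR2), ]
      cu <- cu[order(cu$nCal), ]
      if (nrow(cu) >= 3 && all(diff(cu$nCal) > 0)) {
        fitv <- fitLogCurve(cu$nCal, cu$meanR2)
        cb <- costBenefit(cu$nCal, cu$meanR2)
        lcRows[[length(lcRows) + 1]] <- data.frame(
          trait = cu$trait[1], model = cu$model[1],
          target = cu$target[1], composition = cu$composition[1],
          a = fitv$a, b = fitv$b, fitR2 = fitv$fitR2,
          lastRatio = cb$ratio[nrow(cb)])
      }
    }
    if (length(lcRows))
      write.csv(do.call(rbind, lcRows),
                file.path(out, "learning_curves.csv"), row.names = FALSE)
    ## model comparison on the per-round correlations, per stratum
    models <- unique(combined$model)
    if (length(models) > 1) {
      strata <- split(combined,
                      list(combined$trait, combined$target,
                           combined$fraction, combined$composition),
                      drop = TRUE)
      reps <- Filter(Negate(is.null), lapply(strata, function(s) {
        gs <- split(sqrt(pmax(s$r2, 0)), s$model)
        gs <- lapply(gs, function(g) g[is.finite(g)])
        if (length(gs) < 2 || any(vapply(gs, length, integer(1)) < 2))
          return(NULL)
        rep <- compareGroups(gs)
        data.frame(trait = s$trait[1], target = s$target[1],
                   fraction = s$fraction[1],
                   composition = s$composition[1],
                   group = rep$labels, mean = rep$means,
                   letters = rep$letters[rep$labels], F = rep$F, p = rep$p)
      }))
      if (length(reps))
        write.csv(do.call(rbind, reps),
                  file.path(out, "model_comparison.csv"),
                  row.names = FALSE)
    }
  }
  if (isTRUE(config$transferability)) {
    frT <- if (!is.null(config$transferabilityFraction))
      config$transferabilityFraction else 0.4
    for (trait in unlist(config$traits)) {
      tm <- transferabilityMatrix(spectra, trait,
                                  model = unlist(config$models)[1],
                                  fraction = frT, rounds = config$rounds,
                                  baseSeed = config$baseSeed)
      write.csv(tm, file.path(out,
                              sprintf("transferability_%s.csv", trait)))
      note("wrote transferability matrix for %s", trait)
    }
  }
  manifest <- list(package = "speccal",
                   version = as.character(utils::packageVersion("speccal")),
                   configHash = configHash(config), config = config,
                   baseSeed = config$baseSeed,
                   roundSeeds = sprintf("baseSeed + round - 1 (rounds 1..%d)",
                                        config$rounds),
                   nSamples = nrow(table))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(logLines, file.path(out, "run.log"))
  invisible(out)
}

summarizeRounds <- function(combined) {
  key <- list(trait = combined$trait, model = combined$model,
              composition = combined$composition,
              target = combined$target, fraction = combined$fraction,
              nCal = combined$nCal)
  agg <- aggregate(combined$r2, by = key,
                   FUN = function(v) c(mean = mean(v[is.finite(v)]),
                                       sd = sd(v[is.finite(v)]),
                                       nNaN = sum(!is.finite(v))),
                   drop = TRUE)
  out <- agg[, names(key)]
  out$meanR2 <- agg$x[, "mean"]
  out$sdR2 <- agg$x[, "sd"]
  out$nExcluded <- agg$x[, "nNaN"]
  out <- out[order(out$trait, out$model, out$composition, out$target,
                   out$nCal), ]
  ## delta vs the next-smaller size within each curve
  out$deltaR2 <- NA_real_
  grp <- interaction(out$trait, out$model, out$composition, out$target,
                     drop = TRUE)
  for (g in levels(grp)) {
    i <- which(grp == g)
    if (length(i) > 1)
      out$deltaR2[i[-1]] <- diff(out$meanR2[i])
  }
  out
}

#' Summarise a finished experiment directory
#'
#' Reads the per-round results written by [runExperiment()] and returns
#' mean/sd R-squared by trait, model, composition, target and size, with
#' the delta against the next-smaller calibration size.
#'
#' @param dir experiment output directory containing `manifest.json`
#' @return summary data.frame (empty, with headers, when no results
#'   exist)
#' @export
summarizeResults <- function(dir) {
  if (!file.exists(file.path(dir, "manifest.json")))
    stop("no manifest.json in ", dir, "; not an experiment directory")
  f <- file.path(dir, "results", "all_rounds.csv")
  if (!file.exists(f))
    return(data.frame(trait = character(), model = character(),
                      composition = character(), target = character(),
                      fraction = numeric(), nCal = integer(),
                      meanR2 = numeric(), sdR2 = numeric(),
                      nExcluded = integer(), deltaR2 = numeric()))
  summarizeRounds(read.csv(f, stringsAsFactors = FALSE))
}
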