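## Generative spectral model and the SpectraExperiment container.
##
## Average grain reflectance is modelled as a smooth baseline minus
## nutrient-specific Gaussian absorption signatures scaled by
## concentration, wrapped in per-environment effects (smooth multiplicative
## scatter, additive offset, signature wavelength shifts and sensitivity
## multipliers, standing in for moisture/matrix differences between
## location-years) plus per-sample structured interference and band noise.

gaussBump <- function(wl, center, width) exp(-((wl - center) / width)^2)

## Fixed absorption-band parameters per trait (centers/widths in nm).
## Bands sit in the NIR overtone region; values are stylised, not assayed.
SIGNATURE_PARAMS <- list(
  N  = list(centers = c(1510, 2180), widths = c(40, 55), weights = c(0.6, 1)),
  P  = list(centers = 1650,          widths = 45,        weights = 1),
  K  = list(centers = 1765,          widths = 50,        weights = 1),
  Mg = list(centers = 2050,          widths = 45,        weights = 1),
  Fe = list(centers = 1250,          widths = 50,        weights = 1),
  Zn = list(centers = c(1360, 2320), widths = c(40, 60), weights = c(1, 0.5)))

## Spectral effect amplitude (reflectance units) produced by one standard
## deviation of each trait's concentration. Nitrogen (protein) dominates;
## minerals are weaker, indirect signals.
DEFAULT_SIGNAL_AMP <- c(N = 0.045, P = 0.012, K = 0.011, Mg = 0.010,
                        Fe = 0.011, Zn = 0.011)

## Spectral proxy error per trait as a fraction of the concentration sd.
## Caps the asymptotic R^2 near 1/(1 + frac^2): ~0.93 for N, ~0.6 for the
## minerals.
DEFAULT_PROXY_FRAC <- c(N = 0.18, P = 0.80, K = 0.80, Mg = 0.80,
                        Fe = 0.80, Zn = 0.80)

## Per-environment sensitivity multipliers (traits x 4 environments).
DEFAULT_ENV_SENSITIVITY <- matrix(c(
  1.10, 0.92, 1.05, 0.95,
  0.95, 1.08, 0.90, 1.06,
  1.06, 0.94, 1.08, 0.92,
  0.92, 1.05, 0.96, 1.08,
  1.08, 0.90, 1.04, 0.96,
  0.94, 1.06, 0.92, 1.08), nrow = 6, byrow = TRUE,
  dimnames = list(DEFAULT_TRAITS, NULL))

#' Construct the generative spectral model
#'
#' Builds a [SpectralModel-class] matched to an [ExperimentDesign-class]:
#' a 288-band wavelength grid from 970 to 2500 nm, a smooth grain baseline
#' with water absorption features, per-trait Gaussian absorption signatures
#' whose sensitivities are scaled so that one concentration standard
#' deviation moves the spectrum by `signalAmp` reflectance units, and
#' per-environment scatter/offset/shift effects that make calibrations
#' environment-specific.
#'
#' @param design the [ExperimentDesign-class] the model accompanies
#' @param nBands number of spectral bands (default 288)
#' @param wlRange wavelength range in nm (default 970-2500)
#' @param signalAmp named per-trait spectral amplitude per concentration sd
#' @param proxyFrac named per-trait spectral proxy error, as a fraction of
#'   the concentration sd: the spectrum responds to `conc + proxy error`,
#'   so the asymptotic prediction R-squared is capped near
#'   `1 / (1 + proxyFrac^2)`. Nitrogen (sensed directly through protein
#'   N-H bonds) has a small proxy error; the minerals, sensed only through
#'   correlated organic complexes, a substantial one.
#' @param bandNoiseSd sd of independent per-band noise
#' @param structureAmp sd of per-sample coefficients on the smooth
#'   interference basis (grain geometry / moisture variation)
#' @param sampleScatterSd sdlog of per-sample multiplicative scatter jitter
#' @param pixelJitterSd sdlog of per-pixel grain brightness jitter used by
#'   [generateCube()]
#' @param envEffects logical; FALSE zeroes all environment effects
#'   (identical scatter, offsets, shifts and sensitivities everywhere)
#' @return a [SpectralModel-class]
#' @export
spectralModel <- function(design = experimentDesign(), nBands = 288,
                          wlRange = c(970, 2500),
                          signalAmp = DEFAULT_SIGNAL_AMP,
                          proxyFrac = DEFAULT_PROXY_FRAC,
                          bandNoiseSd = 8e-4, structureAmp = 0.008,
                          sampleScatterSd = 0.012, pixelJitterSd = 0.06,
                          envEffects = TRUE) {
  wl <- seq(wlRange[1], wlRange[2], length.out = nBands)
  u <- (wl - mean(wlRange)) / (diff(wlRange) / 2)
  baseline <- 0.72 - 0.12 * (wl - wlRange[1]) / diff(wlRange) -
    0.10 * gaussBump(wl, 1450, 55) - 0.14 * gaussBump(wl, 1940, 75)
  traits <- design@traits
  params <- SIGNATURE_PARAMS[traits]
  if (any(vapply(params, is.null, logical(1))))
    stop("no signature parameters for traits: ",
         paste(traits[vapply(params, is.null, logical(1))], collapse = ", "))
  sdConc <- sqrt(design@traitVg + design@traitVge + design@traitVr)[traits]
  sens <- signalAmp[traits] / sdConc
  envs <- environmentLabels(design)
  nE <- length(envs)
  if (envEffects && nE == 4L) {
    a <- c(0.030, -0.040, 0.012, -0.020)
    b <- c(0.010, -0.015, 0.020, -0.008)
    cc <- c(0.008, -0.010, 0.004, -0.006)
    d <- c(0.004, -0.006, 0.002, 0.005)
    shift <- c(-6, 5, -2, 6)
    envSens <- DEFAULT_ENV_SENSITIVITY[traits, , drop = FALSE]
  } else {
    a <- b <- cc <- d <- shift <- rep(0, nE)
    envSens <- matrix(1, length(traits), nE,
                      dimnames = list(traits, NULL))
  }
  envScatter <- lapply(seq_len(nE), function(e)
    1 + a[e] * u + b[e] * (u^2 - 1 / 3))
  envOffset <- lapply(seq_len(nE), function(e) cc[e] + d[e] * u)
  names(envScatter) <- names(envOffset) <- envs
  colnames(envSens) <- envs
  basisCenters <- seq(1000, 2480, length.out = 60)
  basisWidths <- rep(seq(50, 140, length.out = 8), length.out = 60)
  structureBasis <- vapply(seq_along(basisCenters),
                           function(j) gaussBump(wl, basisCenters[j],
                                                 basisWidths[j]),
                           numeric(nBands))
  dark <- 95 + 12 * gaussBump(wl, 2100, 600)
  white <- dark + 3800 * (1 - 0.35 * (wl - wlRange[1]) / diff(wlRange))
  fleece <- 0.05 + 0.012 * (wl - wlRange[1]) / diff(wlRange)
  new("SpectralModel",
      wavelengths = wl, baseline = baseline,
      signatureCenters = lapply(params, `[[`, "centers"),
      signatureWidths = lapply(params, `[[`, "widths"),
      signatureWeights = lapply(params, `[[`, "weights"),
      sensitivities = sens, envScatter = envScatter, envOffset = envOffset,
      envSensitivity = envSens, envShift = setNames(shift, envs),
      proxySd = proxyFrac[traits] * sdConc,
      bandNoiseSd = bandNoiseSd, structureBasis = structureBasis,
      structureAmp = structureAmp, sampleScatterSd = sampleScatterSd,
      pixelJitterSd = pixelJitterSd, darkCurrent = dark, whitePanel = white,
      fleece = fleece, reflectanceFloor = 0)
}

#' Per-trait absorption signature spectra for one environment
#'
#' Evaluates the Gaussian absorption signatures on the model's wavelength
#' grid, applying the environment's signature wavelength shift. Each
#' signature is normalised to unit maximum.
#'
#' @param model a [SpectralModel-class]
#' @param environment environment label, or NULL for the unshifted
#'   signatures
#' @return bands x traits matrix
#' @export
signatureMatrix <- function(model, environment = NULL) {
  shift <- if (!is.null(environment) &&
               environment %in% names(model@envShift))
    model@envShift[[environment]] else 0
  wl <- model@wavelengths
  traits <- names(model@signatureCenters)
  sig <- vapply(traits, function(tr) {
    ct <- model@signatureCenters[[tr]] + shift
    wd <- model@signatureWidths[[tr]]
    wt <- model@signatureWeights[[tr]]
    s <- rowSums(vapply(seq_along(ct),
                        function(j) wt[j] * gaussBump(wl, ct[j], wd[j]),
                        numeric(length(wl))))
    s / max(s)
  }, numeric(length(wl)))
  sig
}

## ---- SpectraExperiment ----

#' SpectraExperiment: sample spectra with plot metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding one
#' `"reflectance"` assay (bands x samples), the wavelength grid in
#' `rowData` and the plot table in `colData`.
#'
#' @param spectra bands x samples reflectance matrix, or samples x bands
#'   with `samplesInRows = TRUE`
#' @param wavelengths wavelength per band (nm)
#' @param plotData data.frame of per-sample plot metadata and trait values
#' @param samplesInRows whether `spectra` has samples in rows
#' @return a SpectraExperiment
#' @export
SpectraExperiment <- function(spectra, wavelengths, plotData,
                              samplesInRows = FALSE) {
  if (samplesInRows) spectra <- t(spectra)
  stopifnot(nrow(spectra) == length(wavelengths),
            ncol(spectra) == nrow(plotData))
  se <- SummarizedExperiment(
    assays = list(reflectance = unname(spectra)),
    rowData = DataFrame(wavelength = wavelengths),
    colData = DataFrame(plotData, row.names = plotData$plot_id))
  new("SpectraExperiment", se)
}

#' @exportClass SpectraExperiment
setClass("SpectraExperiment", contains = "SummarizedExperiment")

setValidity("SpectraExperiment", function(object) {
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    return("must carry a 'reflectance' assay")
  if (!"wavelength" %in% colnames(rowData(object)))
    return("rowData must carry the wavelength grid")
  TRUE
})

setMethod("wavelengths", "SpectraExperiment",
          function(x) rowData(x)$wavelength)

#' Samples-by-bands spectra matrix of a SpectraExperiment
#' @param x a SpectraExperiment
#' @return samples x bands numeric matrix (regression orientation)
#' @export
spectraMatrix <- function(x) t(assay(x, "reflectance"))

#' Plot metadata of a SpectraExperiment as a data.frame
#' @param x a SpectraExperiment
#' @return data.frame of plot identifiers and trait values
#' @export
plotData <- function(x) as.data.frame(colData(x))

#' Generate average grain spectra for a plot table
#'
#' One spectrum per plot:
#' `R = jitter * scatter_env * (baseline - sum_t sens_t,env * conc_t * sig_t,env)
#'  + offset_env + structured interference + band noise`,
#' where `sig_t,env` is the trait signature shifted by the environment and
#' `sens_t,env` the environment-adjusted sensitivity. Values falling below
#' the model's reflectance floor are clipped with a warning.
#'
#' @param table plot table from [generatePlotTable()]
#' @param model a [SpectralModel-class]
#' @param seed integer seed; deterministic given the seed
#' @return a [SpectraExperiment] with rows in the order of `table`
#' @export
generateSpectra <- function(table, model, seed) {
  traits <- names(model@signatureCenters)
  if (!all(traits %in% colnames(table)))
    stop("plot table lacks trait columns: ",
         paste(setdiff(traits, colnames(table)), collapse = ", "))
  n <- nrow(table)
  nb <- length(model@wavelengths)
  nBasis <- ncol(model@structureBasis)
  X <- matrix(0, nb, n)
  withr::with_seed(as.integer(seed), {
    jitter <- exp(rnorm(n, 0, model@sampleScatterSd))
    structCoef <- matrix(rnorm(n * nBasis, 0, model@structureAmp), n, nBasis)
    noise <- matrix(rnorm(n * nb, 0, model@bandNoiseSd), nb, n)
    proxy <- matrix(rnorm(n * length(traits)), n, length(traits)) *
      rep(model@proxySd[traits], each = n)
  })
  for (env in unique(table$environment)) {
    idx <- which(table$environment == env)
    sig <- signatureMatrix(model, env)
    sens <- model@sensitivities *
      (if (env %in% colnames(model@envSensitivity))
        model@envSensitivity[, env] else rep(1, length(traits)))
    conc <- t(as.matrix(table[idx, traits, drop = FALSE]) +
                proxy[idx, , drop = FALSE])                 # traits x n_e
    contrib <- sig %*% (sens * conc)                        # bands x n_e
    scatter <- if (env %in% names(model@envScatter))
      model@envScatter[[env]] else rep(1, nb)
    offset <- if (env %in% names(model@envOffset))
      model@envOffset[[env]] else rep(0, nb)
    base <- (model@baseline - contrib) * scatter
    X[, idx] <- sweep(base, 2, jitter[idx], `*`) + offset +
      t(structCoef[idx, , drop = FALSE] %*% t(model@structureBasis)) +
      noise[, idx]
  }
  below <- X < model@reflectanceFloor
  if (any(below)) {
    warning(sum(below), " reflectance values clipped at the floor")
    X[below] <- model@reflectanceFloor
  }
  SpectraExperiment(X, model@wavelengths, table)
}

#' Write / read sample spectra as CSV
#'
#' The CSV carries one row per sample: `plot_id` followed by one column per
#' band, named `wl_<wavelength>`.
#'
#' @param x a [SpectraExperiment]
#' @param path file path
#' @param table optional plot table to re-attach on read (matched by
#'   plot_id); if NULL a minimal table of plot ids is used
#' @return `readSpectra` returns a [SpectraExperiment]
#' @export
writeSpectra <- function(x, path) {
  m <- spectraMatrix(x)
  colnames(m) <- sprintf("wl_%.12g", wavelengths(x))
  df <- data.frame(plot_id = plotData(x)$plot_id, m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectra
#' @export
readSpectra <- function(path, table = NULL) {
  df <- read.csv(path, check.names = FALSE)
  wl <- as.numeric(sub("^wl_", "", setdiff(colnames(df), "plot_id")))
  m <- as.matrix(df[, setdiff(colnames(df), "plot_id"), drop = FALSE])
  tab <- if (is.null(table)) data.frame(plot_id = df$plot_id)
  else table[match(df$plot_id, table$plot_id), , drop = FALSE]
  SpectraExperiment(m, wl, tab, samplesInRows = TRUE)
}
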