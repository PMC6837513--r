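## S4 class definitions for the whole package. Constructors live with their
## module files; validity methods here state the structural contracts.

#' ExperimentDesign: layout and variance structure of a multi-environment trial
#'
#' Describes a field-trial design (genotypes x locations x years x N
#' treatments x replicates) together with the per-trait variance structure
#' (grand mean, genotype variance Vg, genotype-by-environment variance Vge,
#' residual variance Vr, and per-environment mean factors) used by the
#' synthetic plot-table generator. Build with [experimentDesign()].
#'
#' @slot nGenotypes number of genotypes
#' @slot locations location labels
#' @slot years trial years
#' @slot treatments nitrogen treatment labels (balanced 1:1)
#' @slot nReplicates replicates per genotype x environment x treatment
#' @slot nChecks extra check-cultivar entries added to the genotype set
#' @slot traits trait labels
#' @slot traitMeans named grand means, concentration units per trait
#' @slot traitVg named genotype variances
#' @slot traitVge named genotype-by-environment variances
#' @slot traitVr named residual (plot) variances
#' @slot envFactors trait x environment matrix of multiplicative mean factors
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(
    nGenotypes = "integer", locations = "character", years = "integer",
    treatments = "character", nReplicates = "integer", nChecks = "integer",
    traits = "character", traitMeans = "numeric", traitVg = "numeric",
    traitVge = "numeric", traitVr = "numeric", envFactors = "matrix"))

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (object@nGenotypes < 2L) msg <- c(msg, "need at least 2 genotypes")
  if (object@nReplicates < 2L)
    msg <- c(msg, "nReplicates must be >= 2 (repeatability needs replication)")
  if (length(object@traits) == 0L) msg <- c(msg, "trait list is empty")
  for (nm in c("traitMeans", "traitVg", "traitVge", "traitVr")) {
    v <- slot(object, nm)
    if (!identical(sort(names(v)), sort(object@traits)))
      msg <- c(msg, sprintf("%s must be named by the traits", nm))
  }
  if (any(object@traitVg < 0) || any(object@traitVge < 0) ||
      any(object@traitVr < 0))
    msg <- c(msg, "variances must be non-negative")
  ne <- length(object@locations) * length(object@years)
  if (!all(dim(object@envFactors) == c(length(object@traits), ne)))
    msg <- c(msg, "envFactors must be traits x environments")
  if (length(msg)) msg else TRUE
})

#' SpectralModel: generative model for grain reflectance spectra
#'
#' Holds the wavelength grid, baseline grain reflectance, per-trait
#' absorption signatures with sensitivities, per-environment scatter /
#' offset / signature-shift effects, noise levels, and the instrument
#' spectra (dark current, white panel, background fleece) needed to
#' synthesise average grain spectra and raw image cubes. Build with
#' [spectralModel()].
#'
#' @slot wavelengths wavelength grid in nm
#' @slot baseline baseline grain reflectance per band, values in (0, 1)
#' @slot signatureCenters list per trait of absorption band centers (nm)
#' @slot signatureWidths list per trait of Gaussian widths (nm)
#' @slot signatureWeights list per trait of relative bump weights
#' @slot sensitivities named per-trait sensitivity (reflectance units per
#'   concentration unit)
#' @slot envScatter environment-named list of per-band multiplicative
#'   scatter spectra
#' @slot envOffset environment-named list of per-band additive offsets
#' @slot envSensitivity trait x environment matrix of sensitivity
#'   multipliers
#' @slot envShift named per-environment signature wavelength shift (nm)
#' @slot bandNoiseSd sd of independent per-band noise (reflectance units)
#' @slot structureBasis bands x nBasis matrix of smooth interference spectra
#' @slot structureAmp sd of the per-sample coefficient on each basis column
#' @slot proxySd named per-trait sd (concentration units) of the spectral
#'   proxy error: the spectrum responds to the concentration plus this
#'   error, capping the asymptotically achievable prediction R-squared
#' @slot sampleScatterSd sdlog of the per-sample multiplicative scatter
#'   jitter
#' @slot pixelJitterSd sdlog of per-pixel grain brightness jitter in cubes
#' @slot darkCurrent per-band dark-current intensity
#' @slot whitePanel per-band white-reference panel intensity
#' @slot fleece per-band background (black fleece) reflectance
#' @slot reflectanceFloor clip floor for generated reflectance
#' @exportClass SpectralModel
setClass("SpectralModel",
  representation(
    wavelengths = "numeric", baseline = "numeric",
    signatureCenters = "list", signatureWidths = "list",
    signatureWeights = "list", sensitivities = "numeric",
    envScatter = "list", envOffset = "list", envSensitivity = "matrix",
    envShift = "numeric", bandNoiseSd = "numeric",
    structureBasis = "matrix", structureAmp = "numeric",
    proxySd = "numeric",
    sampleScatterSd = "numeric", pixelJitterSd = "numeric",
    darkCurrent = "numeric", whitePanel = "numeric", fleece = "numeric",
    reflectanceFloor = "numeric"))

setValidity("SpectralModel", function(object) {
  msg <- character()
  nb <- length(object@wavelengths)
  for (nm in c("baseline", "darkCurrent", "whitePanel", "fleece"))
    if (length(slot(object, nm)) != nb)
      msg <- c(msg, sprintf("%s must have one value per band", nm))
  if (any(object@baseline <= 0) || any(object@baseline >= 1))
    msg <- c(msg, "baseline reflectance must lie in (0, 1)")
  if (object@bandNoiseSd < 0 || object@structureAmp < 0 ||
      object@sampleScatterSd < 0 || object@pixelJitterSd < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (nrow(object@structureBasis) != nb && ncol(object@structureBasis) > 0)
    msg <- c(msg, "structureBasis rows must match bands")
  if (any(object@whitePanel <= object@darkCurrent))
    msg <- c(msg, "white panel intensity must exceed dark current")
  if (length(msg)) msg else TRUE
})

#' SpectralCube: raw hyperspectral intensity image
#'
#' A height x width x bands array of raw sensor intensities, with the
#' wavelength grid, a per-band dark-current spectrum and (optionally) the
#' rectangular image region covered by the white-reference panel.
#'
#' @slot intensities height x width x bands array of non-negative values
#' @slot wavelengths wavelength per band (nm)
#' @slot darkCurrent per-band dark-current spectrum
#' @slot whiteRegion integer c(row0, col0, row1, col1) of the white panel,
#'   or length 0 if a white spectrum is supplied externally
#' @slot id sample identifier used in provenance
#' @exportClass SpectralCube
setClass("SpectralCube",
  representation(intensities = "array", wavelengths = "numeric",
                 darkCurrent = "numeric", whiteRegion = "integer",
                 id = "character"))

setValidity("SpectralCube", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 3L) msg <- c(msg, "intensities must be a 3-d array")
  else {
    if (d[3] != length(object@wavelengths))
      msg <- c(msg, "band count must match the wavelength grid")
    if (length(object@darkCurrent) != d[3])
      msg <- c(msg, "darkCurrent length must equal the band count")
    if (length(object@whiteRegion) == 4L) {
      wr <- object@whiteRegion
      if (wr[1] < 1L || wr[2] < 1L || wr[3] > d[1] || wr[4] > d[2] ||
          wr[1] > wr[3] || wr[2] > wr[4])
        msg <- c(msg, "whiteRegion outside image bounds")
    } else if (length(object@whiteRegion) != 0L)
      msg <- c(msg, "whiteRegion must be c(row0, col0, row1, col1) or empty")
  }
  if (any(object@intensities < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ReflectanceCube: reflectance-corrected hyperspectral image
#'
#' @slot values height x width x bands reflectance array, clipped to
#'   `[0, clipMax]`
#' @slot wavelengths wavelength per band (nm)
#' @slot clipMax upper clip bound applied during correction
#' @slot nClipped number of pixel-band values clipped at either bound
#' @slot source identifier of the source [SpectralCube-class]
#' @exportClass ReflectanceCube
setClass("ReflectanceCube",
  representation(values = "array", wavelengths = "numeric",
                 clipMax = "numeric", nClipped = "integer",
                 source = "character"))

setValidity("ReflectanceCube", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || d[3] != length(object@wavelengths))
    return("values must be height x width x bands matching the wavelengths")
  if (any(object@values < 0) || any(object@values > object@clipMax + 1e-12))
    return("reflectance values must lie in [0, clipMax]")
  TRUE
})

#' PrototypeSet: Neural Gas prototype spectra
#'
#' @slot prototypes k x bands matrix of prototype spectra
#' @slot schedule the training schedule used (iterations, lambda, epsilon)
#' @slot quantisationError mean distance to the nearest prototype at
#'   initialisation and after training
#' @exportClass PrototypeSet
setClass("PrototypeSet",
  representation(prototypes = "matrix", schedule = "list",
                 quantisationError = "numeric"))

setValidity("PrototypeSet", function(object) {
  if (nrow(object@prototypes) < 1L) return("need at least one prototype")
  if (!all(is.finite(object@prototypes))) return("prototypes must be finite")
  TRUE
})

#' PixelClassifier: RBF network separating grain from background pixels
#'
#' @slot centers RBF centers in spectrum space (m x bands)
#' @slot widths per-center Gaussian widths, > 0
#' @slot weights output weights (length m + 1, intercept first)
#' @slot threshold decision threshold on the continuous output
#' @slot trained whether the classifier has been fitted
#' @slot trainAccuracy training-set classification accuracy
#' @exportClass PixelClassifier
setClass("PixelClassifier",
  representation(centers = "matrix", widths = "numeric", weights = "numeric",
                 threshold = "numeric", trained = "logical",
                 trainAccuracy = "numeric"))

setValidity("PixelClassifier", function(object) {
  if (object@trained && any(object@widths <= 0))
    return("RBF widths must be > 0")
  TRUE
})

#' SegmentationMask: binary foreground (grain) mask
#'
#' @slot mask logical height x width matrix, TRUE = grain pixel
#' @slot provenance free-text provenance of the mask
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(mask = "matrix", provenance = "character"))

## ---- regression back-ends ----

#' Virtual parent of the spectrum-to-trait regression models
#' @exportClass SpectralRegressor
setClass("SpectralRegressor", representation("VIRTUAL",
  xMean = "numeric", yMean = "numeric", trace = "numeric", seed = "integer"))

#' PLSModel: NIPALS partial least squares regression
#'
#' Single-response PLS fitted by NIPALS on centered predictors and
#' response; stores weights, loadings and the equivalent regression
#' coefficient vector. Build with [fitPLS()].
#'
#' @slot nComponents number of latent components actually extracted
#' @slot weights bands x A weight matrix W
#' @slot loadings bands x A X-loading matrix P
#' @slot yLoadings per-component y loadings q
#' @slot coefficients equivalent coefficient vector beta so that
#'   yhat = yMean + (x - xMean) %*% beta
#' @slot scores training score matrix T (n x A); columns are mutually
#'   orthogonal
#' @exportClass PLSModel
setClass("PLSModel", contains = "SpectralRegressor",
  representation(nComponents = "integer", weights = "matrix",
                 loadings = "matrix", yLoadings = "numeric",
                 coefficients = "numeric", scores = "matrix"))

setValidity("PLSModel", function(object) {
  if (!all(is.finite(object@coefficients)))
    return("PLS coefficients must be finite")
  TRUE
})

#' RBFRegressor: radial-basis-function network regression
#'
#' Gaussian-kernel mixture over learned prototype spectra; all parameters
#' (centers, widths, linear output weights) refined by conjugate-gradient
#' descent on the training MSE. Build with [fitRBFRegressor()].
#'
#' @slot centers m x bands basis centers
#' @slot widths per-center Gaussian widths
#' @slot weights output weights (intercept first)
#' @exportClass RBFRegressor
setClass("RBFRegressor", contains = "SpectralRegressor",
  representation(centers = "matrix", widths = "numeric",
                 weights = "numeric"))

setValidity("RBFRegressor", function(object) {
  if (any(object@widths <= 0)) return("widths must be > 0")
  if (!all(is.finite(object@centers))) return("centers must be finite")
  TRUE
})

#' MLPRegressor: two-hidden-layer perceptron regression
#'
#' tanh hidden activations (30 and 10 units by default), linear output,
#' trained by Levenberg-Marquardt on the MSE. Build with [fitMLP()].
#'
#' @slot layers list of weight matrices and bias vectors per layer
#' @slot hidden hidden layer sizes
#' @exportClass MLPRegressor
setClass("MLPRegressor", contains = "SpectralRegressor",
  representation(layers = "list", hidden = "integer"))

setValidity("MLPRegressor", function(object) {
  ok <- all(vapply(object@layers, function(l)
    all(is.finite(l$W)) && all(is.finite(l$b)), logical(1)))
  if (!ok) return("weights must be finite")
  TRUE
})

#' VarianceComponents: one-way random-effects decomposition
#'
#' @slot Vg genotype variance (truncated at 0 if the method-of-moments
#'   estimate is negative)
#' @slot Vr residual variance
#' @slot R replicate count used in the repeatability formula
#' @slot nGenotypes number of genotype groups
#' @slot truncated TRUE if the raw Vg estimate was negative
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(Vg = "numeric", Vr = "numeric", R = "numeric",
                 nGenotypes = "integer", truncated = "logical"))

setValidity("VarianceComponents", function(object) {
  if (object@Vg < 0 || object@Vr < 0) return("variances must be >= 0")
  if (object@R < 2) return("R must be >= 2")
  TRUE
})
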