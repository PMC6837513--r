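## Generics shared across modules.

#' Wavelength grid of a spectral object
#' @param x a SpectralCube, ReflectanceCube, SpectralModel or
#'   SpectraExperiment
#' @return numeric vector of wavelengths in nm
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Raw intensity array of a cube
#' @param x a SpectralCube
#' @return height x width x bands array
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Reflectance array of a corrected cube
#' @param x a ReflectanceCube
#' @return height x width x bands array
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' Dark-current spectrum of a cube
#' @param x a SpectralCube
#' @return numeric per-band dark-current spectrum
#' @export
setGeneric("darkCurrent", function(x) standardGeneric("darkCurrent"))

#' Binary foreground matrix of a segmentation mask
#' @param x a SegmentationMask
#' @return logical height x width matrix
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' Prototype spectra of a fitted Neural Gas model
#' @param x a PrototypeSet
#' @return k x bands numeric matrix
#' @export
setGeneric("prototypes", function(x) standardGeneric("prototypes"))

#' Repeatability from variance components
#'
#' Within-environment repeatability \eqn{Vg / (Vg + Vr / R)}: the fraction
#' of phenotypic variance of genotype means attributable to genotype.
#'
#' @param x a [VarianceComponents-class] object
#' @return repeatability in `[0, 1]`, or NaN when both variances are zero
#' @export
setGeneric("repeatability", function(x) standardGeneric("repeatability"))

setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)
setMethod("wavelengths", "ReflectanceCube", function(x) x@wavelengths)
setMethod("wavelengths", "SpectralModel", function(x) x@wavelengths)
setMethod("intensities", "SpectralCube", function(x) x@intensities)
setMethod("reflectance", "ReflectanceCube", function(x) x@values)
setMethod("darkCurrent", "SpectralCube", function(x) x@darkCurrent)
setMethod("maskMatrix", "SegmentationMask", function(x) x@mask)
setMethod("prototypes", "PrototypeSet", function(x) x@prototypes)

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("SpectralCube '%s': %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              object@id, d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
  if (length(object@whiteRegion) == 4L)
    cat(sprintf("  white panel rows %d-%d, cols %d-%d\n",
                object@whiteRegion[1], object@whiteRegion[3],
                object@whiteRegion[2], object@whiteRegion[4]))
})

setMethod("show", "ReflectanceCube", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ReflectanceCube (source '%s'): %d x %d pixels, %d bands; %d values clipped to [0, %.2f]\n",
    object@source, d[1], d[2], d[3], object@nClipped, object@clipMax))
})

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf(
    "ExperimentDesign: %d genotypes x %d locations x %d years x %d treatments x %d reps = %d plots\n",
    object@nGenotypes, length(object@locations), length(object@years),
    length(object@treatments), object@nReplicates, nPlots(object)))
  cat("  traits:", paste(object@traits, collapse = ", "), "\n")
})

setMethod("show", "PrototypeSet", function(object) {
  cat(sprintf(
    "PrototypeSet: %d prototypes, %d bands; quantisation error %.4g -> %.4g\n",
    nrow(object@prototypes), ncol(object@prototypes),
    object@quantisationError[1], object@quantisationError[2]))
})

setMethod("show", "PixelClassifier", function(object) {
  cat(sprintf(
    "PixelClassifier: %d RBF centers, threshold %.2f, %s (train accuracy %.3f)\n",
    nrow(object@centers), object@threshold,
    if (object@trained) "trained" else "untrained", object@trainAccuracy))
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d components, %d bands\n",
              object@nComponents, length(object@coefficients)))
})

setMethod("show", "RBFRegressor", function(object) {
  cat(sprintf("RBFRegressor: %d basis centers, final training MSE %.4g\n",
              nrow(object@centers), tail(object@trace, 1)))
})

setMethod("show", "MLPRegressor", function(object) {
  cat(sprintf("MLPRegressor: hidden layers (%s), final training MSE %.4g\n",
              paste(object@hidden, collapse = ", "), tail(object@trace, 1)))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents: Vg = %.4g, Vr = %.4g (R = %g, %d genotypes)%s\n",
              object@Vg, object@Vr, object@R, object@nGenotypes,
              if (object@truncated) " [Vg truncated at 0]" else ""))
})
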