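## Reflectance correction of raw cubes against dark current and the
## white-reference panel.

#' Extract the white-reference spectrum from a cube
#'
#' Per-band mean intensity over the pixels of the cube's white-panel
#' region.
#'
#' @param cube a [SpectralCube-class] with a non-empty `whiteRegion`
#' @return per-band white-reference intensity spectrum
#' @export
extractWhiteReference <- function(cube) {
  wr <- cube@whiteRegion
  if (length(wr) != 4L)
    stop("cube has no white-panel region; supply a white spectrum instead")
  sub <- cube@intensities[wr[1]:wr[3], wr[2]:wr[4], , drop = FALSE]
  apply(sub, 3, mean)
}

#' Convert raw intensities to reflectance
#'
#' Applies the dark-current / white-reference correction per pixel and
#' band: `R = (I - I_DC) / (I_W - I_DC)`, then clips to `[0, clipMax]`.
#' The optional `spectralonReflectance` multiplier rescales to absolute
#' reflectance for a reference panel that is not perfectly white (e.g.
#' 0.95 for Spectralon); the default 1 applies the formula as printed.
#'
#' @param cube a [SpectralCube-class]
#' @param white per-band white-reference spectrum; defaults to
#'   [extractWhiteReference()] on the cube's panel region
#' @param clipMax upper clip bound (default 1.1, allowing mild specular
#'   highlights above the diffuse reference)
#' @param spectralonReflectance absolute reflectance of the reference
#'   panel (default 1, i.e. off)
#' @return a [ReflectanceCube-class]
#' @export
correctReflectance <- function(cube, white = NULL, clipMax = 1.1,
                               spectralonReflectance = 1) {
  if (is.null(white)) white <- extractWhiteReference(cube)
  nb <- length(cube@wavelengths)
  stopifnot(length(white) == nb)
  denom <- white - cube@darkCurrent
  bad <- which(denom <= 0)
  if (length(bad))
    stop("white reference does not exceed dark current at band(s) ",
         paste(head(bad, 5), collapse = ", "),
         " (degenerate illumination)")
  d <- dim(cube@intensities)
  R <- cube@intensities
  for (b in seq_len(nb))
    R[, , b] <- (R[, , b] - cube@darkCurrent[b]) / denom[b] *
      spectralonReflectance
  nClip <- sum(R < 0 | R > clipMax)
  R[R < 0] <- 0
  R[R > clipMax] <- clipMax
  new("ReflectanceCube", values = R, wavelengths = cube@wavelengths,
      clipMax = clipMax, nClipped = as.integer(nClip), source = cube@id)
}

#' Flatten a cube to a pixels-by-bands matrix
#'
#' @param cube a [ReflectanceCube-class] or [SpectralCube-class]
#' @return (height * width) x bands matrix; pixel order is column-major,
#'   matching [maskFromLabels()] and [segmentCube()]
#' @export
pixelMatrix <- function(cube) {
  arr <- if (is(cube, "SpectralCube")) cube@intensities else cube@values
  d <- dim(arr)
  dim(arr) <- c(d[1] * d[2], d[3])
  arr
}
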