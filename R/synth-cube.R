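## Synthetic raw image cubes: the inverse of reflectance correction.
##
## A cube holds a white-reference panel strip at the top, circular grains
## on a dark fleece background below it, and raw intensities built as
## I = R * (I_W - I_DC) + I_DC so that reflectance correction recovers the
## generating spectra exactly in the noise-free case.

#' Generate a raw hyperspectral mini-cube for one grain sample
#'
#' Builds a height x width x bands intensity cube: a white-panel region at
#' the top rows, circular grain blobs carrying the plot's reflectance
#' spectrum (with per-pixel multiplicative log-normal brightness jitter),
#' and a low-reflectance fleece background. Intensities follow
#' `I = R * (I_W - I_DC) + I_DC`; optional sensor noise is added on the
#' intensity scale.
#'
#' @param plotSpectrum per-band grain reflectance of the sample
#' @param model a [SpectralModel-class] (supplies dark current, white-panel
#'   and fleece spectra, and the pixel jitter sd)
#' @param imageParams list with height, width, nGrains, grainRadius and
#'   optionally panelRows (default 12)
#' @param seed integer seed
#' @param noise logical; FALSE disables sensor noise and pixel jitter so
#'   the round trip through reflectance correction is exact
#' @return list with `cube` (a [SpectralCube-class]) and `mask` (logical
#'   ground-truth grain matrix)
#' @export
generateCube <- function(plotSpectrum, model,
                         imageParams = list(height = 60, width = 80,
                                            nGrains = 30, grainRadius = 3),
                         seed = 1, noise = TRUE) {
  h <- imageParams$height
  w <- imageParams$width
  nGrains <- imageParams$nGrains
  r <- imageParams$grainRadius
  panelRows <- if (is.null(imageParams$panelRows)) 12L
  else as.integer(imageParams$panelRows)
  nb <- length(model@wavelengths)
  stopifnot(length(plotSpectrum) == nb)
  if (panelRows >= h) stop("white panel leaves no sample area")
  rowLo <- panelRows + 1L + r
  if (nGrains > 0 && (rowLo > h - r || 1L + r > w - r))
    stop("grains do not fit inside the image below the white panel")
  mask <- matrix(FALSE, h, w)
  jitterMap <- matrix(1, h, w)
  withr::with_seed(as.integer(seed), {
    if (nGrains > 0) {
      cy <- sample(seq(rowLo, h - r), nGrains, replace = TRUE)
      cx <- sample(seq(1L + r, w - r), nGrains, replace = TRUE)
      for (g in seq_len(nGrains)) {
        rows <- (cy[g] - r):(cy[g] + r)
        cols <- (cx[g] - r):(cx[g] + r)
        disc <- outer(rows - cy[g], cols - cx[g],
                      function(a, b) a^2 + b^2 <= r^2)
        mask[rows, cols] <- mask[rows, cols] | disc
      }
      if (any(mask[seq_len(panelRows), ]))
        stop("grain region overlaps the white panel")
    }
    if (noise && model@pixelJitterSd > 0)
      jitterMap[] <- exp(rnorm(h * w, 0, model@pixelJitterSd))
    gain <- model@whitePanel - model@darkCurrent
    cube <- array(0, dim = c(h, w, nb))
    for (b in seq_len(nb)) {
      R <- matrix(model@fleece[b], h, w)
      R[mask] <- plotSpectrum[b] * jitterMap[mask]
      I <- R * gain[b] + model@darkCurrent[b]
      I[seq_len(panelRows), ] <- model@whitePanel[b]
      if (noise && model@bandNoiseSd > 0)
        I <- I + rnorm(h * w, 0, model@bandNoiseSd * gain[b])
      cube[, , b] <- pmax(I, 0)
    }
  })
  cubeObj <- new("SpectralCube", intensities = cube,
                 wavelengths = model@wavelengths,
                 darkCurrent = model@darkCurrent,
                 whiteRegion = c(1L, 1L, panelRows, as.integer(w)),
                 id = sprintf("synthetic-cube-seed%d", as.integer(seed)))
  list(cube = cubeObj, mask = mask)
}
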