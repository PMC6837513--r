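## Minimal ENVI raster I/O (BSQ interleave, 32-bit float, little endian).
## Covers exactly what the pipeline needs: a text .hdr with dimensions and
## the wavelength list, and a flat binary data file.

#' Write a cube in ENVI format
#'
#' Writes `<path>.hdr` (text header with dimensions and wavelengths) and
#' `<path>.dat` (band-sequential 32-bit little-endian floats).
#'
#' @param cube a [SpectralCube-class] or [ReflectanceCube-class]
#' @param path output path without extension
#' @return invisibly, the header path
#' @export
writeENVI <- function(cube, path) {
  arr <- if (is(cube, "SpectralCube")) cube@intensities else cube@values
  wl <- wavelengths(cube)
  d <- dim(arr)
  hdr <- c("ENVI",
           "description = {speccal export}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = Nanometers",
           sprintf("wavelength = {%s}",
                   paste(sprintf("%.4f", wl), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  ## BSQ with row-major lines: write each band transposed
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(arr[, , b])), con, size = 4, endian = "little")
  invisible(paste0(path, ".hdr"))
}

parseENVIHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  getNum <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*(\\d+)"), txt))[[1]]
    if (length(m) < 2) stop("ENVI header misses '", key, "'")
    as.integer(m[2])
  }
  wl <- NULL
  m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(m) == 2)
    wl <- as.numeric(strsplit(m[2], ",")[[1]])
  list(samples = getNum("samples"), lines = getNum("lines"),
       bands = getNum("bands"), dataType = getNum("data type"),
       byteOrder = getNum("byte order"),
       interleave = tolower(sub(".*interleave\\s*=\\s*(\\w+).*", "\\1",
                                txt)),
       wavelength = wl)
}

#' Read an ENVI cube
#'
#' Reads a BSQ float32 ENVI file written by [writeENVI()] (or compatible).
#'
#' @param hdrPath path to the `.hdr` file
#' @param darkCurrent per-band dark-current spectrum to attach (default 0)
#' @param whiteRegion optional `c(row0, col0, row1, col1)` white-panel
#'   region
#' @return a [SpectralCube-class]
#' @export
readENVI <- function(hdrPath, darkCurrent = NULL, whiteRegion = integer()) {
  hdr <- parseENVIHeader(hdrPath)
  if (hdr$interleave != "bsq") stop("only BSQ interleave is supported")
  if (hdr$dataType != 4L) stop("only float32 (data type 4) is supported")
  datPath <- sub("\\.hdr$", ".dat", hdrPath)
  if (!file.exists(datPath)) datPath <- sub("\\.hdr$", ".img", hdrPath)
  n <- hdr$samples * hdr$lines * hdr$bands
  con <- file(datPath, "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = n, size = 4,
                 endian = if (hdr$byteOrder == 0) "little" else "big")
  arr <- array(0, dim = c(hdr$lines, hdr$samples, hdr$bands))
  per <- hdr$lines * hdr$samples
  for (b in seq_len(hdr$bands))
    arr[, , b] <- matrix(raw[((b - 1) * per + 1):(b * per)],
                         hdr$lines, hdr$samples, byrow = TRUE)
  wl <- if (is.null(hdr$wavelength)) seq_len(hdr$bands) else hdr$wavelength
  if (is.null(darkCurrent)) darkCurrent <- rep(0, hdr$bands)
  new("SpectralCube", intensities = arr, wavelengths = wl,
      darkCurrent = darkCurrent, whiteRegion = as.integer(whiteRegion),
      id = basename(hdrPath))
}
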