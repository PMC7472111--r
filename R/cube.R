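#' Construct a hyperspectral cube
#'
#' A cube is a 3-D raster of intensity (uncalibrated) or reflectance
#' (calibrated) values indexed `(row, col, band)`, with row 1 at the top of
#' the image, plus a wavelength axis and per-band FWHM.
#'
#' @param data 3-D numeric array `(rows, cols, bands)`.
#' @param wavelengths Band-centre wavelengths (nm), one per band.
#' @param fwhm Per-band FWHM (nm); a single value is recycled.
#' @param calibrated `TRUE` once values are reflectance (dark/white corrected).
#' @param sensor_id Sensor label.
#' @return An object of class `"spectral_cube"`.
#' @export
spectral_cube <- function(data, wavelengths, fwhm, calibrated = FALSE,
                          sensor_id = "unknown") {
  if (length(dim(data)) != 3L)
    stop("cube data must be a 3-D array (row, col, band)", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("band dimension does not match wavelength axis", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (length(fwhm) == 1L) fwhm <- rep(as.numeric(fwhm), length(wavelengths))
  if (length(fwhm) != length(wavelengths) || any(fwhm <= 0))
    stop("fwhm must be positive, one value per band", call. = FALSE)
  if (isTRUE(calibrated) && !all(is.finite(data)))
    stop("calibrated cube must contain only finite values", call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths,
                 fwhm = as.numeric(fwhm), calibrated = isTRUE(calibrated),
                 sensor_id = as.character(sensor_id)[1]),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %s: %d x %d pixels, %d bands (%.0f-%.0f nm), %s\n",
              x$sensor_id, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths),
              if (x$calibrated) "calibrated" else "raw"))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' Extract the spectral signature of one pixel
#'
#' @param cube A `spectral_cube`.
#' @param row,col Pixel coordinates (1-based, row 1 at top).
#' @return Numeric vector of length `n_bands`.
#' @export
pixel_signature <- function(cube, row, col) {
  stopifnot(inherits(cube, "spectral_cube"))
  as.numeric(cube$data[row, col, ])
}

#' Construct a pixel mask
#'
#' A logical raster aligned with a cube's spatial dimensions, labelling a
#' pixel class (background, marker or leaf).
#'
#' @param mask Logical matrix `(rows, cols)`.
#' @param label One of `"background"`, `"marker"`, `"leaf"`.
#' @return An object of class `"pixel_mask"`.
#' @export
pixel_mask <- function(mask, label = c("leaf", "marker", "background")) {
  label <- match.arg(label)
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask & !is.na(mask)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, label = label), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %s: %d / %d pixels set\n",
              x$label, sum(x$mask), length(x$mask)))
  invisible(x)
}
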