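#' Construct a spectrum
#'
#' A spectrum holds one sample's reflectance signature: paired wavelength and
#' reflectance vectors, a per-band full width at half maximum (FWHM), the
#' identifier of the sensor that produced it, and the index ranges of the
#' physical detectors inside that sensor. The detector segmentation drives
#' splice-jump correction: multi-detector spectrometers show step
#' discontinuities at detector boundaries.
#'
#' @param sample_id Sample identifier (single string).
#' @param wavelengths Strictly increasing numeric vector of band centres (nm).
#' @param values Numeric vector of reflectance values, one per band.
#' @param fwhm Per-band FWHM in nm; a single value is recycled.
#' @param sensor_id Sensor label, e.g. `"ASD"`, `"FX10"`.
#' @param detector_segments List of length-2 integer vectors
#'   `c(first, last)` (1-based, inclusive) that partition `1:length(wavelengths)`
#'   contiguously and in order; defaults to a single segment.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(sample_id, wavelengths, values, fwhm,
                     sensor_id = "unknown", detector_segments = NULL) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  n <- length(wavelengths)
  if (length(fwhm) == 1L) fwhm <- rep(as.numeric(fwhm), n)
  fwhm <- as.numeric(fwhm)
  if (is.null(detector_segments)) detector_segments <- list(c(1L, n))
  detector_segments <- lapply(detector_segments, function(s) as.integer(s))
  s <- structure(
    list(sample_id = as.character(sample_id)[1],
         wavelengths = wavelengths, values = values, fwhm = fwhm,
         sensor_id = as.character(sensor_id)[1],
         detector_segments = detector_segments),
    class = "spectrum")
  validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  n <- length(s$wavelengths)
  if (n == 0L) stop("spectrum has no bands", call. = FALSE)
  if (length(s$values) != n || length(s$fwhm) != n)
    stop("wavelengths, values and fwhm must have equal length", call. = FALSE)
  if (any(diff(s$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(s$fwhm <= 0))
    stop("fwhm must be positive everywhere", call. = FALSE)
  seg <- s$detector_segments
  if (length(seg) == 0L) stop("at least one detector segment required", call. = FALSE)
  starts <- vapply(seg, `[`, integer(1), 1L)
  ends <- vapply(seg, `[`, integer(1), 2L)
  if (starts[1] != 1L || ends[length(seg)] != n ||
      any(starts > ends) ||
      (length(seg) > 1L && any(starts[-1] != ends[-length(seg)] + 1L)))
    stop("detector_segments must partition the band indices contiguously and in order",
         call. = FALSE)
  invisible(s)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s [%s]: %d bands, %.0f-%.0f nm, %d detector segment(s)\n",
              x$sample_id, x$sensor_id, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              length(x$detector_segments)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavelengths)

#' Construct a band specification
#'
#' A band specification describes a target sensor layout for spectral band
#' resampling: ordered band centres plus the FWHM of each band's (Gaussian)
#' spectral response function.
#'
#' @param centres Strictly increasing numeric vector of band centres (nm).
#' @param fwhm Per-band FWHM (nm); a single value is recycled.
#' @param label Optional label for the layout.
#' @return An object of class `"band_spec"`.
#' @export
band_spec <- function(centres, fwhm, label = "") {
  centres <- as.numeric(centres)
  if (length(fwhm) == 1L) fwhm <- rep(as.numeric(fwhm), length(centres))
  fwhm <- as.numeric(fwhm)
  if (length(centres) == 0L) stop("band_spec needs at least one band", call. = FALSE)
  if (any(diff(centres) <= 0)) stop("centres must be strictly increasing", call. = FALSE)
  if (length(fwhm) != length(centres)) stop("fwhm length must match centres", call. = FALSE)
  if (any(fwhm <= 0)) stop("fwhm must be positive", call. = FALSE)
  structure(list(centres = centres, fwhm = fwhm, label = as.character(label)[1]),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %d bands, %.1f-%.1f nm, FWHM %.2f-%.2f nm\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$centres), min(x$centres), max(x$centres),
              min(x$fwhm), max(x$fwhm)))
  invisible(x)
}

#' @export
length.band_spec <- function(x) length(x$centres)

#' Band specification of a spectrum's own grid
#'
#' @param s A `spectrum`.
#' @return A `band_spec` with the spectrum's centres and FWHMs.
#' @export
band_spec_of <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  band_spec(s$wavelengths, s$fwhm, label = s$sensor_id)
}

#' Shipped sensor band-layout presets
#'
#' Presets mirror common proximal-sensing instruments: a full-range point
#' spectrometer resampled to a 1 nm grid (`"ASD-1nm"`), a VNIR pushbroom
#' camera with 5.5 nm FWHM (`"FX10-5.5nm"`), and a SWIR camera with 12 nm
#' FWHM (`"SWIR-12nm"`).
#'
#' @param name Preset name.
#' @return A `band_spec`.
#' @export
sensor_preset <- function(name = c("ASD-1nm", "FX10-5.5nm", "SWIR-12nm")) {
  name <- match.arg(name)
  switch(name,
    "ASD-1nm"    = band_spec(seq(350, 2500, by = 1), 1, label = name),
    "FX10-5.5nm" = band_spec(seq(400, 1000, by = 5.5), 5.5, label = name),
    "SWIR-12nm"  = band_spec(seq(1000, 2600, by = 12), 12, label = name))
}

# absolute tolerance (nm) for wavelength-grid comparisons
.WL_TOL <- 1e-6

same_grid <- function(a, b) {
  length(a) == length(b) && all(abs(a - b) <= .WL_TOL)
}
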