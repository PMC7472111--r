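#' Splice-jump correction parameters
#'
#' Multi-detector spectrometers show step discontinuities ("jumps") where the
#' signal hands over from one physical detector to the next. Correction fits
#' a least-squares line through the trailing `m` points of the segment left
#' of each junction, extrapolates it to the first wavelength of the right
#' segment, and shifts the whole right segment additively so its first value
#' lands on the extrapolated line. Junctions are processed left to right so
#' corrections cascade.
#'
#' @param m Number of trailing points fitted (default 6).
#' @param mode Currently `"additive"` only; the multiplicative alternative is
#'   reserved.
#' @return An object of class `"jump_params"`.
#' @export
jump_params <- function(m = 6L, mode = "additive") {
  m <- as.integer(m)
  if (m < 2L) stop("m must be at least 2", call. = FALSE)
  mode <- match.arg(mode, "additive")
  structure(list(m = m, mode = mode), class = "jump_params")
}

#' Calibrate a raw cube to reflectance
#'
#' Per pixel and band, reflectance is
#' `r = (i_plant - i_dark) / (i_white - i_dark)` where the three intensities
#' come from the plant frame, the dark-current frame and the white-reference
#' frame. Elements where `|i_white - i_dark|` falls below `guard` cannot be
#' divided; they are set to `NA` in the returned cube and reported in the
#' attached invalid-pixel mask.
#'
#' @param plant,dark,white `spectral_cube`s of identical shape and wavelength
#'   axis.
#' @param guard Minimum tolerated `|i_white - i_dark|` (intensity units).
#' @return A calibrated `spectral_cube`; attribute `"invalid_mask"` is a
#'   logical `(row, col)` matrix flagging pixels with at least one guarded
#'   band.
#' @export
calibrate_cube <- function(plant, dark, white, guard = 1e-9) {
  stopifnot(inherits(plant, "spectral_cube"), inherits(dark, "spectral_cube"),
            inherits(white, "spectral_cube"))
  if (!identical(dim(plant$data), dim(dark$data)) ||
      !identical(dim(plant$data), dim(white$data)))
    stop("plant, dark and white cubes must have identical shapes", call. = FALSE)
  if (!same_grid(plant$wavelengths, dark$wavelengths) ||
      !same_grid(plant$wavelengths, white$wavelengths))
    stop("plant, dark and white cubes must share one wavelength axis", call. = FALSE)
  denom <- white$data - dark$data
  invalid <- abs(denom) < guard
  r <- (plant$data - dark$data) / denom
  r[invalid] <- 0  # placeholder; masked below
  out <- spectral_cube(r, plant$wavelengths, plant$fwhm, calibrated = TRUE,
                       sensor_id = plant$sensor_id)
  out$data[invalid] <- NA_real_
  attr(out, "invalid_mask") <- apply(invalid, c(1, 2), any)
  out
}

#' Remove detector splice jumps from a spectrum
#'
#' @param s A `spectrum` with at least two detector segments.
#' @param params A `jump_params` (see [jump_params()]).
#' @return The corrected `spectrum`; grid and within-segment first
#'   differences are unchanged.
#' @export
remove_jumps <- function(s, params = jump_params()) {
  stopifnot(inherits(s, "spectrum"), inherits(params, "jump_params"))
  segs <- s$detector_segments
  if (length(segs) < 2L)
    stop("spectrum has a single detector segment; nothing to correct", call. = FALSE)
  m <- params$m
  wl <- s$wavelengths
  v <- s$values
  for (j in seq_len(length(segs) - 1L)) {
    left <- segs[[j]]; right <- segs[[j + 1L]]
    if (left[2] - left[1] + 1L < m)
      stop(sprintf("detector segment %d has fewer than m = %d points", j, m),
           call. = FALSE)
    idx <- (left[2] - m + 1L):left[2]
    fit <- stats::lm.fit(cbind(1, wl[idx]), v[idx])
    predicted <- sum(fit$coefficients * c(1, wl[right[1]]))
    offset <- predicted - v[right[1]]
    v[right[1]:right[2]] <- v[right[1]:right[2]] + offset
  }
  s$values <- v
  s
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' @param s A `spectrum`.
#' @param window Odd filter length (bands); default 11.
#' @param polyorder Polynomial order, strictly less than `window`; default 2.
#' @return The smoothed `spectrum` on the unchanged grid.
#' @export
smooth_spectrum <- function(s, window = 11L, polyorder = 2L) {
  stopifnot(inherits(s, "spectrum"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be smaller than window", call. = FALSE)
  if (window >= length(s$values))
    stop("window must be shorter than the spectrum", call. = FALSE)
  s$values <- as.numeric(signal::sgolayfilt(s$values, p = polyorder, n = window))
  s
}

#' Trim a spectrum to a wavelength interval
#'
#' Keeps bands with `lo <= wavelength <= hi` and re-indexes the detector
#' segments accordingly (segments falling entirely outside are dropped).
#'
#' @param s A `spectrum`.
#' @param lo,hi Interval bounds in nm, `lo < hi`.
#' @return The trimmed `spectrum`.
#' @export
trim_spectrum <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectrum"))
  if (!(lo < hi)) stop("lo must be smaller than hi", call. = FALSE)
  keep <- which(s$wavelengths >= lo & s$wavelengths <= hi)
  if (length(keep) == 0L)
    stop(sprintf("no bands in [%g, %g] nm", lo, hi), call. = FALSE)
  segs <- list()
  for (seg in s$detector_segments) {
    inside <- keep[keep >= seg[1] & keep <= seg[2]]
    if (length(inside) == 0L) next
    segs[[length(segs) + 1L]] <-
      c(match(inside[1], keep), match(inside[length(inside)], keep))
  }
  spectrum(s$sample_id, s$wavelengths[keep], s$values[keep], s$fwhm[keep],
           sensor_id = s$sensor_id, detector_segments = segs)
}

#' Standard spectrometer pre-processing chain
#'
#' Splice-jump removal (when the spectrum has multiple detector segments),
#' Savitzky-Golay smoothing, then trimming of the noisy spectral extremes.
#'
#' @param s A `spectrum`.
#' @param params `jump_params` for the splice correction.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param trim_lo,trim_hi Retained wavelength interval in nm.
#' @return The pre-processed `spectrum`.
#' @export
preprocess_spectrum <- function(s, params = jump_params(),
                                sg_window = 11L, sg_polyorder = 2L,
                                trim_lo = 400, trim_hi = 2400) {
  if (length(s$detector_segments) > 1L) s <- remove_jumps(s, params)
  s <- smooth_spectrum(s, sg_window, sg_polyorder)
  trim_spectrum(s, trim_lo, trim_hi)
}
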