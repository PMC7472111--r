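#' Gaussian spectral-response resampling weights
#'
#' Each destination band is modelled as a Gaussian spectral response centred
#' on its band centre with `sigma = FWHM / (2 * sqrt(2 * log(2)))`. A source
#' band contributes to a destination band only where the FWHMs of the two
#' response functions overlap, i.e. when
#' `|centre_dst - centre_src| <= (FWHM_dst + FWHM_src) / 2`; the weight is
#' the destination response evaluated at the source centre (with a dense
#' source grid this sampling approximation is standard practice and avoids
#' response-overlap integrals). Rows are normalised to sum to one, so
#' resampling is a convex combination of source values.
#'
#' @param src,dst `band_spec`s for the source and destination layouts.
#' @return A `length(dst) x length(src)` weight matrix with unit row sums.
#' @export
gaussian_weights <- function(src, dst) {
  stopifnot(inherits(src, "band_spec"), inherits(dst, "band_spec"))
  dl <- outer(dst$centres, src$centres, `-`)
  halfwidth <- outer(dst$fwhm, src$fwhm, `+`) / 2
  sigma <- dst$fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-(dl^2) / (2 * sigma^2))
  w[abs(dl) > halfwidth] <- 0
  rs <- rowSums(w)
  if (any(rs == 0)) {
    bad <- which(rs == 0)[1]
    stop(sprintf("destination band %g nm (FWHM %g) has no overlapping source band",
                 dst$centres[bad], dst$fwhm[bad]), call. = FALSE)
  }
  w / rs
}

#' Resample a spectrum onto a destination band layout
#'
#' @param s A `spectrum`.
#' @param dst A `band_spec` describing the destination layout.
#' @return A `spectrum` on the destination grid; values are the weighted
#'   combination `W %*% values_src` and the FWHM metadata is taken from
#'   `dst`. The output has a single detector segment.
#' @export
resample_spectrum <- function(s, dst) {
  stopifnot(inherits(s, "spectrum"), inherits(dst, "band_spec"))
  w <- gaussian_weights(band_spec_of(s), dst)
  spectrum(s$sample_id, dst$centres, as.numeric(w %*% s$values), dst$fwhm,
           sensor_id = s$sensor_id)
}

#' Resample every spectrum of a dataset
#'
#' @param data A `spec_dataset`.
#' @param dst A `band_spec`.
#' @return A `spec_dataset` on the destination grid.
#' @export
resample_dataset <- function(data, dst) {
  stopifnot(inherits(data, "spec_dataset"))
  w <- gaussian_weights(band_spec_of(data$spectra[[1]]), dst)
  spectra <- lapply(data$spectra, function(s)
    spectrum(s$sample_id, dst$centres, as.numeric(w %*% s$values), dst$fwhm,
             sensor_id = s$sensor_id))
  spec_dataset(spectra, data$records, data$range_label)
}

#' Evenly distributed band layout
#'
#' Bands of uniform FWHM tile `[lo, hi]`: centres sit at
#' `lo + fwhm/2, lo + 3*fwhm/2, ...` up to `hi - fwhm/2`.
#'
#' @param lo,hi Interval bounds (nm), `hi - lo >= fwhm`.
#' @param fwhm Uniform bandwidth (nm).
#' @return A `band_spec`.
#' @export
even_grid <- function(lo, hi, fwhm) {
  if (hi - lo < fwhm)
    stop("interval narrower than one band", call. = FALSE)
  centres <- seq(lo + fwhm / 2, hi - fwhm / 2 + .WL_TOL, by = fwhm)
  band_spec(centres, fwhm, label = sprintf("even-%gnm", fwhm))
}

#' Band layout centred on key-wavelengths
#'
#' Narrow-band (`"NB"`) layouts reuse the source sensor's native bandwidth at
#' every key-wavelength. Broad-band (`"BB"`) layouts let each band's
#' half-width reach half of the distance to its nearest neighbouring
#' key-wavelength, i.e. `FWHM = min(gap to left, gap to right)`; the end keys
#' use their single neighbour.
#'
#' @param keys Key-wavelengths in nm (duplicates are an error; unsorted input
#'   is ordered).
#' @param mode `"NB"` or `"BB"`.
#' @param nb_fwhm Native sensor FWHM used in `"NB"` mode (nm).
#' @return A `band_spec`.
#' @export
key_band_spec <- function(keys, mode = c("NB", "BB"), nb_fwhm = 1) {
  mode <- match.arg(mode)
  keys <- as.numeric(keys)
  if (anyDuplicated(keys)) stop("duplicate key-wavelengths", call. = FALSE)
  keys <- sort(keys)
  if (mode == "NB") {
    band_spec(keys, nb_fwhm, label = sprintf("keys-NB-%gnm", nb_fwhm))
  } else {
    if (length(keys) < 2L)
      stop("broad-band layout needs at least two key-wavelengths", call. = FALSE)
    gaps <- diff(keys)
    fwhm <- pmin(c(Inf, gaps), c(gaps, Inf))
    band_spec(keys, fwhm, label = "keys-BB")
  }
}
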