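#' Configuration of the synthetic leaf-spectra generator
#'
#' The generator emulates the statistical structure of a greenhouse nitrogen
#' trial: several varieties grown under a set of soil nitrogen treatments,
#' each leaf measured as a full-range reflectance signature. Reflectance is a
#' smooth green-leaf continuum minus Gaussian absorption dips whose depths
#' grow linearly with the leaf's N% (the nitrogen-sensitive features the
#' regression should find), minus nitrogen-independent confounder dips (water
#' bands) with random depths, times a multiplicative amplitude jitter, plus
#' additive Gaussian sensor noise. Default feature centres sit at
#' nitrogen/protein absorption bands (676, 1517, 2106, 2180, 2313 nm).
#'
#' @param n_samples Cohort size (default 300).
#' @param varieties Variety labels (default 5 varieties).
#' @param treatments Soil nitrogen treatments in mg N/kg
#'   (default 25/50/100/200).
#' @param treatment_means Mean leaf N% per treatment (default 2/3/4/5.5).
#' @param treatment_sd Within-treatment N% standard deviation (default 0.6).
#' @param n_percent_range Clipping window for N% (default `c(1, 7)`).
#' @param features Data frame of nitrogen-sensitive absorption features with
#'   columns `centre` (nm), `width` (Gaussian sigma, nm) and `depth_per_n`
#'   (reflectance depth per unit N%).
#' @param confounders Data frame of N-independent dips with columns `centre`,
#'   `width` and `max_depth` (depth drawn uniformly in `[0, max_depth]`).
#' @param noise_sigma Additive reflectance noise SD (default 0.005).
#' @param amplitude_sd SD of the multiplicative amplitude jitter
#'   (default 0.02; 0 disables it).
#' @param grid Target sensor layout: a `band_spec` (default the 1 nm
#'   full-range spectrometer preset).
#' @param splice_junctions Wavelengths (nm) of detector boundaries at which
#'   splice offsets are added; `NULL` for a single-detector signature.
#' @param splice_offsets Additive offsets applied to the signature beyond
#'   each junction (same length as `splice_junctions`).
#' @param sensor_id Sensor label for the generated spectra.
#' @param seed Mandatory integer seed; all randomness flows from it through
#'   named substreams.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_samples = 300L,
                             varieties = paste0("V", 1:5),
                             treatments = c(25, 50, 100, 200),
                             treatment_means = c(2.0, 3.0, 4.0, 5.5),
                             treatment_sd = 0.6,
                             n_percent_range = c(1, 7),
                             features = data.frame(
                               centre = c(676, 1517, 2106, 2180, 2313),
                               width = c(10, 10, 10, 10, 10),
                               depth_per_n = c(0.004, 0.005, 0.006, 0.007, 0.006)),
                             confounders = data.frame(
                               centre = c(1450, 1940),
                               width = c(40, 50),
                               max_depth = c(0.06, 0.08)),
                             noise_sigma = 0.005,
                             amplitude_sd = 0.02,
                             grid = sensor_preset("ASD-1nm"),
                             splice_junctions = NULL,
                             splice_offsets = NULL,
                             sensor_id = "synth",
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(grid, "band_spec"),
            length(treatments) == length(treatment_means))
  if (any(features$depth_per_n < 0)) stop("feature depths must be >= 0", call. = FALSE)
  if (any(features$centre < min(grid$centres) | features$centre > max(grid$centres)))
    stop("feature centres must lie within the generated range", call. = FALSE)
  if (!is.null(splice_junctions) &&
      length(splice_junctions) != length(splice_offsets))
    stop("splice_junctions and splice_offsets must match", call. = FALSE)
  structure(list(
    n_samples = as.integer(n_samples), varieties = varieties,
    treatments = treatments, treatment_means = treatment_means,
    treatment_sd = treatment_sd, n_percent_range = n_percent_range,
    features = features, confounders = confounders,
    noise_sigma = noise_sigma, amplitude_sd = amplitude_sd,
    grid = grid, splice_junctions = splice_junctions,
    splice_offsets = splice_offsets, sensor_id = sensor_id,
    seed = as.integer(seed)), class = "generator_config")
}

# fixed smooth continuum resembling green-leaf reflectance: visible trough
# with a green bump, sharp red edge, NIR plateau, gradual SWIR decline.
# Encoded as control points, not measured data.
.CONTINUUM_WL <- c(350, 400, 450, 500, 550, 600, 650, 680, 700, 720, 750,
                   800, 1000, 1200, 1400, 1500, 1660, 1800, 1900, 2000,
                   2100, 2200, 2350, 2500)
.CONTINUUM_R <- c(0.040, 0.050, 0.052, 0.080, 0.160, 0.110, 0.070, 0.060,
                  0.080, 0.200, 0.400, 0.470, 0.460, 0.430, 0.380, 0.350,
                  0.310, 0.280, 0.220, 0.200, 0.190, 0.170, 0.120, 0.080)

continuum_at <- function(wl) {
  stats::splinefun(.CONTINUUM_WL, .CONTINUUM_R, method = "natural")(wl)
}

#' Deterministic leaf reflectance model
#'
#' The noise-free part of the generator: continuum minus N-dependent feature
#' dips minus confounder dips, evaluated on an arbitrary wavelength grid.
#'
#' @param wl Wavelengths (nm).
#' @param n_percent Leaf nitrogen in percent of dry mass.
#' @param features,confounder_depths Feature table as in
#'   [generator_config()]; `confounder_depths` is a vector of realised depths
#'   (same rows as the config's confounder table), or `NULL` for none.
#' @param confounders Confounder table (centres/widths).
#' @return Reflectance vector on `wl`.
#' @export
leaf_reflectance <- function(wl, n_percent,
                             features = generator_config(seed = 0L)$features,
                             confounders = NULL, confounder_depths = NULL) {
  r <- continuum_at(wl)
  for (i in seq_len(nrow(features)))
    r <- r - features$depth_per_n[i] * n_percent *
      exp(-(wl - features$centre[i])^2 / (2 * features$width[i]^2))
  if (!is.null(confounders) && !is.null(confounder_depths))
    for (i in seq_len(nrow(confounders)))
      r <- r - confounder_depths[i] *
        exp(-(wl - confounders$centre[i])^2 / (2 * confounders$width[i]^2))
  r
}

#' Generate a synthetic measurement cohort with known ground truth
#'
#' @param cfg A `generator_config`.
#' @return List with `dataset` (a `spec_dataset` on the configured sensor
#'   grid) and `truth` (per-sample N%, realised confounder depths, amplitude
#'   factors and the configuration).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  variety <- rep_len(cfg$varieties, n)
  trt_idx <- rep_len(seq_along(cfg$treatments), n)
  n_percent <- with_seed(substream(cfg$seed, "nperc"), {
    v <- stats::rnorm(n, cfg$treatment_means[trt_idx], cfg$treatment_sd)
    pmin(pmax(v, cfg$n_percent_range[1]), cfg$n_percent_range[2])
  })
  n_conf <- nrow(cfg$confounders)
  conf_depths <- with_seed(substream(cfg$seed, "confounders"),
    matrix(stats::runif(n * n_conf, 0, rep(cfg$confounders$max_depth, each = n)),
           n, n_conf))
  amp <- if (cfg$amplitude_sd > 0)
    with_seed(substream(cfg$seed, "amplitude"),
              stats::rnorm(n, 1, cfg$amplitude_sd))
  else rep(1, n)
  # dense internal grid; the sensor grid is reached by Gaussian band resampling
  dense_wl <- seq(min(cfg$grid$centres), max(cfg$grid$centres), by = 1)
  dense <- band_spec(dense_wl, 1, label = "internal-1nm")
  identity_grid <- same_grid(dense_wl, cfg$grid$centres) &&
    all(abs(cfg$grid$fwhm - 1) <= .WL_TOL)
  W <- if (!identity_grid) gaussian_weights(dense, cfg$grid) else NULL
  noise <- with_seed(substream(cfg$seed, "noise"),
    matrix(stats::rnorm(n * length(dense_wl), 0, cfg$noise_sigma),
           n, length(dense_wl)))
  segs <- NULL
  if (!is.null(cfg$splice_junctions)) {
    cuts <- findInterval(cfg$grid$centres, sort(cfg$splice_junctions) + .WL_TOL)
    bounds <- split(seq_along(cuts), cuts)
    segs <- lapply(bounds, function(i) c(min(i), max(i)))
  }
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    r <- leaf_reflectance(dense_wl, n_percent[i], cfg$features,
                          cfg$confounders, conf_depths[i, ])
    r <- amp[i] * r + noise[i, ]
    v <- if (identity_grid) r else as.numeric(W %*% r)
    if (!is.null(cfg$splice_junctions))
      for (j in seq_along(cfg$splice_junctions))
        v[cfg$grid$centres > cfg$splice_junctions[j]] <-
          v[cfg$grid$centres > cfg$splice_junctions[j]] + cfg$splice_offsets[j]
    spectra[[i]] <- spectrum(ids[i], cfg$grid$centres, v, cfg$grid$fwhm,
                             sensor_id = cfg$sensor_id,
                             detector_segments = segs)
  }
  weights <- with_seed(substream(cfg$seed, "weights"),
                       stats::runif(n, 150, 500))
  ledger <- sample_ledger(ids, variety, cfg$treatments[trt_idx],
                          rep_len(1:3, n), weights, n_percent)
  list(dataset = spec_dataset(spectra, ledger, "FULL"),
       truth = list(n_percent = n_percent, confounder_depths = conf_depths,
                    amplitude = amp, config = cfg))
}

#' Synthetic leaf-bed cube layout
#'
#' @param dims Image size `(rows, cols)`.
#' @param marker List with `centre` `(row, col)`, `extent` `(height, width)`
#'   and `angle` (radians) of the blue fiducial marker rectangle.
#' @param leaf List with `rows` and `cols` (inclusive index ranges) of the
#'   leaf rectangle.
#' @param grid `band_spec` of the camera bands.
#' @return A layout list; overlapping marker and leaf regions are an error.
#' @export
cube_layout <- function(dims = c(60, 60),
                        marker = list(centre = c(12, 30),
                                      extent = c(6, 24), angle = 0),
                        leaf = list(rows = c(25, 50), cols = c(12, 52)),
                        grid = even_grid(450, 950, 10)) {
  stopifnot(inherits(grid, "band_spec"))
  roi <- leaf_bed_roi(marker$centre, marker$angle %||% 0, marker$extent)
  mmask <- roi_mask(roi, dims)
  lmask <- matrix(FALSE, dims[1], dims[2])
  lmask[leaf$rows[1]:leaf$rows[2], leaf$cols[1]:leaf$cols[2]] <- TRUE
  if (any(mmask & lmask))
    stop("marker and leaf regions overlap", call. = FALSE)
  list(dims = dims, marker_mask = mmask, leaf_mask = lmask, grid = grid,
       marker = marker, leaf = leaf)
}

#' Idealised blue-marker signature
#'
#' @param wl Wavelengths (nm).
#' @return Reflectance vector peaking in the blue around 465 nm.
#' @export
marker_signature <- function(wl) {
  0.06 + 0.55 * exp(-(wl - 465)^2 / (2 * 45^2))
}

#' Generate a raw synthetic leaf-bed cube with reference frames
#'
#' Builds a reflectance scene — black background, blue marker, leaf pixels
#' drawn from the cohort leaf model with per-pixel noise — and inverts the
#' dark/white calibration so that [calibrate_cube()] recovers the planted
#' reflectance exactly.
#'
#' @param cfg A `generator_config` (supplies the leaf model, noise level and
#'   seed).
#' @param layout A [cube_layout()].
#' @param n_percent Leaf N% of the imaged sample; when `NULL` one value is
#'   drawn from the cohort N% model.
#' @return List with `raw`, `dark`, `white` (`spectral_cube`s) and `truth`
#'   (planted `reflectance` cube, `marker_mask`, `leaf_mask`, clean
#'   `leaf_spectrum`, `n_percent`, `noise_sigma`).
#' @export
generate_cube <- function(cfg, layout = cube_layout(), n_percent = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  wl <- layout$grid$centres
  nb <- length(wl)
  d <- layout$dims
  if (is.null(n_percent))
    n_percent <- with_seed(substream(cfg$seed, "cube-nperc"), {
      trt <- sample(seq_along(cfg$treatments), 1)
      v <- stats::rnorm(1, cfg$treatment_means[trt], cfg$treatment_sd)
      pmin(pmax(v, cfg$n_percent_range[1]), cfg$n_percent_range[2])
    })
  dense_wl <- seq(min(.CONTINUUM_WL), max(.CONTINUUM_WL), by = 1)
  dense <- band_spec(dense_wl, 1)
  W <- gaussian_weights(dense, layout$grid)
  leaf_clean <- as.numeric(W %*% leaf_reflectance(dense_wl, n_percent,
                                                  cfg$features))
  marker_sig <- marker_signature(wl)
  refl <- array(0.05, dim = c(d[1], d[2], nb))
  for (b in seq_len(nb)) {
    plane <- refl[, , b]
    plane[layout$marker_mask] <- marker_sig[b]
    plane[layout$leaf_mask] <- leaf_clean[b]
    refl[, , b] <- plane
  }
  npx <- d[1] * d[2]
  noise <- with_seed(substream(cfg$seed, "cube-noise"),
                     array(stats::rnorm(npx * nb, 0, cfg$noise_sigma),
                           dim = c(d[1], d[2], nb)))
  refl <- refl + noise
  frames <- with_seed(substream(cfg$seed, "cube-frames"), {
    dark <- array(95 + 10 * stats::runif(npx * nb), dim = c(d[1], d[2], nb))
    white <- array(3500 + 300 * stats::runif(npx * nb), dim = c(d[1], d[2], nb))
    list(dark = dark, white = white)
  })
  raw <- refl * (frames$white - frames$dark) + frames$dark
  list(
    raw = spectral_cube(raw, wl, layout$grid$fwhm, calibrated = FALSE,
                        sensor_id = cfg$sensor_id),
    dark = spectral_cube(frames$dark, wl, layout$grid$fwhm,
                         calibrated = FALSE, sensor_id = cfg$sensor_id),
    white = spectral_cube(frames$white, wl, layout$grid$fwhm,
                          calibrated = FALSE, sensor_id = cfg$sensor_id),
    truth = list(reflectance = refl,
                 marker_mask = layout$marker_mask,
                 leaf_mask = layout$leaf_mask,
                 leaf_spectrum = leaf_clean,
                 marker_signature = marker_sig,
                 n_percent = n_percent,
                 noise_sigma = cfg$noise_sigma))
}

#' Generate a ledger fixture with known pathological records
#'
#' Builds a sample ledger containing exactly the requested numbers of
#' under-weight leaves (dried weight below 100 mg, no laboratory N%),
#' N% outliers (values outside the 1-7% window) and acquisition errors
#' (pre-flagged, no N%); the remainder are valid records. Categories are
#' disjoint.
#'
#' @param n_total Total number of records.
#' @param n_too_small,n_outlier,n_error Pathological counts; their sum must
#'   not exceed `n_total`.
#' @param seed Integer seed.
#' @return A `sample_ledger` of `n_total` rows in randomised category order.
#' @export
generate_ledger_for_cleaning <- function(n_total, n_too_small = 0L,
                                         n_outlier = 0L, n_error = 0L, seed = 1L) {
  bad <- n_too_small + n_outlier + n_error
  if (bad > n_total)
    stop(sprintf("infeasible counts: %d pathological > %d total", bad, n_total),
         call. = FALSE)
  with_seed(substream(seed, "ledger"), {
    n_ok <- n_total - bad
    cat_lab <- sample(rep(c("ok", "too_small", "n_outlier", "acquisition_error"),
                          c(n_ok, n_too_small, n_outlier, n_error)))
    weight <- ifelse(cat_lab == "too_small", stats::runif(n_total, 20, 99.5),
                     stats::runif(n_total, 150, 500))
    n_pct <- stats::runif(n_total, 1.5, 6.5)
    n_pct[cat_lab == "n_outlier"] <-
      ifelse(stats::runif(n_outlier) < 0.5,
             stats::runif(n_outlier, 0.2, 0.99),
             stats::runif(n_outlier, 7.01, 9.5))
    n_pct[cat_lab %in% c("too_small", "acquisition_error")] <- NA_real_
    flag <- ifelse(cat_lab == "acquisition_error", "acquisition_error", "none")
    sample_ledger(sprintf("L%04d", seq_len(n_total)),
                  rep_len(paste0("V", 1:5), n_total),
                  rep_len(c(25, 50, 100, 200), n_total),
                  rep_len(1:3, n_total), weight, n_pct, flag)
  })
}
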