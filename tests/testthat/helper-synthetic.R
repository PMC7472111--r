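# Shared fixture builders. Everything is generated in code at test time.

# a tiny cohort on a coarse grid, fast enough for format/regression tests
tiny_cohort <- function(n = 30L, seed = 101L, noise_sigma = 0.005,
                        grid = band_spec(seq(400, 2400, by = 10), 10)) {
  cfg0 <- generator_config(seed = seed)
  feats <- cfg0$features[cfg0$features$centre >= min(grid$centres) &
                           cfg0$features$centre <= max(grid$centres), ]
  generate_cohort(generator_config(n_samples = n, noise_sigma = noise_sigma,
                                   grid = grid, features = feats, seed = seed))
}

# default-condition cohort on the native 1 nm grid, pre-processed
preprocessed_cohort <- function(n = 300L, seed = 11L, noise_sigma = 0.005) {
  coh <- generate_cohort(generator_config(n_samples = n,
                                          noise_sigma = noise_sigma,
                                          seed = seed))
  d <- coh$dataset
  d$spectra <- lapply(d$spectra, preprocess_spectrum)
  list(dataset = spec_dataset(d$spectra, d$records, "FULL"),
       truth = coh$truth)
}

# calibrated synthetic leaf-bed scene plus training hues sampled from the
# planted leaf region
leaf_bed_scene <- function(seed = 3L, n_train = 300L, noise_sigma = 0.005) {
  cfg <- generator_config(n_samples = 10L, noise_sigma = noise_sigma,
                          seed = seed)
  cube <- generate_cube(cfg)
  cal <- calibrate_cube(cube$raw, cube$dark, cube$white)
  idx <- which(cube$truth$leaf_mask, arr.ind = TRUE)
  pick <- with_seed_test(seed, sample(nrow(idx), n_train))
  px <- t(apply(idx[pick, , drop = FALSE], 1,
                function(rc) pixel_signature(cal, rc[1], rc[2])))
  hues <- t(apply(px, 1, hyper_hue))
  geometry <- list(offset = c(0, 26), extent = c(30, 45))
  list(cube = cube, cal = cal, hues = hues, geometry = geometry, cfg = cfg)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

expect_no_na <- function(x) testthat::expect_false(anyNA(x))
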