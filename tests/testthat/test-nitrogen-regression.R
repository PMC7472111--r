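test_that("cleaning rules apply the weight and N% windows with strict bounds", {
  led <- sample_ledger(
    paste0("s", 1:6), "V1", 50, 1,
    dried_weight = c(99, 100, 300, 300, 300, 300),
    n_percent = c(NA, 3, 0.9, 7.0, 1.0, 7.1))
  out <- clean_records(led)
  expect_identical(out$sample_id, c("s2", "s4", "s5"))   # 7.0 and 1.0 retained
  flagged <- attr(out, "flagged")
  expect_identical(flagged$exclusion_flag,
                   c("too_small", "none", "n_outlier", "none", "none", "n_outlier"))
})

test_that("the synthetic cleaning fixture reproduces the survivor count", {
  led <- generate_ledger_for_cleaning(600, 42, 8, 7, seed = 2L)
  expect_equal(nrow(led), 600L)
  out <- clean_records(led)
  expect_identical(nrow(out), 543L)
  expect_true(all(out$exclusion_flag == "none"))
  expect_false(anyNA(out$n_percent))
})

test_that("accuracy metrics match hand-computed values", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$r2, 0.5, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(m$bias, 1 / 3, tolerance = 1e-12)
  expect_equal(m$mean_abs, 1 / 3, tolerance = 1e-12)
  expect_identical(m$median_abs, 0)

  y <- c(2.5, 3.5, 1.0, 4.2)
  perfect <- regression_metrics(y, y)
  expect_identical(perfect$r2, 1)
  expect_identical(perfect$rmse, 0)
  # the mean predictor scores exactly zero
  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2, 0, tolerance = 1e-12)
  # R2 can go negative for models worse than the mean
  expect_lt(regression_metrics(y, rev(y) + 5)$r2, 0)
  expect_error(regression_metrics(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  # rmse >= |bias| on random pairs
  for (seed in 1:5) {
    yy <- with_seed_test(seed, stats::rnorm(20))
    pp <- with_seed_test(seed + 100, stats::rnorm(20))
    mm <- regression_metrics(yy, pp)
    expect_gte(mm$rmse, abs(mm$bias))
  }
})

make_linear_dataset <- function(n = 40L, noise = 0, seed = 5L) {
  wl <- c(500, 600, 700, 800)
  beta <- c(2, -1.5, 0.8, 0)
  with_seed_test(seed, {
    X <- matrix(stats::runif(n * 4, 0.1, 0.6), n, 4)
    y <- 1.5 + X %*% beta + stats::rnorm(n, 0, noise)
    y <- pmin(pmax(as.numeric(y), 1), 7)
    spectra <- lapply(seq_len(n), function(i)
      spectrum(sprintf("s%03d", i), wl, X[i, ], 10))
    led <- sample_ledger(sprintf("s%03d", seq_len(n)), "V1", 50, 1, 300, y)
    spec_dataset(spectra, led)
  })
}

test_that("PLSR attains the least-squares solution on noiseless linear data", {
  d <- make_linear_dataset(noise = 0)
  fit <- fit_plsr_cv(d, lv_range = 1:4, seed = 3L)
  expect_gte(fit$avg_metrics$r2, 0.999)
  # fold coefficients agree with an ordinary least-squares oracle per fold
  xy <- as_xy(d)
  for (f in 1:5) {
    tr <- which(fit$folds != f)
    ols <- stats::lm.fit(cbind(1, xy$X[tr, ]), xy$y[tr])
    fm <- fit$fold_models[[f]]
    if (fm$ncomp == 4L)
      expect_equal(unname(fm$coefficients), unname(ols$coefficients[-1]),
                   tolerance = 1e-8)
    expect_equal(fm$predictions,
                 as.numeric(xy$X[fm$val_idx, ] %*% fm$coefficients + fm$intercept))
  }
})

test_that("a permuted response destroys the cross-validated fit", {
  d <- make_linear_dataset(n = 60L, noise = 0.05)
  d$records$n_percent <- with_seed_test(17, sample(d$records$n_percent))
  fit <- fit_plsr_cv(d, lv_range = 1:4, seed = 3L)
  expect_lte(fit$avg_metrics$r2, 0.1)
})

test_that("folds partition the samples and the fit is seed-deterministic", {
  d <- make_linear_dataset(n = 37L, noise = 0.02)
  fit <- fit_plsr_cv(d, lv_range = 1:4, seed = 9L)
  idx <- sort(unlist(lapply(fit$fold_models, `[[`, "val_idx")))
  expect_identical(idx, seq_len(37L))              # exclusivity + coverage
  fit2 <- fit_plsr_cv(d, lv_range = 1:4, seed = 9L)
  expect_identical(fit$folds, fit2$folds)
  expect_identical(fit$avg_coefficients, fit2$avg_coefficients)
  expect_identical(fit$avg_metrics, fit2$avg_metrics)
  fit3 <- fit_plsr_cv(d, lv_range = 1:4, seed = 10L)
  expect_false(identical(fit$folds, fit3$folds))
})

test_that("duplicating every sample leaves the consensus model unchanged", {
  d <- make_linear_dataset(n = 30L, noise = 0)
  dup_spectra <- c(d$spectra,
                   lapply(d$spectra, function(s) {
                     s$sample_id <- paste0(s$sample_id, "b"); s
                   }))
  dup_led <- rbind(d$records, transform(d$records,
                                        sample_id = paste0(sample_id, "b")))
  dup <- spec_dataset(dup_spectra, sample_ledger(
    dup_led$sample_id, dup_led$variety, dup_led$n_treatment,
    dup_led$time_point, dup_led$dried_weight, dup_led$n_percent))
  # duplicates share folds via the grouping option; the component count is
  # pinned so both fits solve the same problem on each training partition
  fit1 <- fit_plsr_cv(d, lv_range = 4, seed = 3L)
  fit2 <- fit_plsr_cv(dup, lv_range = 4, seed = 3L,
                      groups = rep(d$records$sample_id, 2))
  for (f in 1:5)
    expect_equal(fit2$fold_models[[f]]$coefficients,
                 fit1$fold_models[[f]]$coefficients, tolerance = 1e-8)
  expect_equal(fit2$consensus$coefficients, fit1$consensus$coefficients,
               tolerance = 1e-8)
  expect_equal(fit2$consensus$intercept, fit1$consensus$intercept,
               tolerance = 1e-8)
})

test_that("the latent-variable range is capped with a warning on tiny folds", {
  d <- make_linear_dataset(n = 12L, noise = 0.01)
  expect_warning(fit_plsr_cv(d, lv_range = 1:20, seed = 1L), "capped")
})

test_that("PLS1 coefficients agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(21)
  X <- matrix(stats::rnorm(50 * 15), 50, 15)
  colnames(X) <- paste0("b", seq_len(15))
  y <- as.numeric(0.6 * X[, 2] - 0.4 * X[, 9] + stats::rnorm(50, 0, 0.1))
  path <- nitrospec:::pls1_path(X, y, 5)
  Xt <- matrix(stats::rnorm(12 * 15), 12, 15)
  colnames(Xt) <- colnames(X)
  mine <- Xt %*% path$coef_path[, 5] + path$intercept_path[5]
  ref <- mixOmics::pls(X, y, ncomp = 5, mode = "regression", scale = FALSE)
  theirs <- predict(ref, Xt)$predict[, 1, 5]
  expect_equal(as.numeric(mine), as.numeric(theirs), tolerance = 1e-10)
})

test_that("key-wavelengths land on the analytic extrema of a planted curve", {
  wl <- seq(400, 1000, 1)
  curve <- sin(2 * pi * wl / 200)
  fake <- structure(list(avg_coefficients = curve, wavelengths = wl),
                    class = "plsr_cv_fit")
  kw <- key_wavelengths(fake, top_k = 6L)
  analytic <- seq(450, 950, by = 100)     # d/dl sin(2*pi*l/200) = 0
  expect_length(kw$wavelength, 6L)
  expect_true(all(vapply(kw$wavelength,
                         function(w) min(abs(w - analytic)) <= 1, logical(1))))
  # magnitudes are non-increasing with rank and wavelengths unique
  expect_true(all(diff(kw$coefficient) <= 1e-12))
  expect_false(anyDuplicated(kw$wavelength) > 0)
})

test_that("monotone curves yield no keys and plateaus collapse to their centre", {
  mono <- structure(list(avg_coefficients = seq(0, 1, length.out = 50),
                         wavelengths = 401:450), class = "plsr_cv_fit")
  expect_warning(kw <- key_wavelengths(mono, 3), "no interior extrema")
  expect_identical(nrow(kw), 0L)
  flat_top <- structure(
    list(avg_coefficients = c(0, 1, 2, 3, 3, 3, 2, 1, 0),
         wavelengths = 401:409), class = "plsr_cv_fit")
  kw2 <- key_wavelengths(flat_top, 1)
  expect_identical(kw2$wavelength, 405L)            # plateau centre
  # asking for more keys than extrema warns and returns all
  expect_warning(key_wavelengths(flat_top, 5), "extrema available")
})

test_that("cross-sensor application is linear and reproduces in-sample predictions", {
  d <- make_linear_dataset(n = 40L, noise = 0.02)
  fit <- fit_plsr_cv(d, lv_range = 1:4, seed = 3L)
  pred <- apply_cross_sensor(fit, d$spectra)
  xy <- as_xy(d)
  manual <- as.numeric(xy$X %*% fit$consensus$coefficients +
                         fit$consensus$intercept)
  expect_equal(unname(pred), manual)
  # adding a constant c to every band shifts predictions by c * sum(coefs)
  shifted <- lapply(d$spectra, function(s) { s$values <- s$values + 0.02; s })
  pred2 <- apply_cross_sensor(fit, shifted)
  expect_equal(unname(pred2 - pred),
               rep(0.02 * sum(fit$consensus$coefficients), 40),
               tolerance = 1e-10)
  # grid mismatch is an error
  off <- lapply(d$spectra, function(s) { s$wavelengths <- s$wavelengths + 1; s })
  expect_error(apply_cross_sensor(fit, off), "resample")
})

test_that("a planted gain mismatch shows up as bias with a near-unit slope", {
  d <- make_linear_dataset(n = 60L, noise = 0.01)
  fit <- fit_plsr_cv(d, lv_range = 1:4, seed = 3L)
  distorted <- lapply(d$spectra, function(s) { s$values <- s$values * 1.15; s })
  y <- d$records$n_percent
  pred <- apply_cross_sensor(fit, distorted, reference = y)
  met <- attr(pred, "metrics")
  expect_gt(abs(met$bias), 0.02)
  slope <- stats::coef(stats::lm(pred ~ y))[2]
  expect_equal(unname(slope), 1, tolerance = 0.2)
})

test_that("validation accuracy degrades monotonically with noise", {
  r2 <- vapply(c(0.002, 0.01, 0.05), function(sig) {
    coh <- generate_cohort(generator_config(n_samples = 150L,
                                            noise_sigma = sig, seed = 21L))
    dd <- coh$dataset
    dd$spectra <- lapply(dd$spectra, preprocess_spectrum)
    dd <- spec_dataset(dd$spectra, dd$records, "FULL")
    fit_plsr_cv(dd, seed = 9L)$avg_metrics$r2
  }, numeric(1))
  expect_true(all(diff(r2) <= 0.02))
})
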