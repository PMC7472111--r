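#' Normalised difference of two reflectance values
#'
#' `ndvi(r_i, r_j) = (r_i - r_j) / (r_i + r_j)`, the normalised difference
#' vegetation index generalised to any wavelength pair. Antisymmetric in its
#' arguments and bounded in `[-1, 1]` for non-negative reflectance. A zero
#' denominator yields `NA` (an undefined-value marker excluded from
#' regressions), never an error.
#'
#' @param r_i,r_j Reflectance values (vectorised).
#' @return Dimensionless index values.
#' @export
ndvi <- function(r_i, r_j) {
  denom <- r_i + r_j
  out <- (r_i - r_j) / denom
  out[denom == 0] <- NA_real_
  out
}

#' NDVI matrix of a single spectrum
#'
#' All pairwise NDVI values of one signature over `[lo, hi]`: entry `(i, j)`
#' is `ndvi(r_i, r_j)`, so the matrix is antisymmetric with a zero diagonal.
#'
#' @param s A `spectrum`.
#' @param lo,hi Wavelength window in nm.
#' @return Square matrix with wavelength dimnames.
#' @export
ndvi_matrix <- function(s, lo = 400, hi = 2400) {
  stopifnot(inherits(s, "spectrum"))
  keep <- s$wavelengths >= lo & s$wavelengths <= hi
  v <- s$values[keep]
  wl <- s$wavelengths[keep]
  m <- outer(v, v, ndvi)
  diag(m)[v == 0] <- NA_real_   # 0/0 on the diagonal
  diag(m)[v != 0] <- 0
  dimnames(m) <- list(wl, wl)
  m
}

#' Cross-validated R-squared matrix of all NDVI wavelength pairs
#'
#' For every unordered wavelength pair in `[lo, hi]`, N% is regressed on
#' `ndvi(lambda_i, lambda_j)` by univariate least squares under the same
#' seeded k-fold assignment used for the PLSR models; the fold-averaged
#' validation R-squared is stored. The matrix is symmetric under pair swap
#' (flipping the predictor's sign leaves least-squares R-squared unchanged),
#' so each pair is evaluated once and mirrored. Diagonal entries (constant
#' predictor) and pairs with undefined NDVI or zero predictor variance are
#' `NA`.
#'
#' @param data A `spec_dataset` with reference N% for every sample.
#' @param lo,hi Wavelength window in nm.
#' @param k_folds,seed Cross-validation settings shared with [fit_plsr_cv()].
#' @return List with `r2` (symmetric matrix, wavelength dimnames),
#'   `best_pair` (wavelengths, descending R-squared order `(lambda_i,
#'   lambda_j)` with `lambda_i > lambda_j`), and `best_r2`.
#' @export
ndvi_r2_matrix <- function(data, lo = 400, hi = 2400, k_folds = 5L, seed = 1L) {
  xy <- as_xy(data)
  keep <- xy$wavelengths >= lo & xy$wavelengths <= hi
  X <- xy$X[, keep, drop = FALSE]
  wl <- xy$wavelengths[keep]
  y <- xy$y
  n <- length(y); p <- length(wl)
  if (p < 2L) stop("window contains fewer than two bands", call. = FALSE)
  folds <- make_folds(n, k_folds, seed = seed)
  r2 <- matrix(NA_real_, p, p, dimnames = list(wl, wl))
  for (j in seq_len(p - 1L)) {
    jj <- (j + 1L):p
    Z <- (X[, j] - X[, jj, drop = FALSE]) / (X[, j] + X[, jj, drop = FALSE])
    Z[!is.finite(Z)] <- NA_real_
    r2_acc <- numeric(length(jj))
    valid <- colSums(is.na(Z)) == 0L
    for (f in seq_len(k_folds)) {
      tr <- folds != f; va <- folds == f
      zt <- Z[tr, , drop = FALSE]; zv <- Z[va, , drop = FALSE]
      zbar <- colMeans(zt)
      zc <- sweep(zt, 2, zbar)
      vz <- colSums(zc^2)
      b <- colSums(zc * (y[tr] - mean(y[tr]))) / vz
      b[vz < 1e-20] <- NA_real_
      a <- mean(y[tr]) - b * zbar
      pred <- sweep(sweep(zv, 2, b, `*`), 2, a, `+`)
      res <- pred - y[va]   # recycles down columns: per-sample residuals
      ss_tot <- sum((y[va] - mean(y[va]))^2)
      r2_acc <- r2_acc + (1 - colSums(res^2) / ss_tot)
    }
    r2_acc <- r2_acc / k_folds
    r2_acc[!valid] <- NA_real_
    r2[j, jj] <- r2_acc
    r2[jj, j] <- r2_acc
  }
  best <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
  pair <- sort(c(wl[best[1]], wl[best[2]]), decreasing = TRUE)
  list(r2 = r2, best_pair = pair, best_r2 = max(r2, na.rm = TRUE))
}

#' Normalised red edge area index
#'
#' `NREAI = (SD_r - SD_b) / (SD_r + SD_b)`, where `SD_b` and `SD_r` are the
#' integrals of the first-derivative spectrum over the blue edge (490-530 nm)
#' and red edge (670-737 nm). The derivative uses central finite differences
#' on the native grid (one-sided at the ends) and the integrals use the
#' trapezoidal rule. A zero `SD_r + SD_b` (e.g. a constant spectrum) yields
#' `NA`, an undefined-value marker.
#'
#' @param s A `spectrum` whose grid covers both edge windows.
#' @param blue_edge,red_edge Integration windows in nm.
#' @return Dimensionless index value, or `NA` when undefined.
#' @export
nreai <- function(s, blue_edge = c(490, 530), red_edge = c(670, 737)) {
  stopifnot(inherits(s, "spectrum"))
  wl <- s$wavelengths; v <- s$values
  if (min(wl) > blue_edge[1] || max(wl) < red_edge[2])
    stop("spectrum does not cover the blue and red edge windows", call. = FALSE)
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (wl[3:n] - wl[1:(n - 2)])
  d[1] <- (v[2] - v[1]) / (wl[2] - wl[1])
  d[n] <- (v[n] - v[n - 1]) / (wl[n] - wl[n - 1])
  trapz_window <- function(win) {
    i <- which(wl >= win[1] & wl <= win[2])
    if (length(i) < 2L) stop("fewer than two bands in edge window", call. = FALSE)
    sum(diff(wl[i]) * (d[i][-1] + d[i][-length(i)]) / 2)
  }
  sd_b <- trapz_window(blue_edge)
  sd_r <- trapz_window(red_edge)
  if (sd_r + sd_b == 0) return(NA_real_)
  (sd_r - sd_b) / (sd_r + sd_b)
}

#' Cross-validated univariate regression of N% on a vegetation index
#'
#' Least squares of the reference N% on a single index series under the same
#' seeded fold assignment as the PLSR models. Samples with undefined (`NA`)
#' index values are excluded before fold assignment.
#'
#' @param data A `spec_dataset`.
#' @param vi Numeric index series aligned with the dataset samples, or a
#'   function applied to each `spectrum` (e.g. [nreai()]).
#' @param k_folds,seed Cross-validation settings.
#' @return List with `avg_metrics` (fold-averaged), `metrics` (per fold),
#'   `predictions` (pooled validation predictions) and `n_used`.
#' @export
vi_regression <- function(data, vi, k_folds = 5L, seed = 1L) {
  stopifnot(inherits(data, "spec_dataset"))
  if (is.function(vi)) vi <- vapply(data$spectra, vi, numeric(1))
  y <- data$records$n_percent
  ok <- is.finite(vi) & is.finite(y)
  if (sum(ok) < 3L) stop("fewer than 3 valid samples for VI regression", call. = FALSE)
  vi <- vi[ok]; y <- y[ok]
  n <- length(y)
  folds <- make_folds(n, k_folds, seed = seed)
  pooled <- rep(NA_real_, n)
  mets <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f; va <- folds == f
    fit <- stats::lm.fit(cbind(1, vi[tr]), y[tr])
    pred <- fit$coefficients[1] + fit$coefficients[2] * vi[va]
    pooled[va] <- pred
    mets[[f]] <- regression_metrics(y[va], pred)
  }
  avg <- lapply(c("r2", "rmse", "bias", "mean_abs", "median_abs"),
                function(m) mean(vapply(mets, `[[`, numeric(1), m)))
  names(avg) <- c("r2", "rmse", "bias", "mean_abs", "median_abs")
  list(avg_metrics = avg, metrics = mets, predictions = pooled, n_used = n)
}
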