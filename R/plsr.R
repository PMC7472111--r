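#' Apply the outlier and data-cleaning rules to a ledger
#'
#' Leaves with a dried weight below 100 mg could not be assayed and are
#' flagged `too_small`; reference nitrogen below 1% or above 7% (strict
#' inequalities, so 1.0 and 7.0 are retained) is flagged `n_outlier`;
#' pre-existing `acquisition_error` flags are kept. Only unflagged records
#' are returned.
#'
#' @param records A `sample_ledger`.
#' @param min_weight Minimum dried weight in mg (default 100).
#' @param n_low,n_high Valid N% window (defaults 1 and 7).
#' @return The surviving `sample_ledger`; attribute `"flagged"` carries the
#'   full ledger with updated flags.
#' @export
clean_records <- function(records, min_weight = 100, n_low = 1, n_high = 7) {
  validate_ledger(records)
  flag <- records$exclusion_flag
  too_small <- records$dried_weight < min_weight
  flag[flag == "none" & too_small] <- "too_small"
  outlier <- !is.na(records$n_percent) &
    (records$n_percent < n_low | records$n_percent > n_high)
  flag[flag == "none" & outlier] <- "n_outlier"
  records$exclusion_flag <- flag
  out <- records[flag == "none", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- records
  out
}

#' Regression accuracy metrics
#'
#' Computes the coefficient of determination
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` (which may be
#' negative for models worse than the mean predictor), the root mean square
#' error, the signed bias `mean(yhat - y)`, and the mean and median absolute
#' errors. All error metrics are in the units of `y` (N%).
#'
#' @param y Reference values.
#' @param yhat Predicted values, same length as `y` (length >= 2).
#' @return A list of class `"metrics_report"` with elements `r2`, `rmse`,
#'   `bias`, `mean_abs`, `median_abs` and `n`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length", call. = FALSE)
  if (length(y) < 2L) stop("need at least two samples", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R2 undefined: y has zero variance", call. = FALSE)
  err <- yhat - y
  structure(list(
    r2 = 1 - sum(err^2) / ss_tot,
    rmse = sqrt(mean(err^2)),
    bias = mean(err),
    mean_abs = mean(abs(err)),
    median_abs = stats::median(abs(err)),
    n = length(y)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("R2 = %.4f  RMSE = %.4f  Bias = %+.4f  MeanABS = %.4f  MedianABS = %.4f  (n = %d)\n",
              x$r2, x$rmse, x$bias, x$mean_abs, x$median_abs, x$n))
  invisible(x)
}

# ---- PLS1 core --------------------------------------------------------------

# NIPALS PLS1 with mean-centred predictors and response (no unit-variance
# scaling: reflectance shares units across bands). Returns the full nested
# coefficient path so one decomposition serves every candidate component
# count during model selection.
pls1_path <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  xbar <- colMeans(X); ybar <- mean(y)
  Xd <- sweep(X, 2, xbar)
  yd <- y - ybar
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  used <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break   # response fully deflated
    w <- w / wn
    tt <- Xd %*% w
    t2 <- sum(tt^2)
    pk <- crossprod(Xd, tt) / t2
    qk <- sum(yd * tt) / t2
    Xd <- Xd - tt %*% t(pk)
    yd <- yd - qk * as.numeric(tt)
    W[, k] <- w; P[, k] <- pk; Q[k] <- qk
    used <- k
  }
  if (used == 0L) {
    coef_path <- matrix(0, p, 1L)
    return(list(coef_path = coef_path, intercept_path = ybar,
                ncomp = 1L, xbar = xbar, ybar = ybar))
  }
  # B_k = W_k (P_k' W_k)^{-1} q_k built recursively via the R-weights
  Rw <- matrix(0, p, used)
  B <- matrix(0, p, used)
  b <- numeric(p)
  for (k in seq_len(used)) {
    r <- W[, k]
    if (k > 1L)
      r <- r - Rw[, 1:(k - 1L), drop = FALSE] %*%
        crossprod(P[, 1:(k - 1L), drop = FALSE], W[, k])
    Rw[, k] <- r
    b <- b + Q[k] * as.numeric(r)
    B[, k] <- b
  }
  list(coef_path = B,
       intercept_path = ybar - as.numeric(crossprod(B, xbar)),
       ncomp = used, xbar = xbar, ybar = ybar)
}

# validation RMSE for every candidate component count of a fitted path
path_rmse <- function(path, X, y) {
  pred <- X %*% path$coef_path
  pred <- sweep(pred, 2, path$intercept_path, `+`)
  sqrt(colMeans((pred - y)^2))
}

#' Cross-validated PLSR of nitrogen content on reflectance
#'
#' Fits partial least squares regression (PLS1, NIPALS) of the reference N%
#' on the reflectance matrix under k-fold cross-validation. Fold assignment
#' is a seeded permutation. Within each training partition the number of
#' latent variables is selected by an inner k-fold cross-validation
#' (minimising pooled RMSE over the candidate range), the model is refit on
#' the full training partition, and the held-out fold is predicted. A
#' consensus model refit on all samples (with the median selected component
#' count) is stored for cross-sensor application.
#'
#' @param data A `spec_dataset` (cleaned records, shared grid).
#' @param k_folds Number of outer folds (default 5).
#' @param lv_range Candidate latent-variable counts (default `1:20`); counts
#'   above `min(n_train - 1, n_bands)` are capped with a warning.
#' @param seed Integer seed driving fold assignment.
#' @param groups Optional grouping vector (e.g. plant id) to keep repeated
#'   measures in one fold; default `NULL` randomises at the sample level.
#' @return An object of class `"plsr_cv_fit"`: `folds` (assignment),
#'   `fold_models` (per fold: `coefficients`, `intercept`, `ncomp`,
#'   `val_idx`, `predictions`, `metrics`), `avg_coefficients` (pointwise mean
#'   of the fold coefficient vectors), `metrics` (per-fold list),
#'   `avg_metrics` (fold-averaged), `predictions` (pooled, one per sample),
#'   `consensus` (refit on all samples) and `wavelengths`.
#' @export
fit_plsr_cv <- function(data, k_folds = 5L, lv_range = 1:20, seed = 1L,
                        groups = NULL) {
  xy <- as_xy(data)
  X <- xy$X; y <- xy$y
  n <- nrow(X); p <- ncol(X)
  if (anyNA(y)) stop("n_percent missing; clean the ledger first", call. = FALSE)
  if (n < k_folds) stop("fewer samples than folds", call. = FALSE)
  lv_max <- max(lv_range)
  folds <- make_folds(n, k_folds, seed = seed, groups = groups)
  fold_models <- vector("list", k_folds)
  metrics_by_fold <- vector("list", k_folds)
  pooled_pred <- rep(NA_real_, n)
  warned_cap <- FALSE
  for (f in seq_len(k_folds)) {
    tr <- which(folds != f); va <- which(folds == f)
    cap <- min(length(tr) - 1L, p)
    if (lv_max > cap && !warned_cap) {
      warning(sprintf("latent-variable range capped at %d (n_train - 1 or band count)",
                      cap), call. = FALSE)
      warned_cap <- TRUE
    }
    kmax <- min(lv_max, cap)
    cand <- lv_range[lv_range <= kmax]
    # inner CV on the training partition only, so selection never sees the
    # held-out fold
    inner <- make_folds(length(tr), k_folds, seed = substream(seed, paste0("inner", f)))
    sse <- numeric(kmax); cnt <- 0L
    for (g in seq_len(k_folds)) {
      itr <- tr[inner != g]; iva <- tr[inner == g]
      path <- pls1_path(X[itr, , drop = FALSE], y[itr], kmax)
      pred <- X[iva, , drop = FALSE] %*% path$coef_path
      pred <- sweep(pred, 2, path$intercept_path, `+`)
      if (path$ncomp < kmax)   # pad: deflation exhausted early, model is flat
        pred <- cbind(pred, matrix(pred[, path$ncomp], length(iva),
                                   kmax - path$ncomp))
      sse <- sse + colSums((pred - y[iva])^2)
      cnt <- cnt + length(iva)
    }
    rmse_k <- sqrt(sse / cnt)
    best_k <- cand[which.min(rmse_k[cand])]
    path <- pls1_path(X[tr, , drop = FALSE], y[tr], best_k)
    kk <- min(best_k, path$ncomp)
    coefs <- path$coef_path[, kk]
    icpt <- path$intercept_path[kk]
    pred <- as.numeric(X[va, , drop = FALSE] %*% coefs + icpt)
    pooled_pred[va] <- pred
    met <- regression_metrics(y[va], pred)
    fold_models[[f]] <- list(coefficients = coefs, intercept = icpt,
                             ncomp = as.integer(kk), val_idx = va,
                             predictions = pred, metrics = met)
    metrics_by_fold[[f]] <- met
  }
  avg_coef <- rowMeans(vapply(fold_models, `[[`, numeric(p), "coefficients"))
  avg_metrics <- lapply(c("r2", "rmse", "bias", "mean_abs", "median_abs"),
                        function(m) mean(vapply(metrics_by_fold, `[[`, numeric(1), m)))
  names(avg_metrics) <- c("r2", "rmse", "bias", "mean_abs", "median_abs")
  cons_k <- as.integer(round(stats::median(
    vapply(fold_models, `[[`, integer(1), "ncomp"))))
  cons_path <- pls1_path(X, y, cons_k)
  ck <- min(cons_k, cons_path$ncomp)
  structure(list(
    folds = folds,
    fold_models = fold_models,
    avg_coefficients = avg_coef,
    metrics = metrics_by_fold,
    avg_metrics = avg_metrics,
    predictions = pooled_pred,
    consensus = list(coefficients = cons_path$coef_path[, ck],
                     intercept = cons_path$intercept_path[ck], ncomp = ck),
    wavelengths = xy$wavelengths,
    sample_id = xy$sample_id,
    y = y,
    seed = seed), class = "plsr_cv_fit")
}

#' @export
print.plsr_cv_fit <- function(x, ...) {
  cat(sprintf("<plsr_cv_fit> %d samples, %d bands, %d folds; avg validation R2 = %.3f (RMSE %.3f)\n",
              length(x$y), length(x$wavelengths), length(x$fold_models),
              x$avg_metrics$r2, x$avg_metrics$rmse))
  cat("  latent variables per fold:",
      paste(vapply(x$fold_models, `[[`, integer(1), "ncomp"), collapse = ", "), "\n")
  invisible(x)
}

#' Key-wavelength identification from averaged PLSR coefficients
#'
#' The fold coefficient vectors are averaged pointwise and the wavelengths at
#' strict interior local extrema of the averaged curve are ranked by the
#' magnitude of the averaged coefficient, descending. A run of equal values
#' (plateau) counts as a single extremum at its centre band.
#'
#' @param fit A `plsr_cv_fit` over at least two bands.
#' @param top_k Number of key-wavelengths to return; when more than the
#'   number of extrema, all extrema are returned with a warning.
#' @return A `data.frame` of class `"key_wavelength_set"` with columns
#'   `rank`, `wavelength`, `coefficient` (absolute averaged coefficient) and
#'   `sign`.
#' @export
key_wavelengths <- function(fit, top_k = 26L) {
  stopifnot(inherits(fit, "plsr_cv_fit"))
  cf <- fit$avg_coefficients
  if (length(cf) < 2L) stop("need at least two bands", call. = FALSE)
  ext <- local_extrema(cf)
  if (length(ext) == 0L) {
    warning("coefficient curve has no interior extrema", call. = FALSE)
    out <- data.frame(rank = integer(0), wavelength = numeric(0),
                      coefficient = numeric(0), sign = integer(0))
    class(out) <- c("key_wavelength_set", "data.frame")
    return(out)
  }
  if (top_k > length(ext)) {
    warning(sprintf("only %d extrema available (top_k = %d)", length(ext), top_k),
            call. = FALSE)
    top_k <- length(ext)
  }
  ord <- ext[order(-abs(cf[ext]), fit$wavelengths[ext])][seq_len(top_k)]
  out <- data.frame(rank = seq_len(top_k),
                    wavelength = fit$wavelengths[ord],
                    coefficient = abs(cf[ord]),
                    sign = sign(cf[ord]))
  class(out) <- c("key_wavelength_set", "data.frame")
  out
}

# indices of strict interior local extrema; plateaus collapse to one extremum
# at their centre index
local_extrema <- function(v) {
  r <- rle(v)
  nrun <- length(r$lengths)
  if (nrun < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in 2:(nrun - 1L)) {
    left <- r$values[i - 1L]; mid <- r$values[i]; right <- r$values[i + 1L]
    if ((mid > left && mid > right) || (mid < left && mid < right))
      out <- c(out, as.integer(floor((starts[i] + ends[i]) / 2)))
  }
  out
}

#' Apply a trained PLSR model to spectra from another sensor
#'
#' Spectra must already be resampled onto the model's band grid (see
#' [resample_spectrum()]); any residual grid mismatch is an error. Uses the
#' consensus model (refit on all training samples) of a `plsr_cv_fit`, or a
#' bare `list(coefficients, intercept)`.
#'
#' @param model A `plsr_cv_fit` or a list with `coefficients` and
#'   `intercept`.
#' @param spectra List of `spectrum` objects on the model grid.
#' @param reference Optional reference N% vector; when supplied a
#'   `metrics_report` is attached.
#' @return Numeric vector of predicted N%, with attribute `"metrics"` when
#'   `reference` is given.
#' @export
apply_cross_sensor <- function(model, spectra, reference = NULL) {
  if (inherits(model, "plsr_cv_fit")) {
    coefs <- model$consensus$coefficients
    icpt <- model$consensus$intercept
    wl <- model$wavelengths
  } else {
    coefs <- model$coefficients; icpt <- model$intercept
    wl <- model$wavelengths %||% NULL
  }
  X <- t(vapply(spectra, function(s) {
    if (!is.null(wl) && !same_grid(s$wavelengths, wl))
      stop("spectrum ", s$sample_id,
           " is not on the model grid; resample first", call. = FALSE)
    s$values
  }, numeric(length(coefs))))
  pred <- as.numeric(X %*% coefs + icpt)
  names(pred) <- vapply(spectra, function(s) s$sample_id, character(1))
  if (!is.null(reference))
    attr(pred, "metrics") <- regression_metrics(reference, pred)
  pred
}
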