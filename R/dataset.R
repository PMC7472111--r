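#' Construct a sample ledger
#'
#' The ledger carries one row per leaf measurement: identity, variety,
#' nitrogen treatment, time-point, the dried leaf weight used by the
#' cleaning rules, the laboratory reference N% (percent of dry mass) that is
#' the regression response, and an exclusion flag.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param variety Wheat variety per sample.
#' @param n_treatment Nitrogen treatment in mg N per kg soil.
#' @param time_point Measurement time-point index (1-3).
#' @param dried_weight Dried leaf weight in mg.
#' @param n_percent Reference nitrogen, percent of dry mass. May be `NA` for
#'   samples flagged `too_small` or `acquisition_error`.
#' @param exclusion_flag One of `"none"`, `"too_small"`, `"n_outlier"`,
#'   `"acquisition_error"` per sample; defaults to `"none"`.
#' @return A `data.frame` with class `"sample_ledger"` prepended.
#' @export
sample_ledger <- function(sample_id, variety, n_treatment, time_point,
                          dried_weight, n_percent, exclusion_flag = "none") {
  df <- data.frame(
    sample_id = as.character(sample_id),
    variety = as.character(variety),
    n_treatment = as.numeric(n_treatment),
    time_point = as.integer(time_point),
    dried_weight = as.numeric(dried_weight),
    n_percent = as.numeric(n_percent),
    exclusion_flag = as.character(exclusion_flag),
    stringsAsFactors = FALSE)
  validate_ledger(df)
  class(df) <- c("sample_ledger", "data.frame")
  df
}

.EXCLUSION_LEVELS <- c("none", "too_small", "n_outlier", "acquisition_error")

validate_ledger <- function(df) {
  req <- c("sample_id", "variety", "n_treatment", "time_point",
           "dried_weight", "n_percent", "exclusion_flag")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("ledger is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ledger", call. = FALSE)
  bad_flag <- !df$exclusion_flag %in% .EXCLUSION_LEVELS
  if (any(bad_flag))
    stop("unknown exclusion_flag: ", df$exclusion_flag[bad_flag][1], call. = FALSE)
  # reference N% is only allowed to be missing when the leaf was too small to
  # assay (dried weight below the 100 mg laboratory minimum) or the
  # acquisition failed
  na_n <- is.na(df$n_percent)
  allowed <- df$exclusion_flag %in% c("too_small", "acquisition_error") |
    (!is.na(df$dried_weight) & df$dried_weight < 100)
  if (any(na_n & !allowed))
    stop("n_percent missing for sample(s) not flagged too_small/acquisition_error: ",
         paste(utils::head(df$sample_id[na_n & !allowed], 3), collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Assemble a dataset of spectra and ledger records
#'
#' Every spectrum must have a matching ledger record and all spectra must
#' share one wavelength grid (absolute tolerance 1e-6 nm); grid mismatches
#' fail loudly rather than being silently interpolated.
#'
#' @param spectra List of `spectrum` objects.
#' @param records A `sample_ledger`.
#' @param range_label One of `"FULL"`, `"VNIR"`, `"SWIR"`.
#' @return An object of class `"spec_dataset"`.
#' @export
spec_dataset <- function(spectra, records, range_label = c("FULL", "VNIR", "SWIR")) {
  range_label <- match.arg(range_label)
  stopifnot(is.list(spectra), length(spectra) > 0)
  lapply(spectra, function(s) stopifnot(inherits(s, "spectrum")))
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id among spectra", call. = FALSE)
  names(spectra) <- ids
  validate_ledger(records)
  missing_rec <- setdiff(ids, records$sample_id)
  if (length(missing_rec))
    stop("spectra without ledger record: ",
         paste(utils::head(missing_rec, 3), collapse = ", "), call. = FALSE)
  ref <- spectra[[1]]$wavelengths
  ok <- vapply(spectra, function(s) same_grid(s$wavelengths, ref), logical(1))
  if (!all(ok))
    stop("spectra are not on a shared wavelength grid (first offender: ",
         ids[!ok][1], "); resample explicitly instead", call. = FALSE)
  structure(list(spectra = spectra,
                 records = records[match(ids, records$sample_id), , drop = FALSE],
                 range_label = range_label),
            class = "spec_dataset")
}

#' @export
print.spec_dataset <- function(x, ...) {
  cat(sprintf("<spec_dataset> %s: %d samples, %d bands (%.0f-%.0f nm)\n",
              x$range_label, length(x$spectra),
              length(x$spectra[[1]]$wavelengths),
              min(x$spectra[[1]]$wavelengths),
              max(x$spectra[[1]]$wavelengths)))
  invisible(x)
}

#' Predictor matrix and response vector of a dataset
#'
#' @param data A `spec_dataset`.
#' @return List with `X` (samples x bands reflectance matrix, wavelengths as
#'   column names), `y` (reference N%), `wavelengths` and `sample_id`.
#' @export
as_xy <- function(data) {
  stopifnot(inherits(data, "spec_dataset"))
  wl <- data$spectra[[1]]$wavelengths
  X <- t(vapply(data$spectra, function(s) s$values, numeric(length(wl))))
  colnames(X) <- formatC(wl, format = "fg")
  rownames(X) <- names(data$spectra)
  list(X = X, y = data$records$n_percent, wavelengths = wl,
       sample_id = names(data$spectra))
}
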