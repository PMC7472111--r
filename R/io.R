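#' Read a wide spectra table with its sidecar
#'
#' The interchange format for point spectra is a wide delimited table — one
#' `wavelength` column plus one column per sample — accompanied by a YAML
#' sidecar (`<path>.yaml`) holding the per-band FWHM and the detector segment
#' boundaries needed for splice-jump correction.
#'
#' @param path Path to the CSV table; `<path>.yaml` must exist alongside.
#' @param sensor_id Sensor label attached to every spectrum; when `NULL` the
#'   sidecar's `sensor_id` is used.
#' @return List of `spectrum` objects sharing one wavelength grid.
#' @export
read_spectra_table <- function(path, sensor_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  side_path <- paste0(path, ".yaml")
  if (!file.exists(side_path))
    stop("missing sidecar: ", side_path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength" %in% names(df))
    stop("spectra table needs a 'wavelength' column", call. = FALSE)
  wl <- as.numeric(df$wavelength)
  if (anyNA(wl)) stop("non-numeric wavelength entries", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing (duplicates are a format error)",
         call. = FALSE)
  side <- yaml::read_yaml(side_path)
  fwhm <- as.numeric(unlist(side$fwhm))
  if (length(fwhm) == 1L) fwhm <- rep(fwhm, length(wl))
  if (length(fwhm) != length(wl))
    stop("sidecar fwhm length does not match the wavelength column", call. = FALSE)
  segs <- side$detector_segments
  segs <- if (is.null(segs)) NULL else lapply(segs, as.integer)
  if (is.null(sensor_id)) sensor_id <- side$sensor_id %||% "unknown"
  sample_cols <- setdiff(names(df), "wavelength")
  if (length(sample_cols) == 0L) stop("spectra table has no sample columns", call. = FALSE)
  lapply(sample_cols, function(id) {
    v <- as.numeric(df[[id]])
    if (anyNA(v)) stop("non-numeric reflectance in column ", id, call. = FALSE)
    spectrum(id, wl, v, fwhm, sensor_id = sensor_id, detector_segments = segs)
  })
}

#' Write spectra to a wide table with a YAML sidecar
#'
#' @param spectra List of `spectrum` objects on one shared grid.
#' @param path Destination CSV path; `<path>.yaml` is written alongside.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  ref <- spectra[[1]]
  ok <- vapply(spectra, function(s) same_grid(s$wavelengths, ref$wavelengths),
               logical(1))
  if (!all(ok)) stop("spectra must share one wavelength grid", call. = FALSE)
  df <- data.frame(wavelength = ref$wavelengths)
  for (s in spectra) df[[s$sample_id]] <- s$values
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(sensor_id = ref$sensor_id,
               fwhm = as.list(ref$fwhm),
               detector_segments = lapply(ref$detector_segments, as.integer))
  yaml::write_yaml(side, paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sample ledger from CSV
#'
#' @param path Path to a CSV with columns `sample_id`, `variety`,
#'   `n_treatment`, `time_point`, `dried_weight`, `n_percent` and optionally
#'   `exclusion_flag` (initialised to `"none"` when absent).
#' @return A `sample_ledger`.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  req <- c("sample_id", "variety", "n_treatment", "time_point",
           "dried_weight", "n_percent")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("ledger is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- function(col) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & !(is.na(raw) | raw == "" | toupper(raw) == "NA")
    if (any(bad))
      stop(sprintf("malformed numeric in column '%s' at row %d: '%s'",
                   col, which(bad)[1], raw[which(bad)[1]]), call. = FALSE)
    v
  }
  flag <- if ("exclusion_flag" %in% names(df)) df$exclusion_flag else "none"
  sample_ledger(df$sample_id, df$variety, num("n_treatment"),
                num("time_point"), num("dried_weight"), num("n_percent"),
                exclusion_flag = flag)
}

#' Write a sample ledger to CSV
#'
#' @param ledger A `sample_ledger`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  validate_ledger(ledger)
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE)
  invisible(path)
}

#' Read or write a band specification as CSV
#'
#' The on-disk form is a two-column CSV (`centre`, `fwhm`).
#'
#' @param path CSV path.
#' @param label Label attached on read.
#' @return `read_band_spec`: a `band_spec`; `write_band_spec`: `path`.
#' @export
read_band_spec <- function(path, label = "") {
  df <- utils::read.csv(path)
  if (!all(c("centre", "fwhm") %in% names(df)))
    stop("band spec CSV needs 'centre' and 'fwhm' columns", call. = FALSE)
  band_spec(df$centre, df$fwhm, label = label)
}

#' @param bs A `band_spec` (for `write_band_spec`).
#' @rdname read_band_spec
#' @export
write_band_spec <- function(bs, path) {
  stopifnot(inherits(bs, "band_spec"))
  utils::write.csv(data.frame(centre = bs$centres, fwhm = bs$fwhm),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- ENVI raster IO ---------------------------------------------------------

.ENVI_DTYPE <- c("4" = 4L, "5" = 8L)  # data type code -> bytes (float32/float64)

#' Read an ENVI raster as a hyperspectral cube
#'
#' Supports band-interleaved-by-line (`bil`), by-pixel (`bip`) and
#' band-sequential (`bsq`) layouts with IEEE float data (ENVI data types 4
#' and 5). The wavelength list must be present in the header; cubes are
#' returned uncalibrated.
#'
#' @param path Path to the binary raster; the header is `<path>.hdr` (or the
#'   same basename with extension replaced by `.hdr`).
#' @param sensor_id Sensor label for the cube.
#' @return A `spectral_cube` with `calibrated = FALSE`.
#' @export
read_envi_cube <- function(path, sensor_id = "unknown") {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- paste0(tools::file_path_sans_ext(path), ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header for ", path, call. = FALSE)
  h <- parse_envi_header(hdr_path)
  for (k in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(h[[k]])) stop("ENVI header missing field '", k, "'", call. = FALSE)
  if (is.null(h$wavelength))
    stop("ENVI header has no wavelength metadata", call. = FALSE)
  samples <- as.integer(h$samples); lines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  wl <- as.numeric(h$wavelength)
  if (length(wl) != bands)
    stop("header band count does not match wavelength list", call. = FALSE)
  dtype <- as.character(as.integer(h[["data type"]]))
  if (!dtype %in% names(.ENVI_DTYPE))
    stop("unsupported ENVI data type ", dtype, " (float32/float64 only)", call. = FALSE)
  bytes <- .ENVI_DTYPE[[dtype]]
  endian <- if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) == 1)
    "big" else "little"
  n <- samples * lines * bands
  expected <- n * bytes
  if (file.size(path) != expected)
    stop(sprintf("ENVI data size mismatch: header implies %d bytes, file has %d",
                 expected, file.size(path)), call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, "double", n = n, size = bytes, endian = endian)
  interleave <- tolower(h$interleave)
  # file order (fastest first): bsq = sample,line,band; bil = sample,band,line;
  # bip = band,sample,line. In-memory convention is (row=line, col=sample, band).
  data <- switch(interleave,
    bsq = aperm(array(v, dim = c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(bands, samples, lines)), c(3, 2, 1)),
    stop("unsupported interleave '", interleave, "'", call. = FALSE))
  fwhm <- if (!is.null(h$fwhm)) as.numeric(h$fwhm) else rep(1, bands)
  spectral_cube(data, wl, fwhm, calibrated = FALSE, sensor_id = sensor_id)
}

#' Write a hyperspectral cube as an ENVI raster
#'
#' @param cube A `spectral_cube`.
#' @param path Destination path for the binary raster; `<path>.hdr` is
#'   written alongside.
#' @param interleave One of `"bil"`, `"bip"`, `"bsq"`.
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path, interleave = c("bil", "bip", "bsq")) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  con <- file(path, "wb")
  writeBin(v, con, size = 8, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = { ",
           paste(formatC(cube$wavelengths, format = "fg", digits = 15),
                 collapse = ", "), " }"),
    paste0("fwhm = { ",
           paste(formatC(cube$fwhm, format = "fg", digits = 15),
                 collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ENVI")
    stop("not an ENVI header: ", path, call. = FALSE)
  body <- paste(lines[-1], collapse = "\n")
  out <- list()
  # join multi-line { ... } blocks, then split on newlines outside braces
  chars <- strsplit(body, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "{") depth <- depth + 1L
    else if (chars[i] == "}") depth <- depth - 1L
    else if (chars[i] == "\n" && depth > 0L) chars[i] <- " "
  }
  entries <- strsplit(paste(chars, collapse = ""), "\n")[[1]]
  for (e in entries) {
    if (!grepl("=", e, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", e)))
    val <- trimws(sub("^[^=]*=", "", e))
    if (grepl("^\\{", val)) {
      val <- gsub("^\\{|\\}$", "", val)
      val <- trimws(strsplit(val, ",")[[1]])
    }
    out[[key]] <- val
  }
  out
}
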