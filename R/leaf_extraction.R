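#' Spectral angle between two signatures
#'
#' The spectral angle mapper (SAM) dissimilarity: the arccosine of the cosine
#' similarity, in radians within `[0, pi]`. Invariant to positive scaling of
#' either argument, which makes it insensitive to illumination intensity.
#'
#' @param a,b Numeric reflectance vectors of equal length, neither all-zero.
#' @return Angle in radians.
#' @export
spectral_angle <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("spectral angle of a zero vector is undefined", call. = FALSE)
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

#' Detect blue-marker pixels by spectral angle
#'
#' Classifies a pixel as marker when its spectral angle to the target
#' signature is strictly below `threshold`.
#'
#' @param cube A calibrated `spectral_cube`.
#' @param target Reference marker signature (length = band count), typically
#'   the average of annotated marker pixels.
#' @param threshold SAM threshold in radians (default 0.2).
#' @return A `pixel_mask` labelled `"marker"`.
#' @export
detect_marker <- function(cube, target, threshold = 0.2) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!cube$calibrated) stop("cube must be calibrated first", call. = FALSE)
  d <- dim(cube$data)
  if (length(target) != d[3])
    stop("target length does not match band count", call. = FALSE)
  px <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  tn <- sqrt(sum(target^2))
  if (tn == 0) stop("target signature is a zero vector", call. = FALSE)
  norms <- sqrt(rowSums(px^2))
  cosang <- (px %*% target) / (norms * tn)
  cosang[norms == 0] <- -1      # zero pixels can never be marker
  ang <- acos(pmax(-1, pmin(1, cosang)))
  pixel_mask(matrix(ang < threshold, d[1], d[2]), label = "marker")
}

#' Leaf-bed region of interest
#'
#' @param centre `(row, col)` centre of the ROI.
#' @param orientation Angle of the ROI's long axis in radians, measured from
#'   the image x-axis (columns increasing), with rows increasing downward.
#' @param extent `(height, width)` of the ROI in pixels, across and along the
#'   axis respectively.
#' @return An object of class `"leaf_bed_roi"`.
#' @export
leaf_bed_roi <- function(centre, orientation, extent) {
  if (any(extent <= 0)) stop("ROI extent must be positive", call. = FALSE)
  structure(list(centre = as.numeric(centre),
                 orientation = as.numeric(orientation)[1],
                 extent = as.numeric(extent)),
            class = "leaf_bed_roi")
}

#' Locate the leaf-bed ROI from the marker mask
#'
#' The ROI centre is displaced from the marker centroid by configured offsets
#' along and across the marker's principal axis; the orientation is the
#' principal axis of the marker pixel coordinates (eigenvector of their
#' covariance), reported modulo pi.
#'
#' @param marker A non-empty `pixel_mask`.
#' @param geometry List with `offset = c(along, across)` in pixels and
#'   `extent = c(height, width)`; defaults place the bed on the marker with a
#'   40 x 80 pixel extent, matching the synthetic fixture layout.
#' @return A `leaf_bed_roi`.
#' @export
locate_roi <- function(marker, geometry = list(offset = c(0, 0),
                                               extent = c(40, 80))) {
  stopifnot(inherits(marker, "pixel_mask"))
  idx <- which(marker$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("marker detection failed: empty mask", call. = FALSE)
  if (nrow(idx) < 3L)
    stop("marker too small to orient (", nrow(idx), " pixel(s))", call. = FALSE)
  xy <- cbind(x = idx[, 2], y = idx[, 1])  # x = col, y = row
  centroid <- colMeans(xy)
  cv <- stats::cov(xy)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] < 1e-12)
    stop("degenerate marker geometry: no principal axis", call. = FALSE)
  v <- eg$vectors[, 1]
  theta <- atan2(v[2], v[1]) %% pi
  axis_unit <- c(cos(theta), sin(theta))
  normal_unit <- c(-sin(theta), cos(theta))
  off <- geometry$offset %||% c(0, 0)
  centre_xy <- centroid + off[1] * axis_unit + off[2] * normal_unit
  leaf_bed_roi(centre = c(centre_xy[2], centre_xy[1]), orientation = theta,
               extent = geometry$extent %||% c(40, 80))
}

#' Rasterise a leaf-bed ROI to a pixel mask
#'
#' @param roi A `leaf_bed_roi`.
#' @param dims `(rows, cols)` of the target image; the ROI is clipped to
#'   these bounds.
#' @return A logical `(rows, cols)` matrix.
#' @export
roi_mask <- function(roi, dims) {
  stopifnot(inherits(roi, "leaf_bed_roi"))
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  dx <- cols - roi$centre[2]
  dy <- rows - roi$centre[1]
  along <- dx * cos(roi$orientation) + dy * sin(roi$orientation)
  across <- -dx * sin(roi$orientation) + dy * cos(roi$orientation)
  abs(along) <= roi$extent[2] / 2 & abs(across) <= roi$extent[1] / 2
}

#' Hyper-hue transform of a spectral signature
#'
#' The brightness-independent direction of a signature: the achromatic
#' (equal-value) component is removed and the remainder normalised to unit
#' length. Invariant to adding a constant to all bands and to positive
#' scaling; a constant (achromatic) signature has no hue and raises an error
#' (callers map such pixels to background).
#'
#' @param pixel Numeric reflectance vector, not constant.
#' @return Unit vector of the same length, orthogonal to the all-ones
#'   direction.
#' @export
hyper_hue <- function(pixel) {
  centred <- pixel - mean(pixel)
  nrm <- sqrt(sum(centred^2))
  if (nrm < 1e-12)
    stop("achromatic pixel: hyper-hue undefined for constant signatures",
         call. = FALSE)
  centred / nrm
}

# hyper-hue of every row of a pixel matrix; constant rows -> NA rows
hyper_hue_rows <- function(px) {
  centred <- px - rowMeans(px)
  nrm <- sqrt(rowSums(centred^2))
  h <- centred / nrm
  h[nrm < 1e-12, ] <- NA_real_
  h
}

#' Segment leaf pixels inside an ROI with hyper-hue and a one-class SVM
#'
#' Pixels inside the ROI are transformed to hyper-hue and scored by a
#' one-class support vector machine (radial-basis kernel) trained on
#' hyper-hue vectors from known leaf regions. The kernel bandwidth defaults
#' to the median heuristic on the training pixels. `nu` upper-bounds the
#' fraction of training pixels treated as outliers. Achromatic pixels are
#' mapped to background. An optional morphological cleanup (majority vote in
#' a 3x3 neighbourhood, applied inside the ROI) removes salt-and-pepper
#' misclassifications at the single-pixel scale.
#'
#' @param cube A calibrated `spectral_cube`.
#' @param roi A `leaf_bed_roi` bounding the search.
#' @param training_pixels Matrix of leaf hyper-hue vectors (rows = pixels).
#' @param nu One-class SVM `nu` in (0, 1); default 0.1.
#' @param min_training Minimum number of training pixels (default 20).
#' @param clean Apply the 3x3 majority cleanup (default `TRUE`).
#' @return A `pixel_mask` labelled `"leaf"`.
#' @export
segment_leaf <- function(cube, roi, training_pixels, nu = 0.1,
                         min_training = 20L, clean = TRUE) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(roi, "leaf_bed_roi"))
  if (!cube$calibrated) stop("cube must be calibrated first", call. = FALSE)
  training_pixels <- as.matrix(training_pixels)
  if (nrow(training_pixels) < min_training)
    stop(sprintf("need at least %d training pixels, got %d",
                 min_training, nrow(training_pixels)), call. = FALSE)
  if (!(nu > 0 && nu < 1)) stop("nu must be in (0, 1)", call. = FALSE)
  d <- dim(cube$data)
  inside <- roi_mask(roi, d[1:2])
  px <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  sel <- which(inside)
  hues <- hyper_hue_rows(px[sel, , drop = FALSE])
  chromatic <- !is.na(hues[, 1])
  # median-heuristic bandwidth on a bounded subsample of the training pixels
  tr <- training_pixels
  if (nrow(tr) > 500L) tr <- tr[seq(1L, nrow(tr), length.out = 500L), , drop = FALSE]
  med <- stats::median(stats::dist(tr))
  gamma <- if (med > 0) 1 / (2 * med^2) else 1 / ncol(training_pixels)
  fit <- e1071::svm(x = training_pixels, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma, scale = FALSE)
  pred <- rep(FALSE, length(sel))
  if (any(chromatic))
    pred[chromatic] <- as.logical(stats::predict(fit, hues[chromatic, , drop = FALSE]))
  mask <- matrix(FALSE, d[1], d[2])
  mask[sel] <- pred
  if (clean) mask <- majority_clean(mask, inside)
  pixel_mask(mask, label = "leaf")
}

# 3x3 majority filter restricted to `inside`; flips isolated mislabels while
# leaving region boundaries intact
majority_clean <- function(mask, inside) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  counts <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    counts <- counts + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
  out <- counts >= 5L   # majority of the 3x3 neighbourhood (incl. centre)
  out & inside
}

#' Mean spectral signature over a pixel mask
#'
#' @param cube A calibrated `spectral_cube`.
#' @param mask A non-empty `pixel_mask`.
#' @param sample_id Identifier for the resulting `spectrum`.
#' @return A `spectrum` of the per-band arithmetic mean over masked pixels.
#'   An empty mask raises a condition of class
#'   `"nitrospec_acquisition_error"`, which pipeline callers translate into
#'   an `acquisition_error` exclusion flag.
#' @export
mean_signature <- function(cube, mask, sample_id) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(mask, "pixel_mask"))
  d <- dim(cube$data)
  if (!identical(dim(mask$mask), d[1:2]))
    stop("mask shape does not match cube", call. = FALSE)
  sel <- which(mask$mask)
  if (length(sel) == 0L)
    stop(structure(class = c("nitrospec_acquisition_error", "error", "condition"),
                   list(message = paste0("empty mask for sample ", sample_id),
                        call = NULL)))
  px <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  spectrum(sample_id, cube$wavelengths, colMeans(px[sel, , drop = FALSE]),
           cube$fwhm, sensor_id = cube$sensor_id)
}

#' Merge VNIR and SWIR signatures into one full-range spectrum
#'
#' Concatenates the two signatures on one grid with two detector segments and
#' removes the inter-sensor jump with [remove_jumps()]. When the grids share
#' the boundary wavelength (or overlap), the duplicated/overlapping SWIR
#' bands are dropped and the VNIR values kept. Per-segment FWHM metadata is
#' preserved.
#'
#' @param vnir,swir `spectrum` objects with `max(vnir) <= min(swir)` after
#'   overlap handling; interleaved grids are an error.
#' @param params `jump_params` for the junction correction.
#' @return A merged, jump-corrected `spectrum`.
#' @export
merge_vnir_swir <- function(vnir, swir, params = jump_params()) {
  stopifnot(inherits(vnir, "spectrum"), inherits(swir, "spectrum"))
  vmax <- max(vnir$wavelengths)
  if (min(swir$wavelengths) < vmax - .WL_TOL)
    stop("interleaved VNIR/SWIR grids cannot be merged", call. = FALSE)
  keep <- swir$wavelengths > vmax + .WL_TOL
  if (!any(keep))
    stop("SWIR grid lies entirely within the VNIR range", call. = FALSE)
  nv <- length(vnir$wavelengths); ns <- sum(keep)
  merged <- spectrum(
    vnir$sample_id,
    c(vnir$wavelengths, swir$wavelengths[keep]),
    c(vnir$values, swir$values[keep]),
    c(vnir$fwhm, swir$fwhm[keep]),
    sensor_id = paste(vnir$sensor_id, swir$sensor_id, sep = "+"),
    detector_segments = list(c(1L, nv), c(nv + 1L, nv + ns)))
  remove_jumps(merged, params)
}
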