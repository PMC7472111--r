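test_that("spectral angle is a scale-invariant dissimilarity", {
  a <- c(0.2, 0.4, 0.6)
  expect_identical(spectral_angle(a, a), 0)
  expect_equal(spectral_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(spectral_angle(a, 2 * a), 0)
  expect_error(spectral_angle(a, c(0, 0, 0)), "zero vector")
  expect_error(spectral_angle(a, c(1, 2)), "equal length")
})

test_that("marker detection recovers the planted region and nothing else", {
  scene <- leaf_bed_scene(seed = 3L)
  truth <- scene$cube$truth
  mk <- detect_marker(scene$cal, truth$marker_signature, threshold = 0.2)
  planted <- truth$marker_mask
  recall <- sum(mk$mask & planted) / sum(planted)
  expect_gte(recall, 0.99)
  expect_identical(sum(mk$mask & !planted), 0L)    # zero background pixels
  # threshold 0 gives an empty mask (strict inequality)
  empty <- detect_marker(scene$cal, truth$marker_signature, threshold = 0)
  expect_identical(sum(empty$mask), 0L)
  expect_error(detect_marker(scene$cal, truth$marker_signature[-1], 0.2),
               "band count")
})

test_that("marker detection is insensitive to illumination scale", {
  scene <- leaf_bed_scene(seed = 13L)
  truth <- scene$cube$truth
  dimmed <- scene$cal
  dimmed$data <- dimmed$data * 0.55
  mk <- detect_marker(dimmed, truth$marker_signature, threshold = 0.2)
  recall <- sum(mk$mask & truth$marker_mask) / sum(truth$marker_mask)
  expect_gte(recall, 0.99)
  expect_identical(sum(mk$mask & !truth$marker_mask), 0L)
})

test_that("ROI orientation follows the marker's principal axis", {
  m <- matrix(FALSE, 40, 40)
  m[18:22, 8:32] <- TRUE                            # axis-aligned rectangle
  roi <- locate_roi(pixel_mask(m, "marker"))
  expect_lt(min(roi$orientation %% pi, pi - roi$orientation %% pi), 1e-8)
  expect_equal(roi$centre, c(20, 20))

  # the same bar rotated by 30 degrees
  ang <- 30 * pi / 180
  m2 <- matrix(FALSE, 60, 60)
  for (t in seq(-15, 15, by = 0.25)) {
    r <- round(30 + t * sin(ang)); c <- round(30 + t * cos(ang))
    m2[pmax(1, r + (-1:1)), c] <- TRUE
  }
  roi2 <- locate_roi(pixel_mask(m2, "marker"))
  expect_lt(abs(roi2$orientation - ang) * 180 / pi, 1)

  single <- matrix(FALSE, 10, 10); single[5, 5] <- TRUE
  expect_error(locate_roi(pixel_mask(single, "marker")), "too small")
  expect_error(locate_roi(pixel_mask(matrix(FALSE, 5, 5), "marker")), "empty")
})

test_that("hyper-hue removes brightness and intensity scaling", {
  v <- c(0.2, 0.5, 0.3, 0.8)
  h <- hyper_hue(v)
  expect_equal(sum(h^2), 1)
  expect_equal(sum(h), 0, tolerance = 1e-12)        # orthogonal to ones
  expect_equal(hyper_hue(v + 0.17), h)
  expect_equal(hyper_hue(3.2 * v), h)
  expect_error(hyper_hue(c(0.3, 0.3, 0.3)), "achromatic")
})

test_that("one-class SVM segmentation recovers the planted leaf", {
  scene <- leaf_bed_scene(seed = 3L)
  truth <- scene$cube$truth
  roi <- locate_roi(detect_marker(scene$cal, truth$marker_signature),
                    geometry = scene$geometry)
  seg <- segment_leaf(scene$cal, roi, scene$hues, nu = 0.1)
  inter <- sum(seg$mask & truth$leaf_mask)
  union <- sum(seg$mask | truth$leaf_mask)
  expect_gte(inter / union, 0.95)
  # raw SVM decisions keep at least ~1 - nu of the leaf distribution (nu
  # bounds training margin errors; held-out pixels add sampling slack)
  raw <- segment_leaf(scene$cal, roi, scene$hues, nu = 0.1, clean = FALSE)
  in_roi_leaf <- truth$leaf_mask & roi_mask(roi, dim(scene$cal)[1:2])
  kept <- sum(raw$mask & in_roi_leaf) / sum(in_roi_leaf)
  expect_gte(kept, 1 - 0.1 - 0.08)
  expect_error(segment_leaf(scene$cal, roi, scene$hues[1:5, ], nu = 0.1),
               "training pixels")
})

test_that("an all-background ROI yields a near-empty leaf mask", {
  scene <- leaf_bed_scene(seed = 7L)
  bg_roi <- leaf_bed_roi(centre = c(5, 52), orientation = 0, extent = c(8, 14))
  seg <- segment_leaf(scene$cal, bg_roi, scene$hues, nu = 0.1)
  expect_lt(sum(seg$mask) / sum(roi_mask(bg_roi, dim(scene$cal)[1:2])), 0.01)
})

test_that("mean signatures average masked pixels and flag empty masks", {
  arr <- array(0.2, c(2, 2, 3))
  arr[2, 2, ] <- 0.4
  cube <- spectral_cube(arr, c(500, 510, 520), 10, calibrated = TRUE)
  all_mask <- pixel_mask(matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
  expect_equal(mean_signature(cube, all_mask, "x")$values, rep(0.4, 3))
  two <- pixel_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_equal(mean_signature(cube, two, "x")$values, rep(0.3, 3))
  # convexity: the mean lies between the per-band min and max
  scene <- leaf_bed_scene(seed = 5L)
  ms <- mean_signature(scene$cal, pixel_mask(scene$cube$truth$leaf_mask), "s")
  d <- dim(scene$cal$data)
  px <- matrix(scene$cal$data, d[1] * d[2], d[3])[which(scene$cube$truth$leaf_mask), ]
  expect_true(all(ms$values >= apply(px, 2, min) - 1e-12))
  expect_true(all(ms$values <= apply(px, 2, max) + 1e-12))
  expect_error(mean_signature(cube, pixel_mask(matrix(FALSE, 2, 2)), "x"),
               class = "nitrospec_acquisition_error")
})

test_that("recovered per-leaf mean spectra sit within sampling error of truth", {
  scene <- leaf_bed_scene(seed = 3L)
  truth <- scene$cube$truth
  roi <- locate_roi(detect_marker(scene$cal, truth$marker_signature),
                    geometry = scene$geometry)
  seg <- segment_leaf(scene$cal, roi, scene$hues, nu = 0.1)
  keep <- pixel_mask(seg$mask & truth$leaf_mask)
  ms <- mean_signature(scene$cal, keep, "s")
  bound <- 3 * truth$noise_sigma / sqrt(sum(keep$mask))
  expect_lt(max(abs(ms$values - truth$leaf_spectrum)), bound)
})

test_that("VNIR and SWIR signatures merge continuously", {
  vn_wl <- seq(400, 1000, 5)
  sw_wl <- seq(1000, 2400, 12)
  line <- function(wl) 0.1 + 2e-4 * wl
  vnir <- spectrum("s", vn_wl, line(vn_wl), 5.5, sensor_id = "FX10")
  swir <- spectrum("s", sw_wl, line(sw_wl) + 0.05, 12, sensor_id = "SWIR")
  merged <- merge_vnir_swir(vnir, swir)
  # offset removed: the merged curve is back on the line
  expect_lt(max(abs(merged$values - line(merged$wavelengths))), 1e-9)
  # duplicate boundary band dropped from the SWIR side
  expect_identical(sum(merged$wavelengths == 1000), 1L)
  expect_length(merged$detector_segments, 2L)
  # per-segment FWHM metadata preserved
  seg2 <- merged$detector_segments[[2]]
  expect_true(all(merged$fwhm[seg2[1]:seg2[2]] == 12))
  expect_true(all(merged$fwhm[1:length(vn_wl)] == 5.5))

  # zero-offset inputs concatenate unchanged
  swir0 <- spectrum("s", sw_wl[-1], line(sw_wl[-1]), 12)
  merged0 <- merge_vnir_swir(vnir, swir0)
  expect_equal(merged0$values, line(merged0$wavelengths), tolerance = 1e-12)

  inter <- spectrum("s", seq(900, 2400, 12), line(seq(900, 2400, 12)), 12)
  expect_error(merge_vnir_swir(vnir, inter), "interleaved")
})
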