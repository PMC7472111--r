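random_cube_triplet <- function(seed, dims = c(5, 6, 4)) {
  with_seed_test(seed, {
    wl <- seq(500, by = 10, length.out = dims[3])
    dark <- array(stats::runif(prod(dims), 90, 110), dims)
    white <- dark + array(stats::runif(prod(dims), 2000, 4000), dims)
    list(dark = spectral_cube(dark, wl, 10),
         white = spectral_cube(white, wl, 10), wl = wl, dims = dims)
  })
}

test_that("reflectance calibration satisfies the white/dark/midpoint identities", {
  for (seed in c(1, 2, 3)) {
    tri <- random_cube_triplet(seed)
    as_cube <- function(a) spectral_cube(a, tri$wl, 10)
    white_r <- calibrate_cube(as_cube(tri$white$data), tri$dark, tri$white)
    expect_equal(max(abs(white_r$data - 1)), 0, tolerance = 1e-12)
    dark_r <- calibrate_cube(as_cube(tri$dark$data), tri$dark, tri$white)
    expect_equal(max(abs(dark_r$data)), 0, tolerance = 1e-12)
    mid <- as_cube((tri$white$data + tri$dark$data) / 2)
    mid_r <- calibrate_cube(mid, tri$dark, tri$white)
    expect_equal(max(abs(mid_r$data - 0.5)), 0, tolerance = 1e-12)
    expect_true(white_r$calibrated)
  }
})

test_that("calibration guards zero-denominator elements and shape mismatches", {
  tri <- random_cube_triplet(4)
  white <- tri$white
  white$data[2, 3, ] <- tri$dark$data[2, 3, ]   # dead reference pixel
  out <- calibrate_cube(tri$white, tri$dark, white)
  inv <- attr(out, "invalid_mask")
  expect_true(inv[2, 3])
  expect_equal(sum(inv), 1L)
  expect_true(all(is.na(out$data[2, 3, ])))
  small <- spectral_cube(tri$dark$data[1:3, , , drop = FALSE], tri$wl, 10)
  expect_error(calibrate_cube(small, tri$dark, tri$white), "identical shapes")
})

test_that("planted splice offsets are removed to numerical precision", {
  wl <- seq(401, 430)
  truth <- 0.2 + 1e-3 * (wl - 400)     # exactly linear left segment
  v <- truth
  v[16:30] <- v[16:30] + 0.05
  s <- spectrum("j", wl, v, 1, detector_segments = list(c(1L, 15L), c(16L, 30L)))
  out <- remove_jumps(s, jump_params(m = 6))
  expect_lt(max(abs(out$values - truth)), 1e-10)
  # post-correction discontinuity at the junction is zero
  expect_lt(abs(diff(out$values)[15] - 1e-3), 1e-10)
})

test_that("a right segment already on the extrapolated line is untouched", {
  wl <- seq(401, 430)
  v <- 0.2 + 1e-3 * (wl - 400)
  s <- spectrum("j", wl, v, 1, detector_segments = list(c(1L, 15L), c(16L, 30L)))
  expect_equal(remove_jumps(s)$values, v)
})

test_that("cascaded junctions, idempotence and shape preservation hold", {
  wl <- seq(401, 445)
  truth <- 0.1 + 2e-3 * (wl - 400)
  v <- truth
  v[16:45] <- v[16:45] + 0.05          # first junction
  v[31:45] <- v[31:45] - 0.02          # second junction (cumulative -0.02)
  segs <- list(c(1L, 15L), c(16L, 30L), c(31L, 45L))
  s <- spectrum("j", wl, v, 1, detector_segments = segs)
  once <- remove_jumps(s)
  expect_lt(max(abs(once$values - truth)), 1e-10)
  twice <- remove_jumps(once)
  expect_identical(twice$values, once$values)   # idempotent
  # within-segment first differences preserved exactly
  for (seg in segs) {
    i <- seg[1]:seg[2]
    expect_equal(diff(once$values[i]), diff(v[i]))
  }
  short <- spectrum("k", wl[1:10], v[1:10], 1,
                    detector_segments = list(c(1L, 4L), c(5L, 10L)))
  expect_error(remove_jumps(short, jump_params(m = 6)), "segment 1")
})

test_that("Savitzky-Golay smoothing reproduces low-degree polynomials", {
  wl <- 1:61
  quad <- 2 + 0.3 * wl - 0.01 * wl^2
  s <- spectrum("p", wl + 400, quad, 1)
  sm <- smooth_spectrum(s, window = 11, polyorder = 2)
  interior <- 6:56
  expect_equal(sm$values[interior], quad[interior], tolerance = 1e-10)
  const <- smooth_spectrum(spectrum("c", wl + 400, rep(0.4, 61), 1), 11, 2)
  expect_equal(const$values, rep(0.4, 61), tolerance = 1e-12)
})

test_that("smoothing matches a direct local-polynomial oracle and cuts noise", {
  wl <- 1:81
  noisy <- with_seed_test(9, stats::rnorm(81, 0.3, 0.05))
  s <- spectrum("n", wl + 400, noisy, 1)
  sm <- smooth_spectrum(s, window = 9, polyorder = 2)
  # oracle: at each interior point, fit the window polynomial by least
  # squares and evaluate at the centre
  oracle <- vapply(5:77, function(i) {
    idx <- (i - 4):(i + 4)
    fit <- stats::lm(y ~ x + I(x^2), data.frame(x = idx - i, y = noisy[idx]))
    unname(fit$fitted.values[5])
  }, numeric(1))
  expect_equal(sm$values[5:77], oracle, tolerance = 1e-8)
  expect_lt(stats::var(sm$values[5:77]), stats::var(noisy[5:77]))
  expect_error(smooth_spectrum(s, window = 81, polyorder = 2), "shorter")
  expect_error(smooth_spectrum(s, window = 10, polyorder = 2), "odd")
})

test_that("trimming keeps the stated bounds and re-indexes segments", {
  wl <- seq(350, 2500, 10)
  s <- spectrum("t", wl, seq_along(wl) / 1000, 3,
                detector_segments = list(c(1L, 66L), c(67L, 146L), c(147L, 216L)))
  tr <- trim_spectrum(s, 400, 2400)
  expect_gte(min(tr$wavelengths), 400)
  expect_lte(max(tr$wavelengths), 2400)
  n <- length(tr$wavelengths)
  expect_identical(tr$detector_segments[[1]][1], 1L)
  expect_identical(tr$detector_segments[[length(tr$detector_segments)]][2], n)
  expect_identical(trim_spectrum(s, 350, 2500)$values, s$values)   # identity
  expect_error(trim_spectrum(s, 3000, 3100), "no bands")
  expect_error(trim_spectrum(s, 500, 400), "smaller")
})

test_that("calibrating the white frame against itself yields 1 everywhere", {
  tri <- random_cube_triplet(6)
  out <- calibrate_cube(tri$white, tri$dark, tri$white)
  expect_equal(range(out$data), c(1, 1), tolerance = 1e-12)
})
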