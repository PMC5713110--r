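make_cube <- function(vals, nl = 2, ns = 2, nb = 3, wl = NULL) {
  if (is.null(wl)) wl <- seq(500, 600, length.out = nb)
  hypercube(array(vals, c(nl, ns, nb)), wl)
}

test_that("calibration maps raw counts to reflectance", {
  wl <- c(500, 550, 600)
  white <- matrix(0.9, 2, 3)
  dark <- matrix(0.1, 2, 3)

  expect_equal(unique(as.vector(
    calibrate_cube(make_cube(0.9), white, dark)$data)), 1.0)
  expect_equal(unique(as.vector(
    calibrate_cube(make_cube(0.1), white, dark)$data)), 0.0)
  expect_equal(unique(as.vector(
    calibrate_cube(make_cube(0.5), white, dark)$data)), 0.5)
  expect_true(calibrate_cube(make_cube(0.5), white, dark)$calibrated)
})

test_that("calibration is invariant to detector gain and clips extremes", {
  set.seed(1)
  raw <- array(runif(2 * 2 * 3, 0.2, 0.8), c(2, 2, 3))
  white <- matrix(runif(6, 0.9, 1.0), 2, 3)
  dark <- matrix(runif(6, 0.0, 0.1), 2, 3)
  a <- calibrate_cube(make_cube(raw), white, dark)
  b <- calibrate_cube(make_cube(raw * 7.3), white * 7.3, dark * 7.3)
  expect_equal(a$data, b$data, tolerance = 1e-12)

  # dead cells (white == dark) become 0 with a warning, never NaN
  white2 <- white; white2[1, 1] <- dark[1, 1]
  expect_warning(cal <- calibrate_cube(make_cube(raw), white2, dark), "dead")
  expect_true(all(is.finite(cal$data)))
  expect_true(all(cal$data[, 1, 1] == 0))

  # specular pixels clip at the configured ceiling
  hot <- raw; hot[1, 1, ] <- 10
  expect_equal(calibrate_cube(make_cube(hot), white, dark)$data[1, 1, ],
               rep(1.5, 3))
  expect_error(calibrate_cube(make_cube(raw), white[, 1:2], dark), "samples x bands")
})

test_that("band trimming drops head/tail bands and composes additively", {
  cube <- make_cube(seq_len(2 * 2 * 10) / 40, nb = 10,
                    wl = seq(400, 850, length.out = 10))
  t1 <- trim_bands(cube, 2, 3)
  expect_equal(dim(t1)[3], 5)
  expect_equal(t1$wavelengths, cube$wavelengths[3:7])
  expect_identical(trim_bands(cube, 0, 0)$data, cube$data)
  expect_equal(trim_bands(trim_bands(cube, 1, 2), 2, 1)$data,
               trim_bands(cube, 3, 3)$data)
  expect_error(trim_bands(cube, 6, 4), "cannot trim")

  sm <- spectra_matrix(matrix(1:20, 2, 10), cube$wavelengths)
  expect_equal(dim(trim_bands(sm, 2, 3))[2], 5)
  expect_equal(trim_bands(sm, 2, 3)$wavelengths, cube$wavelengths[3:7])
})

test_that("512-band axis trims to the 408-band working range", {
  sm <- spectra_matrix(matrix(0, 2, 512), seq(380, 1030, length.out = 512))
  tr <- trim_bands(sm, 82, 22)
  expect_equal(ncol(tr$values), 408)
  expect_gt(min(tr$wavelengths), 480)
  expect_lt(max(tr$wavelengths), 1005)
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  x <- seq_len(41)
  const <- matrix(2.5, 1, 41)
  expect_equal(sg_smooth(const, 9, 3), const)

  ramp <- matrix(0.3 * x - 2, 1, 41)
  expect_equal(sg_smooth(ramp, 11, 1), ramp, tolerance = 1e-10)

  quad <- matrix(0.02 * x^2 - 0.3 * x + 1, 1, 41)
  expect_equal(sg_smooth(quad, 9, 2), quad, tolerance = 1e-10)

  # mean preservation and noise-variance reduction on white noise
  set.seed(4)
  noisy <- matrix(rnorm(500), 1, 500)
  sm <- sg_smooth(noisy, 9, 3)
  expect_lt(var(as.vector(sm)), var(as.vector(noisy)))

  expect_error(sg_smooth(const, 8, 3), "odd")
  expect_error(sg_smooth(const, 9, 9), "polyorder")
})

test_that("quadratic smoothing matches a direct per-window polynomial fit", {
  set.seed(9)
  y <- as.numeric(stats::filter(rnorm(60), rep(1 / 5, 5), circular = TRUE))
  w <- 7L; half <- 3L
  sm <- sg_smooth(matrix(y, 1), w, 2L)
  direct <- vapply((half + 1):(60 - half), function(i) {
    idx <- (i - half):(i + half)
    fit <- lm(y[idx] ~ poly(idx, 2, raw = TRUE))
    unname(predict(fit, data.frame(idx = i)))
  }, numeric(1))
  expect_equal(as.vector(sm)[(half + 1):(60 - half)], direct,
               tolerance = 1e-8)
})

test_that("ROI averaging matches per-band arithmetic means", {
  cube <- make_cube(0, nl = 2, ns = 2, nb = 2, wl = c(500, 600))
  cube$data[1, 1, ] <- c(0.2, 0.6)
  cube$data[2, 1, ] <- c(0.4, 0.8)
  cube$calibrated <- TRUE

  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(unname(roi_mean_spectrum(cube, one)), c(0.2, 0.6))

  two <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(unname(roi_mean_spectrum(cube, two)), c(0.3, 0.7))

  unif <- make_cube(0.37, nb = 2, wl = c(500, 600))
  unif$calibrated <- TRUE
  expect_equal(unname(roi_mean_spectrum(unif, matrix(TRUE, 2, 2))),
               c(0.37, 0.37))
  expect_error(roi_mean_spectrum(cube, matrix(FALSE, 2, 2)), "empty")
  cube$calibrated <- FALSE
  expect_error(roi_mean_spectrum(cube, two), "calibrated")
})
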