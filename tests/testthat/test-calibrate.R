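test_that("a +2 cm^-1 axis shift is recovered to within 0.2 cm^-1", {
  cfg <- synthetic_config(axis_shift = 2)
  cal <- fit_calibration(generate_reference(cfg))
  # the fitted correction maps measured (shifted) positions back to truth
  shift_hat <- mean(cal$matched$measured - cal$matched$literature)
  expect_lt(abs(shift_hat - 2), 0.2)
  wn <- seq(500, 3000, by = 50)
  expect_lt(max(abs(predict(cal, wn + 2) - wn)), 0.2)
})

test_that("an unshifted reference yields the identity map with near-zero rmse", {
  cal <- fit_calibration(generate_reference(synthetic_config(axis_shift = 0)))
  wn <- seq(500, 3000, by = 50)
  expect_lt(max(abs(predict(cal, wn) - wn)), 0.2)
  expect_lt(cal$fit_rmse, 0.3)
  expect_gte(cal$n_peaks_used, cal$poly_degree + 1)
})

test_that("too few detectable peaks for the requested degree errors", {
  wn <- seq(400, 1600, by = 1)
  y <- 10 + 200 * exp(-0.5 * ((wn - 600) / 3)^2) +
    200 * exp(-0.5 * ((wn - 1200) / 3)^2)
  y <- y + withr::with_seed(2, rnorm(length(wn), 0, 2))
  ref <- raman_spectra(matrix(y, 1), wn, tibble::tibble(spectrum_id = "r"))
  pk <- tibble::tibble(position = c(600, 900, 1200), name = letters[1:3])
  expect_error(fit_calibration(ref, peaks = pk, poly_degree = 2), "peaks")
})

test_that("overwhelming noise defeats peak detection", {
  cfg <- synthetic_config(noise_sd = 5000)
  expect_error(fit_calibration(generate_reference(cfg)), "peaks")
})

test_that("identity calibration equals plain resampling", {
  ds <- toy_spectra()
  ident <- structure(list(poly_degree = 1, coefficients = c(0, 1),
                          fit_rmse = 0, n_peaks_used = 3,
                          matched = tibble::tibble()),
                     class = "raman_calibration")
  target <- c(450, 550, 650, 750)
  a <- apply_calibration(ds, ident, target)
  b <- resample_to_axis(ds, target)
  expect_equal(a$intensity, b$intensity, ignore_attr = TRUE)
})

test_that("a calibrated distorted dataset lands peaks on truth within 0.5 cm^-1", {
  cfg <- synthetic_config(axis_shift = 2)
  cal <- fit_calibration(generate_reference(cfg))
  ref <- generate_reference(cfg)
  corr <- apply_calibration(ref, cal)
  # strongest band should sit at its literature position after correction
  pks <- reference_peaks()
  for (p in c(651.6, 1168.5, 1648.4)) {
    sel <- which(abs(corr$wavenumber - p) <= 6)
    i <- sel[which.max(corr$intensity[1, sel])]
    y <- corr$intensity[1, ]
    d2 <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (d2 < 0) 0.5 * (y[i - 1] - y[i + 1]) / d2 else 0
    centroid <- corr$wavenumber[i] + delta *
      (corr$wavenumber[i + 1] - corr$wavenumber[i - 1]) / 2
    expect_lt(abs(centroid - p), 0.5)
  }
})

test_that("refitting on a corrected reference is stable", {
  cfg <- synthetic_config(axis_shift = 2)
  ref <- generate_reference(cfg)
  cal <- fit_calibration(ref)
  corrected <- apply_calibration(ref, cal)
  cal2 <- fit_calibration(corrected)
  wn <- seq(450, 3000, by = 50)
  expect_lt(max(abs(predict(cal2, wn) - wn)), 0.2)
})

test_that("a fold-back calibration polynomial is rejected", {
  fold <- structure(list(poly_degree = 2, coefficients = c(0, 1, -1e-3),
                         fit_rmse = 0, n_peaks_used = 3,
                         matched = tibble::tibble()),
                    class = "raman_calibration")
  expect_error(apply_calibration(toy_spectra(), fold), "folds")
})
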