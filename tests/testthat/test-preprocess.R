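test_that("an injected spike is repaired and clean channels stay bit-identical", {
  cfg <- tiny_config(spike_rate = 0)
  ds <- generate_dataset(cfg)
  noise <- cfg$noise_sd
  i <- 3L; ch <- 200L
  spiked <- ds
  spiked$intensity[i, ch] <- spiked$intensity[i, ch] + 50 * noise
  out <- despike(spiked)
  rep <- spike_report(out)
  expect_true(any(rep$spectrum_id == ds$meta$spectrum_id[i] &
                    rep$channel == ch))
  expect_lt(abs(out$intensity[i, ch] - ds$intensity[i, ch]), 5 * noise)
  # unflagged channels are untouched
  flagged <- rep$channel[rep$spectrum_id == ds$meta$spectrum_id[i]]
  expect_identical(out$intensity[i, -flagged], spiked$intensity[i, -flagged])
})

test_that("spike-free and degenerate spectra yield zero repairs", {
  ds <- generate_dataset(tiny_config(spike_rate = 0))
  out <- despike(ds)
  # clean-channel false-alarm fraction, not strict absence: noise can
  # occasionally exceed the 8-MAD threshold
  expect_lt(nrow(spike_report(out)) / length(ds$intensity), 0.01)
  zero <- raman_spectra(matrix(0, 1, 100), seq(400, 895, by = 5),
                        tibble::tibble(spectrum_id = "z"))
  expect_equal(nrow(spike_report(despike(zero))), 0)
  expect_equal(despike(zero)$intensity[1, ], rep(0, 100),
               ignore_attr = TRUE)
})

test_that("snip removes a pure linear baseline", {
  y <- seq(100, 1000, length.out = 1500)
  raw <- snip_baseline(y, preprocess_config(snip_lls = FALSE))
  expect_lt(max(abs(raw$corrected)), 0.01 * diff(range(y)))
  # the LLS-compressed variant carries a bounded low-end curvature bias
  lls <- snip_baseline(y)
  expect_lt(max(abs(lls$corrected)), 0.15 * diff(range(y)))
})

test_that("snip recovers an isolated Gaussian peak height within 5%", {
  x <- seq_len(1200)
  truth <- 80 * exp(-0.5 * ((x - 600) / 5)^2)
  out <- snip_baseline(truth + 250)
  expect_lt(abs(max(out$corrected) - 80) / 80, 0.05)
})

test_that("snip on the zero spectrum is a fixed point and rejects non-finite", {
  out <- snip_baseline(rep(0, 200))
  expect_equal(out$baseline, rep(0, 200))
  expect_equal(out$corrected, rep(0, 200))
  expect_error(snip_baseline(c(1, NA, 3)), "finite")
})

test_that("snip baseline never exceeds the input", {
  set.seed(4)
  for (k in 1:5) {
    y <- abs(rnorm(400, 100, 20)) +
      60 * exp(-0.5 * ((seq_len(400) - 80 * k) / 6)^2)
    out <- snip_baseline(y)
    expect_true(all(out$baseline <= y + 1e-9))
    expect_true(all(out$corrected >= -1e-9))
  }
})

test_that("raw-domain snip baseline is shift-equivariant", {
  cfg <- preprocess_config(snip_lls = FALSE)
  set.seed(7)
  for (k in 1:5) {
    y <- abs(rnorm(300, 50, 10)) +
      40 * exp(-0.5 * ((seq_len(300) - 150) / 8)^2)
    c0 <- 10 * k
    b1 <- snip_baseline(y, cfg)$baseline
    b2 <- snip_baseline(y + c0, cfg)$baseline
    expect_equal(b2, b1 + c0, tolerance = 1e-6)
  }
})

test_that("vector normalization has unit norm, preserves direction, rejects zero", {
  y <- c(3, 4, 0, 1)
  out <- vector_normalize(y)
  expect_equal(sqrt(sum(out^2)), 1, tolerance = 1e-12)
  expect_equal(vector_normalize(7 * y), out)
  expect_error(vector_normalize(rep(0, 5)), "zero")
})

test_that("clipping retains exactly the keep ranges, inclusively", {
  wn <- seq(350, 3500, by = 1)
  rs <- raman_spectra(matrix(1, 1, length(wn)), wn,
                      tibble::tibble(spectrum_id = "a"))
  out <- clip_ranges(rs)
  expect_setequal(out$wavenumber, c(400:1800, 2800:3050))
  # idempotence on an axis already equal to the keep set
  again <- clip_ranges(out)
  expect_equal(again$wavenumber, out$wavenumber)
  expect_equal(again$intensity, out$intensity, ignore_attr = TRUE)
  # axis entirely inside the excluded silent region
  silent <- raman_spectra(matrix(1, 1, 101), seq(2000, 2100, by = 1),
                          tibble::tibble(spectrum_id = "a"))
  expect_error(clip_ranges(silent), "every channel")
})

test_that("full chain yields unit-norm spectra on the keep ranges", {
  ds <- generate_dataset(tiny_config())
  pp <- preprocess(ds)
  expect_true(all(abs(sqrt(rowSums(pp$intensity^2)) - 1) < 1e-9))
  expect_true(all((pp$wavenumber >= 400 & pp$wavenumber <= 1800) |
                    (pp$wavenumber >= 2800 & pp$wavenumber <= 3050)))
  expect_true(any(grepl("despike", pp$provenance)))
  expect_true(any(grepl("snip", pp$provenance)))
})

test_that("normalization and clipping are idempotent on a second pass", {
  ds <- generate_dataset(tiny_config())
  once <- preprocess(ds)
  twice <- preprocess(once, despike = FALSE, baseline = FALSE)
  expect_equal(twice$intensity, once$intensity, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("mean corrected spectrum matches the clean class template", {
  # full-resolution axis: the SNIP window is defined in channels, so the
  # clean-recovery oracle is stated at the 1 cm^-1 study resolution
  ds <- generate_dataset(tiny_config(cells_per_mouse = 15, axis_step = 1))
  gt <- ground_truth(ds)
  pp <- preprocess(ds)
  keep <- ds$wavenumber %in% pp$wavenumber
  for (cl in c("sham", "sick")) {
    m <- colMeans(pp$intensity[pp$meta$group == cl, ])
    expect_gt(stats::cor(m, gt$templates[[cl]][keep]), 0.99)
  }
})
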