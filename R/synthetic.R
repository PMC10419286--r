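#' Default band template for synthetic T-lymphocyte spectra
#'
#' A compact Gaussian-band model of a T-cell Raman spectrum: band centres
#' follow the biochemical band catalogue (nucleic acids, proteins, lipids,
#' amino acids), widths are 6-16 cm^-1 in the fingerprint region and
#' 20-30 cm^-1 in the CH-stretch region, amplitudes are arbitrary counts.
#' `sick_factor` is the multiplicative class effect applied to the sick
#' group: nucleic-acid bands (785, 1094, 1334 cm^-1) are elevated in sick
#' cells; amino-acid bands (527, 641 cm^-1) and the lipid ester band
#' (1754 cm^-1) are elevated in sham cells.
#'
#' @return A tibble with columns `center`, `width`, `amplitude`,
#'   `sick_factor`, `category`.
#' @examples
#' default_band_template()
#' @export
default_band_template <- function() {
  tibble::tribble(
    ~center, ~width, ~amplitude, ~sick_factor, ~category,
    527,   8,  25, 0.75, "Amino Acids",
    641,   8,  25, 0.75, "Amino Acids",
    785,   9,  60, 1.35, "Nucleic Acids",
    830,  10,  30, 1.00, "Amino Acids",
    1004,   6,  70, 1.00, "Proteins",
    1094,  10,  50, 1.40, "Nucleic Acids",
    1127,  10,  30, 1.00, "Lipids",
    1260,  14,  40, 1.00, "Proteins",
    1334,  10,  45, 1.30, "Nucleic Acids",
    1450,  12,  60, 1.00, "Proteins",
    1580,  12,  35, 1.00, "Nucleic Acids",
    1657,  16,  80, 1.00, "Proteins",
    1754,  10,  20, 0.75, "Lipids",
    2850,  22,  50, 1.00, "Lipids",
    2885,  22,  60, 1.00, "Lipids",
    2936,  28, 120, 1.00, "Proteins",
    3010,  20,  25, 1.00, "Lipids"
  )
}

#' Configuration of the synthetic dataset generator
#'
#' Describes the full generative model for hierarchical single-cell Raman
#' data: batch -> mouse -> cell -> spectrum. Each spectrum is a sum of
#' Gaussian bands whose amplitudes carry a multiplicative class effect
#' (raised to `effect_scale`; 0 gives an exact null), lognormal per-mouse
#' band jitter and a lognormal per-batch gain, plus a smooth fluorescence
#' baseline (quadratic + broad hump), white Gaussian noise and
#' Poisson-placed cosmic spikes. `axis_shift` offsets the recorded
#' wavenumber axis to emulate miscalibration.
#'
#' @param band_template tibble as from [default_band_template()].
#' @param effect_scale global exponent on the class factors; 0 = null,
#'   1 = default (strong, separable) effect.
#' @param n_batches,mice_per_group_per_batch,cells_per_mouse,spectra_per_cell
#'   hierarchy sizes (defaults 4, 4, 50, 1: a screening-mode design of
#'   1600 spectra).
#' @param model infection model label stamped on the metadata
#'   (`"PCI"` or `"LPS"`).
#' @param baseline_scale typical fluorescence baseline magnitude (counts).
#' @param noise_sd white-noise standard deviation (counts).
#' @param spike_rate expected cosmic spikes per spectrum (Poisson).
#' @param spike_amplitude spike height as a multiple of `noise_sd`.
#' @param batch_effect_sd sdlog of the per-batch lognormal gain; a matching
#'   per-batch baseline tilt is also drawn.
#' @param mouse_sdlog sdlog of the per-mouse, per-band lognormal amplitude
#'   jitter (biological heterogeneity between animals).
#' @param axis_start,axis_stop,axis_step recorded wavenumber grid (cm^-1).
#' @param axis_shift constant miscalibration of the recorded axis (cm^-1):
#'   true band centres appear at `center + axis_shift`.
#' @param seed integer seed; all randomness derives from it.
#' @return A `synthetic_config` list.
#' @examples
#' synthetic_config(n_batches = 2, cells_per_mouse = 10)
#' @export
synthetic_config <- function(band_template = default_band_template(),
                             effect_scale = 1,
                             n_batches = 4,
                             mice_per_group_per_batch = 4,
                             cells_per_mouse = 50,
                             spectra_per_cell = 1,
                             model = "PCI",
                             baseline_scale = 400,
                             noise_sd = 4,
                             spike_rate = 0.3,
                             spike_amplitude = 50,
                             batch_effect_sd = 0.05,
                             mouse_sdlog = 0.06,
                             axis_start = 350,
                             axis_stop = 3100,
                             axis_step = 1,
                             axis_shift = 0,
                             seed = 1) {
  stopifnot(n_batches >= 1, mice_per_group_per_batch >= 1,
            cells_per_mouse >= 1, spectra_per_cell >= 1,
            noise_sd >= 0, spike_rate >= 0, effect_scale >= 0,
            axis_step > 0, axis_start > 0, axis_stop > axis_start)
  model <- match.arg(model, c("PCI", "LPS"))
  structure(
    list(band_template = tibble::as_tibble(band_template),
         effect_scale = effect_scale, n_batches = n_batches,
         mice_per_group_per_batch = mice_per_group_per_batch,
         cells_per_mouse = cells_per_mouse,
         spectra_per_cell = spectra_per_cell, model = model,
         baseline_scale = baseline_scale, noise_sd = noise_sd,
         spike_rate = spike_rate, spike_amplitude = spike_amplitude,
         batch_effect_sd = batch_effect_sd, mouse_sdlog = mouse_sdlog,
         axis_start = axis_start, axis_stop = axis_stop,
         axis_step = axis_step, axis_shift = axis_shift,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

gaussian_shapes <- function(axis_true, centers, widths) {
  # channels x bands matrix of unit-height Gaussian band profiles
  vapply(seq_along(centers), function(j) {
    exp(-0.5 * ((axis_true - centers[j]) / widths[j])^2)
  }, numeric(length(axis_true)))
}

#' Generate a hierarchical synthetic single-cell Raman dataset
#'
#' Draws a full dataset under a [synthetic_config()], with sham and sick
#' mice in every batch. Ground truth is attached as the `ground_truth`
#' attribute: the clean band-only signal per spectrum, the unit-norm class
#' templates on the clipped axis convention, injected spike positions and
#' the config itself.
#'
#' @param cfg a [synthetic_config()].
#' @return A [raman_spectra] dataset with a `ground_truth` attribute
#'   (retrievable with [ground_truth()]).
#' @examples
#' rs <- generate_dataset(synthetic_config(n_batches = 2, cells_per_mouse = 5))
#' rs
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  axis <- seq(cfg$axis_start, cfg$axis_stop, by = cfg$axis_step)
  axis_true <- axis - cfg$axis_shift     # band positions in recorded coords
  bt <- cfg$band_template
  shapes <- gaussian_shapes(axis_true, bt$center, bt$width)
  n_ch <- length(axis)
  class_factor <- function(group) {
    if (group == "sick") bt$sick_factor^cfg$effect_scale else rep(1, nrow(bt))
  }
  t01 <- seq(0, 1, length.out = n_ch)

  n_total <- cfg$n_batches * 2 * cfg$mice_per_group_per_batch *
    cfg$cells_per_mouse * cfg$spectra_per_cell
  intensity <- matrix(0, n_total, n_ch)
  clean <- matrix(0, n_total, n_ch)
  meta <- vector("list", n_total)
  spike_rows <- list()
  idx <- 0L

  for (b in seq_len(cfg$n_batches)) {
    batch_gain <- stats::rlnorm(1, 0, cfg$batch_effect_sd)
    batch_tilt <- stats::rnorm(1, 0, cfg$batch_effect_sd) * cfg$baseline_scale
    for (grp in c("sham", "sick")) {
      for (m in seq_len(cfg$mice_per_group_per_batch)) {
        mouse_id <- sprintf("b%d_%s_m%d", b, grp, m)
        mouse_jitter <- stats::rlnorm(nrow(bt), 0, cfg$mouse_sdlog)
        amps <- bt$amplitude * class_factor(grp) * mouse_jitter * batch_gain
        mouse_clean <- drop(shapes %*% amps)
        for (cc in seq_len(cfg$cells_per_mouse)) {
          for (s in seq_len(cfg$spectra_per_cell)) {
            idx <- idx + 1L
            cell_gain <- stats::rlnorm(1, 0, 0.03)
            sig <- mouse_clean * cell_gain
            b0 <- cfg$baseline_scale * stats::runif(1, 0.5, 1.5)
            b1 <- stats::rnorm(1, 0, 0.3) * cfg$baseline_scale + batch_tilt
            b2 <- stats::rnorm(1, 0, 0.2) * cfg$baseline_scale
            hump_c <- stats::runif(1, cfg$axis_start, cfg$axis_stop)
            hump_w <- stats::runif(1, 300, 700)
            hump_a <- stats::runif(1, 0, 0.5) * cfg$baseline_scale
            base <- b0 + b1 * t01 + b2 * t01^2 +
              hump_a * exp(-0.5 * ((axis - hump_c) / hump_w)^2)
            base <- base - min(base) + 0.1 * cfg$baseline_scale  # keep counts positive
            y <- sig + base + stats::rnorm(n_ch, 0, cfg$noise_sd)
            n_spk <- stats::rpois(1, cfg$spike_rate)
            if (n_spk > 0) {
              pos <- sample(seq(3, n_ch - 2), n_spk)
              for (p in pos) {
                w <- sample(c(1L, 2L), 1, prob = c(0.8, 0.2))
                ch <- p:min(p + w - 1L, n_ch)
                y[ch] <- y[ch] + cfg$spike_amplitude * cfg$noise_sd *
                  stats::runif(1, 0.7, 1.3)
                spike_rows[[length(spike_rows) + 1L]] <-
                  tibble::tibble(row = idx, channel = ch)
              }
            }
            intensity[idx, ] <- y
            clean[idx, ] <- sig
            meta[[idx]] <- tibble::tibble(
              spectrum_id = sprintf("s%05d", idx),
              batch_id = sprintf("batch%d", b), mouse_id = mouse_id,
              group = grp, model = cfg$model,
              cell_id = sprintf("%s_c%d", mouse_id, cc)
            )
          }
        }
      }
    }
  }
  meta <- dplyr::bind_rows(meta)
  ds <- raman_spectra(intensity, axis, meta,
                      provenance = sprintf("synthetic[seed=%d]", cfg$seed))
  spikes <- if (length(spike_rows)) {
    sp <- dplyr::bind_rows(spike_rows)
    tibble::tibble(spectrum_id = meta$spectrum_id[sp$row],
                   channel = sp$channel)
  } else {
    tibble::tibble(spectrum_id = character(), channel = integer())
  }
  templates <- list(
    sham = drop(shapes %*% bt$amplitude),
    sick = drop(shapes %*% (bt$amplitude * bt$sick_factor^cfg$effect_scale))
  )
  attr(ds, "ground_truth") <- list(
    clean = clean, templates = templates, spikes = spikes,
    band_template = bt, config = cfg
  )
  ds
}

#' Ground truth attached to a synthetic dataset
#' @param ds a dataset from [generate_dataset()].
#' @return The `ground_truth` list (clean signal matrix, class templates,
#'   spike table, band template, config), or `NULL`.
#' @export
ground_truth <- function(ds) attr(ds, "ground_truth")

#' Generate a synthetic calibration-reference spectrum
#'
#' A sharp-band spectrum of the 4-acetamidophenol standard at the shipped
#' literature positions, on the same (possibly shifted) recorded axis as
#' [generate_dataset()], with a small constant offset and the config's
#' white noise. Used to exercise wavenumber calibration with a known
#' distortion.
#'
#' @param cfg a [synthetic_config()]; `axis_shift` and `noise_sd` apply.
#' @param peaks band table from [reference_peaks()].
#' @return A single-spectrum [raman_spectra].
#' @examples
#' generate_reference(synthetic_config(axis_shift = 2))
#' @export
generate_reference <- function(cfg, peaks = reference_peaks()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed + 1L, {
    axis <- seq(cfg$axis_start, cfg$axis_stop, by = cfg$axis_step)
    axis_true <- axis - cfg$axis_shift
    keep <- peaks$position > min(axis_true) + 10 &
      peaks$position < max(axis_true) - 10
    shapes <- gaussian_shapes(axis_true, peaks$position[keep],
                              rep(3, sum(keep)))
    y <- drop(shapes %*% rep(200, sum(keep))) + 20 +
      stats::rnorm(length(axis), 0, cfg$noise_sd)
    raman_spectra(matrix(y, nrow = 1), axis,
                  tibble::tibble(spectrum_id = "reference"),
                  provenance = sprintf("synthetic_reference[shift=%g]",
                                       cfg$axis_shift))
  })
}
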