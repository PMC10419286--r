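#' Preprocessing configuration
#'
#' Collects every tunable of the spectral preprocessing chain: cosmic-spike
#' removal, SNIP baseline estimation, spectral clipping and vector
#' normalization.
#'
#' @param despike_zscore_threshold positive; a channel is a spike candidate
#'   when its residual from a running-median smooth exceeds this multiple of
#'   the robust residual scale (MAD). Default 8.
#' @param despike_max_width maximum run width (channels) still treated as a
#'   cosmic spike; wider excursions are real bands. Default 2.
#' @param despike_max_repairs cap on repaired channels per spectrum; runs
#'   beyond the cap are left untouched. Default 20.
#' @param despike_window running-median window (odd, >= 3). Default 5.
#' @param snip_max_halfwidth largest SNIP clipping half-window in channels
#'   (>= 1). Default 60.
#' @param snip_decreasing iterate the clipping window from wide to narrow
#'   (the low-artifact variant). Default `TRUE`.
#' @param snip_lls run the clipping in the compressed
#'   log-log-square-root domain, appropriate for count-like intensities.
#'   Default `TRUE`.
#' @param clip_keep_ranges list of `c(low, high)` wavenumber intervals
#'   (cm^-1) to retain, non-overlapping and increasing; boundaries are
#'   inclusive. Default keeps the fingerprint (400-1800) and CH-stretch
#'   (2800-3050) regions, excluding the silent region.
#' @param normalization only `"vector"` (unit Euclidean norm) is available.
#' @return A `preprocess_config` list.
#' @examples
#' preprocess_config(snip_max_halfwidth = 40)
#' @export
preprocess_config <- function(despike_zscore_threshold = 8,
                              despike_max_width = 2,
                              despike_max_repairs = 20,
                              despike_window = 5,
                              snip_max_halfwidth = 60,
                              snip_decreasing = TRUE,
                              snip_lls = TRUE,
                              clip_keep_ranges = list(c(400, 1800),
                                                      c(2800, 3050)),
                              normalization = "vector") {
  stopifnot(despike_zscore_threshold > 0, despike_max_width >= 1,
            despike_window >= 3, despike_window %% 2 == 1,
            snip_max_halfwidth >= 1)
  normalization <- match.arg(normalization, "vector")
  clip_keep_ranges <- lapply(clip_keep_ranges, as.numeric)
  flat <- unlist(clip_keep_ranges)
  if (any(diff(flat) <= 0)) {
    stop("clip_keep_ranges must be non-overlapping and increasing",
         call. = FALSE)
  }
  structure(
    list(despike_zscore_threshold = despike_zscore_threshold,
         despike_max_width = despike_max_width,
         despike_max_repairs = despike_max_repairs,
         despike_window = despike_window,
         snip_max_halfwidth = as.integer(snip_max_halfwidth),
         snip_decreasing = snip_decreasing,
         snip_lls = snip_lls,
         clip_keep_ranges = clip_keep_ranges,
         normalization = normalization),
    class = "preprocess_config"
  )
}

# flag narrow high-amplitude runs in one spectrum; returns integer channels
find_spikes <- function(y, cfg) {
  n <- length(y)
  med <- stats::runmed(y, cfg$despike_window, endrule = "median")
  resid <- y - med
  s <- stats::mad(resid)
  if (s == 0) return(integer())
  cand <- which(abs(resid) > cfg$despike_zscore_threshold * s)
  if (!length(cand)) return(integer())
  runs <- split(cand, cumsum(c(1, diff(cand) > 1)))
  hits <- unlist(runs[vapply(runs, length, 1L) <= cfg$despike_max_width],
                 use.names = FALSE)
  if (length(hits) > cfg$despike_max_repairs) {
    hits <- hits[seq_len(cfg$despike_max_repairs)]
  }
  sort(hits)
}

# replace flagged channels by linear interpolation across clean neighbours
repair_channels <- function(y, bad) {
  if (!length(bad)) return(y)
  good <- setdiff(seq_along(y), bad)
  y[bad] <- stats::approx(good, y[good], xout = bad, rule = 2)$y
  y
}

#' Remove cosmic spikes
#'
#' Detects narrow outlier runs (cosmic-ray artefacts) against a
#' running-median smooth and repairs them by linear interpolation across
#' the flanking clean channels. Channels that are not flagged are returned
#' bit-identical. The repairs are recorded in the `spike_report` attribute,
#' a tibble of `(spectrum_id, channel, wavenumber)`, retrievable with
#' [spike_report()].
#'
#' @param ds a [raman_spectra] dataset with >= 16 channels.
#' @param cfg a [preprocess_config()].
#' @return The despiked [raman_spectra] with a `spike_report` attribute.
#' @examples
#' rs <- generate_dataset(synthetic_config(n_batches = 1, cells_per_mouse = 2,
#'                                         spike_rate = 1))
#' out <- despike(rs)
#' spike_report(out)
#' @export
despike <- function(ds, cfg = preprocess_config()) {
  if (n_channels(ds) < max(16, cfg$despike_window)) {
    stop("spectra too short to despike (need >= 16 channels)", call. = FALSE)
  }
  reports <- vector("list", n_spectra(ds))
  for (i in seq_len(n_spectra(ds))) {
    bad <- find_spikes(ds$intensity[i, ], cfg)
    if (length(bad)) {
      ds$intensity[i, ] <- repair_channels(ds$intensity[i, ], bad)
      reports[[i]] <- tibble::tibble(
        spectrum_id = ds$meta$spectrum_id[i],
        channel = bad,
        wavenumber = ds$wavenumber[bad]
      )
    }
  }
  report <- dplyr::bind_rows(reports)
  if (nrow(report) == 0) {
    report <- tibble::tibble(spectrum_id = character(), channel = integer(),
                             wavenumber = numeric())
  }
  ds <- add_provenance(ds, sprintf("despike[z=%g,w=%d,repairs=%d]",
                                   cfg$despike_zscore_threshold,
                                   cfg$despike_max_width, nrow(report)))
  attr(ds, "spike_report") <- report
  ds
}

#' @rdname despike
#' @param x an object returned by [despike()] or [preprocess()].
#' @export
spike_report <- function(x) {
  rep <- attr(x, "spike_report")
  if (is.null(rep)) {
    tibble::tibble(spectrum_id = character(), channel = integer(),
                   wavenumber = numeric())
  } else rep
}

lls_forward <- function(y) log(log(sqrt(y + 1) + 1) + 1)
lls_backward <- function(z) (exp(exp(z) - 1) - 1)^2 - 1

# SNIP clipping on a spectra-by-channels matrix; returns the baseline matrix
snip_matrix <- function(mat, cfg) {
  n <- ncol(mat)
  m <- min(cfg$snip_max_halfwidth, (n - 1) %/% 2)
  offs <- NULL
  if (cfg$snip_lls) {
    offs <- apply(mat, 1, min)        # LLS needs non-negative input
    z <- lls_forward(sweep(mat, 1, offs))
  } else {
    z <- mat
  }
  windows <- if (cfg$snip_decreasing) seq(m, 1) else seq(1, m)
  for (p in windows) {
    i <- (p + 1):(n - p)
    z[, i] <- pmin(z[, i], (z[, i - p] + z[, i + p]) / 2)
  }
  base <- if (cfg$snip_lls) sweep(lls_backward(z), 1, offs, `+`) else z
  pmin(base, mat)
}

#' SNIP baseline estimation
#'
#' Estimates the slowly varying background (fluorescence, substrate) of a
#' spectrum by iterative peak clipping: at half-window p every channel is
#' replaced by the minimum of itself and the mean of its two neighbours p
#' channels away, sweeping p over `1..snip_max_halfwidth` (wide-to-narrow by
#' default). With `snip_lls = TRUE` the clipping runs in the compressed
#' log-log-square-root domain. The baseline never exceeds the input, so the
#' corrected spectrum is non-negative at every channel.
#'
#' @param spectrum numeric vector of finite intensities.
#' @param cfg a [preprocess_config()].
#' @return A list with `baseline` and `corrected` (= `spectrum - baseline`).
#' @examples
#' y <- 100 + 0.05 * (1:500) + 50 * exp(-((1:500) - 250)^2 / 50)
#' out <- snip_baseline(y)
#' max(out$corrected)
#' @export
snip_baseline <- function(spectrum, cfg = preprocess_config()) {
  if (!all(is.finite(spectrum))) {
    stop("spectrum contains non-finite values", call. = FALSE)
  }
  base <- snip_matrix(matrix(spectrum, nrow = 1), cfg)[1, ]
  list(baseline = base, corrected = spectrum - base)
}

subtract_baseline <- function(ds, cfg) {
  base <- snip_matrix(ds$intensity, cfg)
  ds$intensity <- ds$intensity - base
  add_provenance(ds, sprintf("snip[m=%d,%s%s]", cfg$snip_max_halfwidth,
                             if (cfg$snip_decreasing) "dec" else "inc",
                             if (cfg$snip_lls) ",lls" else ""))
}

#' Vector (unit Euclidean norm) normalization
#'
#' @param spectrum numeric vector with positive Euclidean norm.
#' @return The spectrum scaled to unit L2 norm.
#' @examples
#' sqrt(sum(vector_normalize(c(3, 4))^2))
#' @export
vector_normalize <- function(spectrum) {
  nrm <- sqrt(sum(spectrum^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop("cannot vector-normalize a zero (or non-finite) spectrum",
         call. = FALSE)
  }
  spectrum / nrm
}

normalize_rows <- function(ds) {
  nrm <- sqrt(rowSums(ds$intensity^2))
  if (any(nrm == 0)) {
    stop("dataset contains all-zero spectra; cannot vector-normalize",
         call. = FALSE)
  }
  ds$intensity <- ds$intensity / nrm
  add_provenance(ds, "vector_normalize")
}

#' Clip spectra to the informative wavenumber ranges
#'
#' Retains exactly the channels whose wavenumber falls inside one of the
#' keep intervals (boundaries inclusive); by default the fingerprint region
#' 400-1800 cm^-1 and the CH-stretching region 2800-3050 cm^-1, dropping
#' the biologically silent 1800-2800 cm^-1 band.
#'
#' @param ds a [raman_spectra] dataset.
#' @param cfg a [preprocess_config()] supplying `clip_keep_ranges`.
#' @return The clipped [raman_spectra].
#' @examples
#' rs <- generate_dataset(synthetic_config(n_batches = 1, cells_per_mouse = 2))
#' range(clip_ranges(rs)$wavenumber)
#' @export
clip_ranges <- function(ds, cfg = preprocess_config()) {
  keep <- rep(FALSE, n_channels(ds))
  for (rng in cfg$clip_keep_ranges) {
    keep <- keep | (ds$wavenumber >= rng[1] & ds$wavenumber <= rng[2])
  }
  if (!any(keep)) {
    stop("clipping removed every channel; check clip_keep_ranges",
         call. = FALSE)
  }
  out <- raman_spectra(ds$intensity[, keep, drop = FALSE],
                       ds$wavenumber[keep], ds$meta, ds$provenance)
  add_provenance(out, sprintf("clip[%s]", paste(
    vapply(cfg$clip_keep_ranges, function(r) paste(r, collapse = "-"), ""),
    collapse = ",")))
}

#' Full preprocessing chain
#'
#' Applies, in order: cosmic-spike removal, SNIP baseline subtraction,
#' wavenumber calibration (when a fitted [calibration] model is given),
#' clipping to the keep ranges, and vector normalization over the retained
#' channels. Each stage and its parameters are recorded in the provenance
#' log; the despiking repairs are kept in the `spike_report` attribute.
#'
#' @param ds a [raman_spectra] dataset.
#' @param cfg a [preprocess_config()].
#' @param calibration optional calibration model from [fit_calibration()].
#' @param despike,baseline logical switches for the first two stages
#'   (both `TRUE` by default); normalization and clipping always run.
#' @return The preprocessed [raman_spectra]: unit-norm spectra on the
#'   clipped axis.
#' @examples
#' rs <- generate_dataset(synthetic_config(n_batches = 1, cells_per_mouse = 2))
#' pp <- preprocess(rs)
#' range(pp$wavenumber); sqrt(sum(pp$intensity[1, ]^2))
#' @export
preprocess <- function(ds, cfg = preprocess_config(), calibration = NULL,
                       despike = TRUE, baseline = TRUE) {
  report <- NULL
  if (despike) {
    ds <- scraman::despike(ds, cfg)
    report <- spike_report(ds)
  }
  if (baseline) ds <- subtract_baseline(ds, cfg)
  if (!is.null(calibration)) ds <- apply_calibration(ds, calibration)
  ds <- clip_ranges(ds, cfg)
  ds <- normalize_rows(ds)
  attr(ds, "spike_report") <- report
  ds
}
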