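#' Biochemical band assignment catalogue
#'
#' Loads the shipped catalogue of tentative Raman band assignments for
#' immune cells: single positions and ranges (cm^-1) mapped to the classes
#' Nucleic Acids, Proteins, Lipids, Lipids and Proteins, Amino Acids. The
#' table is plain CSV under `inst/extdata` and may be extended by the user.
#'
#' @param path CSV with columns `low`, `high`, `category`.
#' @return A tibble with one row per band.
#' @examples
#' band_table()
#' @export
band_table <- function(path = system.file("extdata", "band_assignments.csv",
                                          package = "scraman")) {
  bt <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("low", "high", "category") %in% names(bt)),
            all(bt$high >= bt$low))
  bt
}

#' Channelwise mean spectrum of a metadata selection
#'
#' @param ds a [raman_spectra] dataset.
#' @param ... optional [dplyr::filter()] expressions over the metadata;
#'   omitted means all spectra.
#' @return A tibble with `wavenumber`, `mean` and `sd` (per-channel
#'   standard deviation; 0 for a single spectrum).
#' @examples
#' rs <- preprocess(generate_dataset(synthetic_config(n_batches = 1,
#'                                                    cells_per_mouse = 5)))
#' mean_spectrum(rs, group == "sick")
#' @export
mean_spectrum <- function(ds, ...) {
  sel <- if (...length() > 0) filter_spectra(ds, ...) else ds
  if (n_spectra(sel) == 0) {
    stop("selection matches no spectra", call. = FALSE)
  }
  s <- if (n_spectra(sel) > 1) apply(sel$intensity, 2, stats::sd) else
    rep(0, n_channels(sel))
  tibble::tibble(wavenumber = sel$wavenumber,
                 mean = colMeans(sel$intensity), sd = s)
}

# robust noise scale from channel-to-channel increments
increment_noise <- function(v) {
  stats::median(abs(diff(v))) / (0.6745 * sqrt(2))
}

# local extrema of one sign with a simple prominence estimate
find_extrema <- function(wn, v, sign = 1, min_prominence = 0) {
  s <- sign * v
  n <- length(s)
  cand <- which(s[c(-1, -n)] > s[seq_len(n - 2)] &
                  s[c(-1, -n)] >= s[3:n]) + 1L
  rows <- lapply(cand, function(i) {
    j <- i; leftmin <- s[i]
    while (j > 1 && s[j] <= s[i]) { leftmin <- min(leftmin, s[j]); j <- j - 1 }
    if (j == 1 && s[j] <= s[i]) leftmin <- min(leftmin, s[1])
    j <- i; rightmin <- s[i]
    while (j < n && s[j] <= s[i]) { rightmin <- min(rightmin, s[j]); j <- j + 1 }
    if (j == n && s[j] <= s[i]) rightmin <- min(rightmin, s[n])
    prom <- s[i] - max(leftmin, rightmin)
    tibble::tibble(position = wn[i], amplitude = v[i], prominence = prom,
                   sign = sign)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(position = numeric(), amplitude = numeric(),
                          prominence = numeric(), sign = numeric()))
  }
  dplyr::filter(out, .data$prominence >= min_prominence)
}

#' Difference spectrum between two metadata selections
#'
#' Computes `mean(A) - mean(B)` channelwise and detects signed peaks:
#' local extrema of either sign whose prominence exceeds
#' `prominence_factor` times the robust noise scale (estimated from the
#' median absolute channel-to-channel increment). Detected peaks are
#' annotated against the band catalogue with [assign_bands()]. Positive
#' peaks mark bands elevated in selection A, negative peaks bands elevated
#' in B; swapping A and B negates the spectrum.
#'
#' @param ds a [raman_spectra] dataset (preprocessed, shared axis).
#' @param group_a,group_b [dplyr::filter()] expressions selecting the two
#'   groups, e.g. `group == "sick"`.
#' @param prominence_factor peak-prominence threshold in units of the
#'   noise scale (default 3).
#' @param bands band catalogue from [band_table()].
#' @param tolerance assignment tolerance in cm^-1 (see [assign_bands()]).
#' @return A `raman_difference` object: `data` (tibble `wavenumber`,
#'   `value`), `peaks` (annotated peak tibble), `label_a`, `label_b`.
#' @examples
#' rs <- preprocess(generate_dataset(synthetic_config(n_batches = 2,
#'                                                    cells_per_mouse = 10)))
#' difference_spectrum(rs, group == "sick", group == "sham")
#' @export
difference_spectrum <- function(ds, group_a, group_b,
                                prominence_factor = 3,
                                bands = band_table(), tolerance = 5) {
  qa <- rlang::enquo(group_a)
  qb <- rlang::enquo(group_b)
  a <- dplyr::filter(dplyr::mutate(ds$meta, .row = dplyr::row_number()), !!qa)
  b <- dplyr::filter(dplyr::mutate(ds$meta, .row = dplyr::row_number()), !!qb)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("both selections must match at least one spectrum", call. = FALSE)
  }
  v <- colMeans(ds$intensity[a$.row, , drop = FALSE]) -
    colMeans(ds$intensity[b$.row, , drop = FALSE])
  noise <- increment_noise(v)
  thr <- prominence_factor * noise
  peaks <- dplyr::bind_rows(
    find_extrema(ds$wavenumber, v, sign = 1, min_prominence = thr),
    find_extrema(ds$wavenumber, v, sign = -1, min_prominence = thr)
  )
  peaks <- dplyr::arrange(peaks, .data$position)
  peaks <- assign_bands(peaks, bands, tolerance = tolerance)
  structure(
    list(data = tibble::tibble(wavenumber = ds$wavenumber, value = v),
         peaks = peaks, label_a = rlang::as_label(qa),
         label_b = rlang::as_label(qb), noise = noise),
    class = "raman_difference"
  )
}

#' @export
print.raman_difference <- function(x, ...) {
  cat("<raman_difference> ", x$label_a, " - ", x$label_b, "; ",
      nrow(x$peaks), " peaks above ", signif(3 * x$noise, 3),
      "\n", sep = "")
  print(x$peaks, n = 10)
  invisible(x)
}

#' @export
tidy.raman_difference <- function(x, ...) x$peaks

#' Annotate peaks against the band catalogue
#'
#' Matches each detected peak to the nearest catalogue band whose single
#' position (within `tolerance` cm^-1) or range contains it. With
#' `tolerance = 0` only exact range containment assigns. Peaks matching
#' several equally close bands report all categories, separated by `"; "`;
#' peaks outside every band are labelled `"unassigned"`.
#'
#' @param peaks tibble with a `position` column (cm^-1).
#' @param bands catalogue from [band_table()].
#' @param tolerance matching tolerance in cm^-1 (default 5).
#' @return `peaks` with added `category` and `band` columns.
#' @examples
#' assign_bands(tibble::tibble(position = c(1094, 2000)))
#' @export
assign_bands <- function(peaks, bands = band_table(), tolerance = 5) {
  annotate <- function(p) {
    d <- pmax(bands$low - p, p - bands$high, 0)
    hit <- which(d <= tolerance)
    if (!length(hit)) {
      return(tibble::tibble(category = "unassigned", band = NA_character_))
    }
    hit <- hit[d[hit] == min(d[hit])]
    lab <- ifelse(bands$low[hit] == bands$high[hit],
                  as.character(bands$low[hit]),
                  paste0(bands$low[hit], "-", bands$high[hit]))
    tibble::tibble(category = paste(unique(bands$category[hit]),
                                    collapse = "; "),
                   band = paste(unique(lab), collapse = "; "))
  }
  dplyr::bind_cols(peaks, purrr::map_dfr(peaks$position, annotate))
}
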