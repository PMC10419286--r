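#' Single-cell Raman spectral dataset
#'
#' `raman_spectra()` bundles a collection of single-cell Raman spectra that
#' share one wavenumber axis with their hierarchical metadata (experimental
#' batch, mouse, group, infection model, cell). Intensities are stored as a
#' spectra-by-channels matrix; metadata as a tibble with one row per
#' spectrum. All processing verbs in the package take and return this
#' container, so calls chain with the pipe.
#'
#' @param intensity numeric matrix, one row per spectrum, one column per
#'   wavenumber channel (arbitrary counts).
#' @param wavenumber numeric vector of Raman shifts in cm^-1, strictly
#'   increasing, finite and positive; length must equal `ncol(intensity)`.
#' @param meta data frame with one row per spectrum. Must contain a
#'   `spectrum_id` column with unique values; the columns `batch_id`,
#'   `mouse_id`, `group` (`"sham"`/`"sick"`), `model` (`"PCI"`/`"LPS"`) and
#'   `cell_id` are filled with `"unknown"` when absent.
#' @param provenance character vector logging the processing steps already
#'   applied.
#'
#' @return An object of class `raman_spectra`: a list with elements
#'   `wavenumber`, `intensity`, `meta` and `provenance`.
#' @examples
#' wn <- 400:500
#' x <- matrix(rexp(2 * length(wn)), nrow = 2)
#' rs <- raman_spectra(x, wn, tibble::tibble(spectrum_id = c("a", "b")))
#' rs
#' @export
raman_spectra <- function(intensity, wavenumber, meta,
                          provenance = character()) {
  if (is.vector(intensity)) intensity <- matrix(intensity, nrow = 1)
  intensity <- as.matrix(intensity)
  wavenumber <- as.numeric(wavenumber)
  check_axis(wavenumber)
  if (ncol(intensity) != length(wavenumber)) {
    stop("`intensity` has ", ncol(intensity), " channels but `wavenumber` has ",
         length(wavenumber), call. = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  if (!"spectrum_id" %in% names(meta)) {
    stop("`meta` must contain a `spectrum_id` column", call. = FALSE)
  }
  if (nrow(meta) != nrow(intensity)) {
    stop("`meta` has ", nrow(meta), " rows but `intensity` has ",
         nrow(intensity), " spectra", call. = FALSE)
  }
  meta$spectrum_id <- as.character(meta$spectrum_id)
  if (anyDuplicated(meta$spectrum_id)) {
    stop("`spectrum_id` values must be unique", call. = FALSE)
  }
  for (col in c("batch_id", "mouse_id", "group", "model", "cell_id")) {
    if (!col %in% names(meta)) meta[[col]] <- "unknown"
    meta[[col]] <- as.character(meta[[col]])
  }
  bad_group <- setdiff(unique(meta$group), c("sham", "sick", "unknown"))
  if (length(bad_group)) {
    stop("`group` labels must be 'sham' or 'sick'; found: ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  }
  bad_model <- setdiff(unique(meta$model), c("PCI", "LPS", "unknown"))
  if (length(bad_model)) {
    stop("`model` labels must be 'PCI' or 'LPS'; found: ",
         paste(bad_model, collapse = ", "), call. = FALSE)
  }
  rownames(intensity) <- meta$spectrum_id
  structure(
    list(wavenumber = wavenumber, intensity = intensity, meta = meta,
         provenance = as.character(provenance)),
    class = "raman_spectra"
  )
}

check_axis <- function(wavenumber) {
  if (length(wavenumber) < 1 || !all(is.finite(wavenumber))) {
    stop("wavenumber axis must be finite", call. = FALSE)
  }
  if (any(wavenumber <= 0)) {
    stop("wavenumber axis must be positive", call. = FALSE)
  }
  if (length(wavenumber) > 1 && any(diff(wavenumber) <= 0)) {
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  invisible(wavenumber)
}

#' @export
print.raman_spectra <- function(x, ...) {
  cat("<raman_spectra> ", nrow(x$intensity), " spectra x ",
      length(x$wavenumber), " channels (",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)),
      " cm^-1)\n", sep = "")
  grp <- table(x$meta$group)
  cat("  groups: ", paste(names(grp), grp, sep = "=", collapse = ", "),
      "; batches: ", length(unique(x$meta$batch_id)),
      "; mice: ", length(unique(x$meta$mouse_id)), "\n", sep = "")
  if (length(x$provenance)) {
    cat("  provenance: ", paste(x$provenance, collapse = " -> "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Number of spectra / channels in a dataset
#' @param ds a [raman_spectra] object.
#' @return An integer count.
#' @export
n_spectra <- function(ds) nrow(ds$intensity)

#' @rdname n_spectra
#' @export
n_channels <- function(ds) length(ds$wavenumber)

#' Subset a spectral dataset by spectrum
#'
#' @param x a [raman_spectra] object.
#' @param i row (spectrum) index: integer, logical or spectrum_id character.
#' @param ... ignored.
#' @return A [raman_spectra] with the selected spectra.
#' @export
`[.raman_spectra` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$spectrum_id)
  raman_spectra(x$intensity[i, , drop = FALSE], x$wavenumber,
                x$meta[i, , drop = FALSE], x$provenance)
}

#' Filter spectra by metadata
#'
#' dplyr-style filtering on the metadata table; the intensity matrix is
#' subset to match.
#'
#' @param ds a [raman_spectra] object.
#' @param ... logical expressions over metadata columns, as in
#'   [dplyr::filter()].
#' @return A [raman_spectra] with matching spectra only.
#' @examples
#' rs <- generate_dataset(synthetic_config(n_batches = 1, cells_per_mouse = 2))
#' filter_spectra(rs, group == "sick")
#' @export
filter_spectra <- function(ds, ...) {
  keep <- dplyr::mutate(ds$meta, .row = dplyr::row_number())
  keep <- dplyr::filter(keep, ...)
  ds[keep$.row]
}

#' Tidy a spectral dataset into long form
#'
#' @param x a [raman_spectra] object.
#' @param ... ignored.
#' @return A tibble with columns `spectrum_id`, `wavenumber`, `intensity`
#'   and the metadata columns.
#' @export
tidy.raman_spectra <- function(x, ...) {
  long <- tibble::tibble(
    spectrum_id = rep(x$meta$spectrum_id, each = length(x$wavenumber)),
    wavenumber = rep(x$wavenumber, times = nrow(x$intensity)),
    intensity = as.vector(t(x$intensity))
  )
  dplyr::left_join(long, x$meta, by = "spectrum_id")
}

#' @exportS3Method tibble::as_tibble
as_tibble.raman_spectra <- function(x, ...) tidy.raman_spectra(x, ...)

#' One-line summary of a spectral dataset
#' @param x a [raman_spectra] object.
#' @param ... ignored.
#' @return A one-row tibble with dataset dimensions and axis range.
#' @export
glance.raman_spectra <- function(x, ...) {
  tibble::tibble(
    n_spectra = n_spectra(x), n_channels = n_channels(x),
    wn_min = min(x$wavenumber), wn_max = max(x$wavenumber),
    n_batches = length(unique(x$meta$batch_id)),
    n_mice = length(unique(x$meta$mouse_id))
  )
}

add_provenance <- function(ds, step) {
  ds$provenance <- c(ds$provenance, step)
  ds
}

#' Resample spectra onto a target wavenumber axis
#'
#' Linear interpolation of every spectrum onto `target`. The target must lie
#' inside the source axis range: extrapolation is refused.
#'
#' @param ds a [raman_spectra] object.
#' @param target numeric wavenumber axis (strictly increasing, cm^-1). The
#'   default builds a uniform 1 cm^-1 grid spanning the source axis.
#' @return A [raman_spectra] on the target axis.
#' @examples
#' rs <- generate_dataset(synthetic_config(n_batches = 1, cells_per_mouse = 2))
#' resample_to_axis(rs, seq(500, 3000, by = 2))
#' @export
resample_to_axis <- function(ds, target = NULL) {
  if (is.null(target)) {
    target <- seq(ceiling(min(ds$wavenumber)), floor(max(ds$wavenumber)), by = 1)
  }
  target <- as.numeric(target)
  check_axis(target)
  if (min(target) < min(ds$wavenumber) || max(target) > max(ds$wavenumber)) {
    stop("target axis [", min(target), ", ", max(target),
         "] extends past the source axis [", min(ds$wavenumber), ", ",
         max(ds$wavenumber), "]; extrapolation is not supported",
         call. = FALSE)
  }
  res <- t(apply(ds$intensity, 1, function(y) {
    stats::approx(ds$wavenumber, y, xout = target)$y
  }))
  if (length(target) == 1) res <- matrix(res, ncol = 1)
  out <- raman_spectra(res, target, ds$meta, ds$provenance)
  add_provenance(out, sprintf("resample[%g-%g,n=%d]", min(target),
                              max(target), length(target)))
}
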