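#' Read spectra from delimited text
#'
#' Two plain-text dialects are supported. `wide`: first column `wavenumber`,
#' one column per spectrum (column name = spectrum_id). `long`: columns
#' `spectrum_id`, `wavenumber`, `intensity`. Metadata travel in a sidecar
#' table keyed by `spectrum_id` with columns `batch_id`, `mouse_id`,
#' `group`, `model`, `cell_id`; it is required for the long dialect and
#' optional for the wide one.
#'
#' @param path path to the spectral table (CSV).
#' @param format `"wide"` or `"long"`.
#' @param metadata optional path to the metadata sidecar CSV.
#' @return A [raman_spectra] dataset.
#' @examples
#' rs <- generate_dataset(synthetic_config(n_batches = 1, cells_per_mouse = 2))
#' f <- tempfile(fileext = ".csv")
#' write_spectra(rs, f, format = "wide")
#' read_spectra(f, format = "wide")
#' @export
read_spectra <- function(path, format = c("wide", "long"), metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE)
  if (format == "wide") {
    wn <- as.numeric(raw[[1]])
    ids <- names(raw)[-1]
    mat <- t(as.matrix(raw[, -1, drop = FALSE]))
    o <- order(wn)
    wn <- wn[o]
    mat <- mat[, o, drop = FALSE]
    meta <- tibble::tibble(spectrum_id = ids)
  } else {
    need <- c("spectrum_id", "wavenumber", "intensity")
    if (!all(need %in% names(raw))) {
      stop("long format requires columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    ids <- unique(raw$spectrum_id)
    wn <- sort(unique(raw$wavenumber))
    wide <- tidyr::pivot_wider(raw, id_cols = "spectrum_id",
                               names_from = "wavenumber",
                               values_from = "intensity")
    lens <- table(raw$spectrum_id)
    if (length(unique(lens)) > 1 || anyNA(wide)) {
      stop("spectra have mismatched wavenumber support across spectrum_id",
           call. = FALSE)
    }
    mat <- as.matrix(wide[, -1, drop = FALSE])
    mat <- mat[, order(as.numeric(colnames(mat))), drop = FALSE]
    ids <- wide$spectrum_id
    meta <- tibble::tibble(spectrum_id = as.character(ids))
    if (is.null(metadata)) {
      side <- sub("\\.csv$", "_meta.csv", path)
      if (file.exists(side)) metadata <- side
      else stop("long format requires a metadata sidecar (use `metadata=`)",
                call. = FALSE)
    }
  }
  if (!is.null(metadata)) {
    md <- tibble::as_tibble(utils::read.csv(metadata,
                                            colClasses = "character"))
    missing <- setdiff(meta$spectrum_id, md$spectrum_id)
    if (length(missing)) {
      stop("metadata sidecar lacks entries for spectrum_id: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    meta <- dplyr::left_join(meta, md, by = "spectrum_id")
  }
  raman_spectra(mat, wn, meta,
                provenance = sprintf("read[%s,%s]", basename(path), format))
}

#' Write spectra to delimited text
#'
#' Inverse of [read_spectra()]; a metadata sidecar is always written so the
#' round trip preserves all labels.
#'
#' @param ds a non-empty [raman_spectra] dataset.
#' @param path output CSV path.
#' @param format `"wide"` or `"long"`.
#' @param metadata path for the metadata sidecar; defaults to
#'   `<path>_meta.csv`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, format = c("wide", "long"),
                          metadata = NULL) {
  format <- match.arg(format)
  if (n_spectra(ds) == 0) stop("refusing to write an empty dataset",
                               call. = FALSE)
  if (is.null(metadata)) metadata <- sub("\\.csv$", "_meta.csv", path)
  if (format == "wide") {
    out <- data.frame(wavenumber = ds$wavenumber, check.names = FALSE)
    out <- cbind(out, as.data.frame(t(ds$intensity), check.names = FALSE))
    names(out) <- c("wavenumber", ds$meta$spectrum_id)
    ok <- try(utils::write.csv(out, path, row.names = FALSE), silent = TRUE)
  } else {
    long <- tidy.raman_spectra(ds)[, c("spectrum_id", "wavenumber",
                                       "intensity")]
    ok <- try(utils::write.csv(long, path, row.names = FALSE), silent = TRUE)
  }
  if (inherits(ok, "try-error")) {
    stop("could not write to ", path, call. = FALSE)
  }
  utils::write.csv(
    ds$meta[, c("spectrum_id", "batch_id", "mouse_id", "group", "model",
                "cell_id")],
    metadata, row.names = FALSE
  )
  invisible(path)
}
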