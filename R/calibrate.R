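#' Literature band positions of the 4-acetamidophenol reference
#'
#' Loads the shipped band list for the wavenumber-calibration standard
#' (4-acetamidophenol / paracetamol; ASTM E1840-style positions). The file
#' is plain CSV under `inst/extdata` and can be replaced by the user.
#'
#' @param path CSV with a `position` column (cm^-1, strictly increasing);
#'   defaults to the shipped list.
#' @return A tibble with columns `position` and `name`.
#' @examples
#' reference_peaks()
#' @export
reference_peaks <- function(path = system.file("extdata",
                                               "acetaminophenol_peaks.csv",
                                               package = "scraman")) {
  pk <- tibble::as_tibble(utils::read.csv(path))
  if (!"position" %in% names(pk)) {
    stop("peak table needs a `position` column", call. = FALSE)
  }
  pk <- dplyr::arrange(pk, .data$position)
  if (nrow(pk) < 3 || any(diff(pk$position) <= 0)) {
    stop("need >= 3 strictly increasing reference positions", call. = FALSE)
  }
  if (!"name" %in% names(pk)) pk$name <- as.character(pk$position)
  pk
}

# locate one peak near `pos`: windowed argmax + parabolic refinement.
# Returns NA when no convincing local maximum exists.
locate_peak <- function(wn, y, pos, window = 10, min_z = 5) {
  sel <- which(wn >= pos - window & wn <= pos + window)
  if (length(sel) < 3) return(NA_real_)
  i <- sel[which.max(y[sel])]
  if (i <= 1 || i >= length(y)) return(NA_real_)
  noise <- stats::mad(diff(y)) / sqrt(2)
  floor_level <- stats::median(y[sel])
  if (noise > 0 && (y[i] - floor_level) < min_z * noise) return(NA_real_)
  d2 <- y[i - 1] - 2 * y[i] + y[i + 1]
  delta <- if (d2 < 0) 0.5 * (y[i - 1] - y[i + 1]) / d2 else 0
  step <- (wn[i + 1] - wn[i - 1]) / 2
  wn[i] + max(-1, min(1, delta)) * step
}

#' Fit a wavenumber calibration against the reference standard
#'
#' Detects the measured position of each literature band of the reference
#' substance (windowed maximum with parabolic sub-channel refinement,
#' +/- `window` cm^-1 search) and fits a polynomial mapping measured ->
#' literature positions by least squares.
#'
#' @param reference a [raman_spectra] with one (despiked, baseline-corrected)
#'   spectrum of the reference substance, or a numeric vector together with
#'   `wavenumber`.
#' @param peaks reference band table from [reference_peaks()].
#' @param poly_degree polynomial degree of the correction (default 2:
#'   offset plus mild dispersion nonlinearity).
#' @param window half-width of the peak search window in cm^-1.
#' @param wavenumber axis for a vector `reference`.
#' @return A `raman_calibration` object with the fitted coefficients, the
#'   per-peak match table, `fit_rmse` (cm^-1) and `n_peaks_used`.
#' @examples
#' ref <- generate_reference(synthetic_config(axis_shift = 2))
#' fit_calibration(ref)
#' @export
fit_calibration <- function(reference, peaks = reference_peaks(),
                            poly_degree = 2, window = 10,
                            wavenumber = NULL) {
  if (inherits(reference, "raman_spectra")) {
    wn <- reference$wavenumber
    y <- reference$intensity[1, ]
  } else {
    wn <- wavenumber
    y <- as.numeric(reference)
  }
  measured <- vapply(peaks$position, function(p) locate_peak(wn, y, p, window),
                     numeric(1))
  ok <- is.finite(measured)
  if (sum(ok) < poly_degree + 1) {
    stop("only ", sum(ok), " reference peaks detected; need at least ",
         poly_degree + 1, " for degree ", poly_degree, call. = FALSE)
  }
  fit <- stats::lm(lit ~ stats::poly(meas, poly_degree, raw = TRUE),
                   data = data.frame(lit = peaks$position[ok],
                                     meas = measured[ok]))
  structure(
    list(poly_degree = poly_degree,
         coefficients = unname(stats::coef(fit)),
         fit_rmse = sqrt(mean(stats::residuals(fit)^2)),
         n_peaks_used = sum(ok),
         matched = tibble::tibble(name = peaks$name[ok],
                                  literature = peaks$position[ok],
                                  measured = measured[ok])),
    class = "raman_calibration"
  )
}

#' @export
print.raman_calibration <- function(x, ...) {
  cat("<raman_calibration> degree ", x$poly_degree, ", ", x$n_peaks_used,
      " peaks, rmse ", signif(x$fit_rmse, 3), " cm^-1\n", sep = "")
  invisible(x)
}

#' @export
tidy.raman_calibration <- function(x, ...) x$matched

#' @export
glance.raman_calibration <- function(x, ...) {
  tibble::tibble(poly_degree = x$poly_degree, fit_rmse = x$fit_rmse,
                 n_peaks_used = x$n_peaks_used)
}

#' Evaluate a calibration polynomial
#' @param object a `raman_calibration`.
#' @param newdata numeric measured wavenumbers.
#' @param ... ignored.
#' @return Corrected wavenumbers.
#' @export
predict.raman_calibration <- function(object, newdata, ...) {
  drop(outer(as.numeric(newdata), 0:object$poly_degree, `^`) %*%
         object$coefficients)
}

#' Apply a wavenumber calibration to a dataset
#'
#' Corrects the axis through the fitted polynomial and resamples every
#' spectrum onto `target` (uniform 1 cm^-1 grid inside the corrected range
#' by default) so downstream group means and PCA see one shared axis.
#'
#' @param ds a [raman_spectra] dataset.
#' @param model a `raman_calibration` from [fit_calibration()].
#' @param target optional target axis passed to [resample_to_axis()].
#' @return The calibrated, resampled [raman_spectra].
#' @examples
#' cfg <- synthetic_config(n_batches = 1, cells_per_mouse = 2, axis_shift = 2)
#' cal <- fit_calibration(generate_reference(cfg))
#' apply_calibration(generate_dataset(cfg), cal)
#' @export
apply_calibration <- function(ds, model, target = NULL) {
  corrected <- predict(model, ds$wavenumber)
  if (any(diff(corrected) <= 0)) {
    stop("calibration polynomial folds the axis back on itself",
         call. = FALSE)
  }
  ds2 <- raman_spectra(ds$intensity, corrected, ds$meta, ds$provenance)
  ds2 <- add_provenance(ds2, sprintf("calibrate[deg=%d,rmse=%.3g]",
                                     model$poly_degree, model$fit_rmse))
  resample_to_axis(ds2, target)
}
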