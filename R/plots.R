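#' Plot mean spectra by group
#'
#' Mean intensity per wavenumber with a +/- 1 SD ribbon, one panel-free
#' colour per group.
#'
#' @param object a [raman_spectra] dataset.
#' @param by metadata column to colour by (default `"group"`).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.raman_spectra <- function(object, by = "group", ...) {
  groups <- unique(object$meta[[by]])
  dat <- purrr::map_dfr(groups, function(g) {
    sel <- object[object$meta[[by]] == g]
    dplyr::mutate(mean_spectrum(sel), !!by := g)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$wavenumber, y = .data$mean,
                                    colour = .data[[by]],
                                    fill = .data[[by]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Normalized intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a difference spectrum with annotated peaks
#'
#' @param object a `raman_difference` from [difference_spectrum()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.raman_difference <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$wavenumber, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression("Raman shift (cm"^-1 * ")"),
      y = "Intensity difference (a.u.)",
      title = paste(object$label_a, "-", object$label_b)
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$peaks)) {
    p <- p + ggplot2::geom_point(
      data = object$peaks,
      ggplot2::aes(x = .data$position, y = .data$amplitude,
                   colour = .data$category)
    )
  }
  p
}

#' Plot discriminant scores of a cross-validation result
#'
#' LD score per spectrum against its index, coloured by predicted label
#' and shaped by true label (sick-side scores are negative by convention).
#' Falls back to per-fold balanced accuracies when no scores are available
#' (RF/SVM models).
#'
#' @param object a `raman_eval` from [kfold_cv()] or [batchwise_cv()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.raman_eval <- function(object, ...) {
  pr <- object$predictions
  if (all(is.na(pr$score))) {
    dat <- tidy.raman_eval(object)
    return(
      ggplot2::ggplot(dat, ggplot2::aes(x = .data$fold,
                                        y = .data$balanced_accuracy)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "Fold", y = "Balanced accuracy") +
        ggplot2::theme_minimal()
    )
  }
  pr$index <- seq_len(nrow(pr))
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$index, y = .data$score,
                                   colour = .data$predicted,
                                   shape = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(sham = "black", sick = "red")) +
    ggplot2::labs(x = "Spectrum index", y = "LD score") +
    ggplot2::theme_minimal()
}

#' Plot the LD loading of a fitted model
#'
#' @param model a `raman_model` with `classifier = "LDA"`.
#' @return A ggplot object; positive peaks mark sham-elevated bands,
#'   negative peaks sick-elevated bands.
#' @export
plot_ld_loading <- function(model) {
  ggplot2::ggplot(ld_loading(model),
                  ggplot2::aes(x = .data$wavenumber, y = .data$loading)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "LD loading (a.u.)") +
    ggplot2::theme_minimal()
}
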