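#' Confusion matrix over the sham/sick vocabulary
#'
#' @param truth,predicted label vectors of equal length.
#' @param labels class order; defaults to `c("sham", "sick")`.
#' @return An integer matrix, true classes in rows, predictions in columns.
#' @examples
#' confusion_matrix(c("sham", "sick"), c("sham", "sham"))
#' @export
confusion_matrix <- function(truth, predicted, labels = c("sham", "sick")) {
  stopifnot(length(truth) == length(predicted))
  tab <- table(factor(truth, levels = labels),
               factor(predicted, levels = labels))
  mat <- matrix(as.integer(tab), nrow = length(labels),
                dimnames = list(truth = labels, predicted = labels))
  mat
}

#' Balanced accuracy (mean per-class recall)
#'
#' The mean over true classes of the within-class fraction of correct
#' predictions — the "mean sensitivity". Insensitive to class imbalance.
#'
#' @param cm square confusion matrix, true classes in rows.
#' @return A fraction in `[0, 1]`.
#' @examples
#' balanced_accuracy(matrix(c(9, 2, 1, 3), 2))
#' @export
balanced_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  totals <- rowSums(cm)
  if (any(totals == 0)) {
    stop("every true class needs at least one item", call. = FALSE)
  }
  mean(diag(cm) / totals)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement and `p_e` the agreement expected from the row/column
#' marginals. Returns 0 when `p_e = 1` (degenerate one-cell matrix).
#'
#' @param cm square confusion matrix, true classes in rows.
#' @return A value in `[-1, 1]`.
#' @examples
#' cohens_kappa(matrix(c(40, 10, 10, 40), 2))
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Per-class sensitivity and specificity of a 2x2 confusion matrix
#' @param cm 2x2 confusion matrix, rows `sham`, `sick`.
#' @return A one-row tibble with `sensitivity` (sick recall),
#'   `specificity` (sham recall), `balanced_accuracy` and `cohens_kappa`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  tibble::tibble(
    sensitivity = cm["sick", "sick"] / sum(cm["sick", ]),
    specificity = cm["sham", "sham"] / sum(cm["sham", ]),
    balanced_accuracy = balanced_accuracy(cm),
    cohens_kappa = cohens_kappa(cm)
  )
}

#' Animal-level majority vote
#'
#' Collapses spectrum-level predictions to one label per mouse: the label
#' carried by the majority of that animal's spectra. Exact ties go to
#' `tie` (default `"sick"`, favouring sensitivity in a screening setting).
#' Mice with zero predictions are excluded with a warning.
#'
#' @param predictions tibble with columns `mouse_id`, `group` (true label)
#'   and `predicted` (spectrum-level label), e.g. from [predict()] output
#'   joined to metadata, or a `raman_eval` object's `predictions`.
#' @param tie label assigned on an exact tie.
#' @return A `raman_votes` object: list with `votes` (per-mouse tibble:
#'   `mouse_id`, `group`, `n_spectra`, `fraction_sick`, `vote`),
#'   `confusion` (mouse-level matrix) and `balanced_accuracy`.
#' @examples
#' pred <- tibble::tibble(mouse_id = rep(c("a", "b"), each = 10),
#'                        group = rep(c("sham", "sick"), each = 10),
#'                        predicted = rep(c("sham", "sick"), each = 10))
#' majority_vote(pred)
#' @export
majority_vote <- function(predictions, tie = "sick") {
  if (inherits(predictions, "raman_eval")) {
    predictions <- predictions$predictions
  }
  need <- c("mouse_id", "group", "predicted")
  stopifnot(all(need %in% names(predictions)))
  predictions <- dplyr::filter(predictions, !is.na(.data$predicted))
  if (nrow(predictions) == 0) {
    stop("no predictions to vote on", call. = FALSE)
  }
  votes <- predictions |>
    dplyr::group_by(.data$mouse_id, .data$group) |>
    dplyr::summarise(
      n_spectra = dplyr::n(),
      fraction_sick = mean(.data$predicted == "sick"),
      .groups = "drop"
    ) |>
    dplyr::mutate(vote = dplyr::case_when(
      .data$fraction_sick > 0.5 ~ "sick",
      .data$fraction_sick < 0.5 ~ "sham",
      TRUE ~ tie
    ))
  cm <- confusion_matrix(votes$group, votes$vote)
  structure(list(votes = votes, confusion = cm,
                 balanced_accuracy = balanced_accuracy(cm), tie = tie),
            class = "raman_votes")
}

#' @export
print.raman_votes <- function(x, ...) {
  cat("<raman_votes> ", nrow(x$votes), " mice, majority-vote balanced accuracy ",
      signif(x$balanced_accuracy, 3), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.raman_votes <- function(x, ...) x$votes

#' @export
glance.raman_votes <- function(x, ...) {
  tibble::tibble(n_mice = nrow(x$votes),
                 majority_vote_balanced_accuracy = x$balanced_accuracy)
}
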