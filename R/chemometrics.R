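#' Aggregate spectra within strata
#'
#' Reduces shot noise and cell-to-cell variability by averaging disjoint
#' random groups of spectra drawn within a stratum. The stratum (the
#' "type" being aggregated) defaults to batch x mouse x group, so
#' aggregates never mix animals and cross-validation folds stay leakage
#' free. Within each stratum the spectra are randomly partitioned (seeded)
#' into `floor(n / group_size)` disjoint groups of exactly `group_size`;
#' each group is replaced by its channelwise mean and re-vector-normalized;
#' remainder spectra are discarded. Strata smaller than `group_size` are
#' dropped with a warning.
#'
#' @param ds a [raman_spectra] dataset (normally preprocessed).
#' @param group_size spectra per aggregate (e.g. 10 for a screening-mode
#'   sepsis model, 12 for an imaging-mode endotoxemia model).
#' @param stratum_keys metadata columns defining the stratum.
#' @param seed integer seed for the random partition.
#' @return The aggregated [raman_spectra]; metadata inherited from the
#'   stratum, `cell_id` set to `"aggregate"`.
#' @examples
#' rs <- generate_dataset(synthetic_config(n_batches = 1, cells_per_mouse = 25))
#' n_spectra(aggregate_spectra(preprocess(rs), group_size = 10))
#' @export
aggregate_spectra <- function(ds, group_size = 10,
                              stratum_keys = c("batch_id", "mouse_id",
                                               "group"),
                              seed = 1) {
  stopifnot(group_size >= 1)
  strata <- ds$meta |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratum_keys)))
  keys <- dplyr::group_keys(strata)
  rows <- dplyr::group_rows(strata)
  sizes <- lengths(rows)
  if (group_size > max(sizes)) {
    stop("group_size (", group_size, ") exceeds the largest stratum (",
         max(sizes), ")", call. = FALSE)
  }
  if (any(sizes < group_size)) {
    warning(sum(sizes < group_size),
            " strata smaller than group_size were dropped", call. = FALSE)
  }
  out_int <- list()
  out_meta <- list()
  withr::with_seed(seed, {
    for (g in seq_along(rows)) {
      n_groups <- sizes[g] %/% group_size
      if (n_groups == 0) next
      idx <- sample(strata$.row[rows[[g]]])
      proto <- ds$meta[idx[1], ]
      for (j in seq_len(n_groups)) {
        take <- idx[((j - 1) * group_size + 1):(j * group_size)]
        avg <- colMeans(ds$intensity[take, , drop = FALSE])
        out_int[[length(out_int) + 1L]] <- vector_normalize(avg)
        md <- proto
        md$spectrum_id <- paste0("agg_", g, "_", j)
        md$cell_id <- "aggregate"
        out_meta[[length(out_meta) + 1L]] <- md
      }
    }
  })
  out <- raman_spectra(do.call(rbind, out_int), ds$wavenumber,
                       dplyr::bind_rows(out_meta), ds$provenance)
  add_provenance(out, sprintf("aggregate[size=%d,seed=%d]", group_size, seed))
}

median_heuristic_gamma <- function(x) {
  n <- nrow(x)
  if (n > 200) x <- x[sample.int(n, 200), , drop = FALSE]
  d <- stats::dist(x)
  sigma <- stats::median(d[d > 0])
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  1 / (2 * sigma^2)
}

#' Fit a PCA-based classification model
#'
#' Mean-centres the training spectra (no per-channel scaling: spectra are
#' already vector-normalized), fits PCA, and passes the scores on the first
#' `n_pcs` components to the chosen classifier: linear discriminant
#' analysis (`"LDA"`), random forest (`"RF"`, 500 trees) or a support
#' vector machine (`"SVM"`, RBF kernel, C = 1, bandwidth from the median
#' pairwise-distance heuristic). For LDA the discriminant score sign is
#' fixed so the sick class mean is negative.
#'
#' @param train a [raman_spectra] training set with both classes present.
#' @param n_pcs number of principal components (must be < training size
#'   and <= number of channels).
#' @param classifier `"LDA"`, `"RF"` or `"SVM"`.
#' @param seed integer seed (consumed by the RF bootstrap; recorded
#'   regardless).
#' @return A `raman_model` object.
#' @examples
#' rs <- preprocess(generate_dataset(synthetic_config(n_batches = 2,
#'                                                    cells_per_mouse = 10)))
#' fit_model(rs, n_pcs = 5)
#' @export
fit_model <- function(train, n_pcs = 5, classifier = c("LDA", "RF", "SVM"),
                      seed = 1) {
  classifier <- match.arg(classifier)
  if (n_spectra(train) == 0) stop("empty training set", call. = FALSE)
  y <- factor(train$meta$group, levels = c("sham", "sick"))
  if (nlevels(droplevels(y)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (any(table(y) < 2)) {
    stop("need >= 2 training spectra per class", call. = FALSE)
  }
  if (n_pcs >= n_spectra(train) || n_pcs > n_channels(train)) {
    stop("n_pcs (", n_pcs, ") must be < number of training spectra (",
         n_spectra(train), ") and <= number of channels", call. = FALSE)
  }
  pca <- stats::prcomp(train$intensity, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  sign_flip <- 1
  fit <- switch(
    classifier,
    LDA = {
      f <- MASS::lda(scores, grouping = y)
      tr_sc <- stats::predict(f, scores)$x[, 1]
      if (mean(tr_sc[y == "sick"]) > mean(tr_sc[y == "sham"])) sign_flip <- -1
      f
    },
    RF = withr::with_seed(seed, randomForest::randomForest(
      x = scores, y = y, ntree = 500)),
    SVM = withr::with_seed(seed, e1071::svm(
      x = scores, y = y, kernel = "radial", cost = 1,
      gamma = median_heuristic_gamma(scores)))
  )
  model <- structure(
    list(wavenumber = train$wavenumber, pca_mean = pca$center,
         rotation = pca$rotation[, seq_len(n_pcs), drop = FALSE],
         n_pcs = n_pcs, classifier = classifier, fit = fit,
         classes = c("sham", "sick"), sign_flip = sign_flip, seed = seed),
    class = "raman_model"
  )
  tr_pred <- predict(model, train)
  model$train_balanced_accuracy <-
    balanced_accuracy(confusion_matrix(train$meta$group, tr_pred$predicted))
  model
}

#' @export
print.raman_model <- function(x, ...) {
  cat("<raman_model> PCA-", x$classifier, ", ", x$n_pcs,
      " PCs, training balanced accuracy ",
      signif(x$train_balanced_accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' @export
glance.raman_model <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, n_pcs = x$n_pcs,
                 train_balanced_accuracy = x$train_balanced_accuracy)
}

#' Predict class labels for new spectra
#'
#' Projects the spectra onto the model's PCA basis and applies the stored
#' classifier. For LDA a scalar discriminant score per spectrum is
#' returned, with the convention that sick-side scores are negative.
#'
#' @param object a `raman_model`.
#' @param newdata a [raman_spectra] on the model's wavenumber axis.
#' @param ... ignored.
#' @return A tibble: `spectrum_id`, metadata columns, `predicted`, and
#'   `score` (LDA only, otherwise `NA`).
#' @export
predict.raman_model <- function(object, newdata, ...) {
  if (n_spectra(newdata) == 0) stop("empty dataset", call. = FALSE)
  if (length(newdata$wavenumber) != length(object$wavenumber) ||
      max(abs(newdata$wavenumber - object$wavenumber)) > 1e-8) {
    stop("dataset axis does not match the model's training axis",
         call. = FALSE)
  }
  scores <- sweep(newdata$intensity, 2, object$pca_mean) %*% object$rotation
  out <- switch(
    object$classifier,
    LDA = {
      p <- stats::predict(object$fit, scores)
      tibble::tibble(predicted = as.character(p$class),
                     score = object$sign_flip * p$x[, 1])
    },
    RF = tibble::tibble(
      predicted = as.character(stats::predict(object$fit, scores)),
      score = NA_real_),
    SVM = tibble::tibble(
      predicted = as.character(stats::predict(object$fit, scores)),
      score = NA_real_)
  )
  dplyr::bind_cols(newdata$meta, out)
}

#' Discriminant loading in wavenumber space
#'
#' Back-projects the fitted LD direction through the PCA basis onto the
#' wavenumber axis. With the package's sign convention, positive loading
#' peaks mark bands elevated in sham (positive-scoring) spectra and
#' negative peaks mark bands elevated in sick spectra.
#'
#' @param model a `raman_model` with `classifier = "LDA"`.
#' @return A tibble with `wavenumber` and `loading`.
#' @export
ld_loading <- function(model) {
  if (model$classifier != "LDA") {
    stop("LD loadings are only defined for LDA models", call. = FALSE)
  }
  w <- drop(model$rotation %*% model$fit$scaling[, 1]) * model$sign_flip
  tibble::tibble(wavenumber = model$wavenumber, loading = w)
}

make_eval <- function(scheme, predictions, fold_cms) {
  cm <- confusion_matrix(predictions$group, predictions$predicted)
  votes <- majority_vote(predictions)
  structure(
    list(scheme = scheme, predictions = predictions, fold_confusions = fold_cms,
         confusion = cm, metrics = classification_metrics(cm), votes = votes,
         majority_vote_balanced_accuracy = votes$balanced_accuracy),
    class = "raman_eval"
  )
}

#' @export
print.raman_eval <- function(x, ...) {
  cat("<raman_eval> ", x$scheme, " (", length(x$fold_confusions),
      " folds, ", nrow(x$predictions), " spectra)\n", sep = "")
  print(x$confusion)
  m <- x$metrics
  cat("  balanced accuracy ", signif(m$balanced_accuracy, 3),
      ", kappa ", signif(m$cohens_kappa, 3),
      ", majority-vote BA ", signif(x$majority_vote_balanced_accuracy, 3),
      "\n", sep = "")
  invisible(x)
}

#' Per-fold metrics of a cross-validation result
#' @param x a `raman_eval`.
#' @param ... ignored.
#' @return A tibble with one row per fold.
#' @export
tidy.raman_eval <- function(x, ...) {
  purrr::imap_dfr(x$fold_confusions, function(cm, nm) {
    ok <- all(rowSums(cm) > 0)
    tibble::tibble(
      fold = nm, n = sum(cm),
      balanced_accuracy = if (ok) balanced_accuracy(cm) else NA_real_,
      cohens_kappa = cohens_kappa(cm)
    )
  })
}

#' Pooled metrics of a cross-validation result
#' @param x a `raman_eval`.
#' @param ... ignored.
#' @return A one-row tibble: sensitivity, specificity, balanced accuracy,
#'   Cohen's kappa, majority-vote balanced accuracy.
#' @export
glance.raman_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(scheme = x$scheme, n_folds = length(x$fold_confusions)),
    x$metrics,
    tibble::tibble(
      majority_vote_balanced_accuracy = x$majority_vote_balanced_accuracy)
  )
}

#' Stratified k-fold cross-validation
#'
#' Splits the spectra into `k` folds stratified by class (or, with
#' `by_mouse = TRUE`, assigns whole mice to folds so spectra of one animal
#' never straddle a split), refits PCA and the classifier on each training
#' split and predicts the held-out fold. Metrics are computed on the pooled
#' out-of-fold confusion matrix.
#'
#' @param ds a preprocessed (and typically aggregated) [raman_spectra].
#' @param k number of folds (default 10).
#' @param n_pcs,classifier,seed passed to [fit_model()]; `seed` also drives
#'   the fold assignment.
#' @param by_mouse group folds by `mouse_id` instead of stratifying by
#'   class at the spectrum level.
#' @return A `raman_eval` object.
#' @examples
#' rs <- preprocess(generate_dataset(synthetic_config(n_batches = 2,
#'                                                    cells_per_mouse = 10)))
#' glance(kfold_cv(rs, k = 5, n_pcs = 5))
#' @export
kfold_cv <- function(ds, k = 10, n_pcs = 5,
                     classifier = c("LDA", "RF", "SVM"), seed = 1,
                     by_mouse = FALSE) {
  classifier <- match.arg(classifier)
  n <- n_spectra(ds)
  if (k > n) stop("k (", k, ") exceeds the number of spectra (", n, ")",
                  call. = FALSE)
  fold <- integer(n)
  withr::with_seed(seed, {
    if (by_mouse) {
      mice <- unique(ds$meta$mouse_id)
      mf <- sample(rep_len(seq_len(k), length(mice)))
      fold <- mf[match(ds$meta$mouse_id, mice)]
    } else {
      for (cl in unique(ds$meta$group)) {
        idx <- which(ds$meta$group == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
  })
  preds <- vector("list", k)
  cms <- list()
  for (f in seq_len(k)) {
    train <- ds[fold != f]
    test <- ds[fold == f]
    if (n_spectra(test) == 0) next
    if (length(unique(train$meta$group)) < 2) {
      stop("fold ", f, " leaves a single-class training split; reduce k",
           call. = FALSE)
    }
    model <- fit_model(train, n_pcs = n_pcs, classifier = classifier,
                       seed = seed + f)
    p <- predict(model, test)
    p$fold <- f
    preds[[f]] <- p
    cms[[as.character(f)]] <- confusion_matrix(p$group, p$predicted)
  }
  make_eval(sprintf("%d-fold", k), dplyr::bind_rows(preds), cms)
}

#' Leave-one-batch-out cross-validation
#'
#' One fold per experimental batch: the held-out batch contributes no
#' spectra, no mice and no PCA-fitting data to its own training split, so
#' the estimate measures generalization across acquisition sessions.
#' Batches containing a single class are excluded from the fold rotation
#' with a warning (no model can be scored against them in a balanced way)
#' but still contribute to the training splits of the other folds.
#'
#' @param ds a preprocessed (and typically aggregated) [raman_spectra]
#'   spanning at least two batches.
#' @param n_pcs,classifier,seed passed to [fit_model()].
#' @return A `raman_eval` object.
#' @export
batchwise_cv <- function(ds, n_pcs = 5, classifier = c("LDA", "RF", "SVM"),
                         seed = 1) {
  classifier <- match.arg(classifier)
  batches <- unique(ds$meta$batch_id)
  if (length(batches) < 2) {
    stop("batchwise CV needs >= 2 batches", call. = FALSE)
  }
  eligible <- batches[vapply(batches, function(b) {
    length(unique(ds$meta$group[ds$meta$batch_id == b])) == 2
  }, logical(1))]
  if (length(setdiff(batches, eligible))) {
    warning("batches with a single class excluded from fold rotation: ",
            paste(setdiff(batches, eligible), collapse = ", "),
            call. = FALSE)
  }
  if (length(eligible) == 0) {
    stop("no batch contains both classes", call. = FALSE)
  }
  preds <- list()
  cms <- list()
  for (b in eligible) {
    train <- ds[ds$meta$batch_id != b]
    test <- ds[ds$meta$batch_id == b]
    model <- fit_model(train, n_pcs = n_pcs, classifier = classifier,
                       seed = seed)
    p <- predict(model, test)
    p$fold <- b
    preds[[b]] <- p
    cms[[b]] <- confusion_matrix(p$group, p$predicted)
  }
  make_eval("batchwise", dplyr::bind_rows(preds), cms)
}
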