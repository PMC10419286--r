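make_stratum <- function(n, mouse = "m1", group = "sham", batch = "b1",
                         nch = 30, seed = 5) {
  withr::with_seed(seed, {
    raman_spectra(matrix(abs(rnorm(n * nch, 10, 2)), n, nch),
                  seq(400, 400 + 5 * (nch - 1), by = 5),
                  tibble::tibble(spectrum_id = paste0(mouse, "_", seq_len(n)),
                                 batch_id = batch, mouse_id = mouse,
                                 group = group, model = "PCI",
                                 cell_id = paste0("c", seq_len(n))))
  })
}

test_that("aggregation partitions strata into floor(n/size) disjoint means", {
  ds <- make_stratum(25)
  agg <- aggregate_spectra(ds, group_size = 10, seed = 3)
  expect_equal(n_spectra(agg), 2)      # floor(25/10), 5 discarded
  expect_equal(unique(agg$meta$mouse_id), "m1")
  expect_equal(unique(agg$meta$cell_id), "aggregate")
  # same seed -> identical output; different seed -> different partition
  agg2 <- aggregate_spectra(ds, group_size = 10, seed = 3)
  expect_identical(agg$intensity, agg2$intensity)
})

test_that("group_size 1 re-normalizes but preserves the collection", {
  ds <- make_stratum(6)
  agg <- aggregate_spectra(ds, group_size = 1, seed = 1)
  expect_equal(n_spectra(agg), 6)
  norm_in <- ds$intensity / sqrt(rowSums(ds$intensity^2))
  expect_equal(sort(agg$intensity[, 1]), sort(norm_in[, 1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("aggregating identical copies returns the same spectrum", {
  base <- vector_normalize(abs(rnorm(30, 10, 2)))
  ds <- raman_spectra(matrix(rep(base, each = 12), 12, byrow = FALSE),
                      seq(400, 545, by = 5),
                      tibble::tibble(spectrum_id = paste0("s", 1:12),
                                     mouse_id = "m1", group = "sham"))
  ds$intensity <- matrix(base, 12, 30, byrow = TRUE)
  agg <- aggregate_spectra(ds, group_size = 4, seed = 9)
  for (i in seq_len(n_spectra(agg))) {
    expect_equal(agg$intensity[i, ], base, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("aggregation errors when group_size exceeds every stratum", {
  ds <- make_stratum(5)
  expect_error(aggregate_spectra(ds, group_size = 10), "largest stratum")
  both <- ds
  both$meta$mouse_id[4:5] <- "m2"
  both$meta$spectrum_id <- paste0("x", 1:5)
  expect_warning(aggregate_spectra(both, group_size = 3, seed = 1),
                 "dropped")
})

test_that("a separable synthetic set is perfectly fit and predicted by PCA-LDA", {
  pp <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 10)))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  model <- fit_model(agg, n_pcs = 5)
  expect_equal(model$train_balanced_accuracy, 1)
  pred <- predict(model, agg)
  expect_true(all(pred$predicted == agg$meta$group))
  # the sick class scores negative by convention
  expect_lt(mean(pred$score[pred$group == "sick"]), 0)
  expect_gt(mean(pred$score[pred$group == "sham"]), 0)
})

test_that("a spectrum at the sham class mean is predicted sham", {
  pp <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 10)))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  model <- fit_model(agg, n_pcs = 5)
  cm <- colMeans(agg$intensity[agg$meta$group == "sham", ])
  probe <- raman_spectra(matrix(cm, 1), agg$wavenumber,
                         tibble::tibble(spectrum_id = "probe"))
  expect_equal(predict(model, probe)$predicted, "sham")
})

test_that("model fitting enforces its contracts", {
  pp <- preprocess(generate_dataset(tiny_config()))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  sham_only <- agg[agg$meta$group == "sham"]
  expect_error(fit_model(sham_only, n_pcs = 3), "both classes")
  expect_error(fit_model(agg, n_pcs = n_spectra(agg) + 5), "n_pcs")
  model <- fit_model(agg, n_pcs = 3)
  expect_error(predict(model, agg[integer(0)]), "empty")
  shifted <- raman_spectra(agg$intensity, agg$wavenumber + 1, agg$meta)
  expect_error(predict(model, shifted), "axis")
})

test_that("RF and SVM classifiers train and predict through the same surface", {
  pp <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 10)))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  for (cls in c("RF", "SVM")) {
    m <- fit_model(agg, n_pcs = 5, classifier = cls, seed = 2)
    pred <- predict(m, agg)
    expect_gt(balanced_accuracy(confusion_matrix(pred$group,
                                                 pred$predicted)), 0.9)
    expect_true(all(is.na(pred$score)))
  }
})

test_that("leave-one-out bookkeeping pools every spectrum exactly once", {
  pp <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 10)))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  ds10 <- agg[1:10]
  ev <- kfold_cv(ds10, k = 10, n_pcs = 2, seed = 1)
  expect_equal(sum(ev$confusion), 10)
})

test_that("permuted labels drive cross-validated accuracy to chance", {
  pp <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 25)))
  agg <- aggregate_spectra(pp, group_size = 2, seed = 1)
  bas <- vapply(1:3, function(s) {
    null <- agg
    withr::with_seed(s, null$meta$group <- sample(null$meta$group))
    kfold_cv(null, k = 5, n_pcs = 5, seed = s)$metrics$balanced_accuracy
  }, numeric(1))
  expect_gt(mean(bas), 0.35)
  expect_lt(mean(bas), 0.65)
})

test_that("batchwise CV builds one fold per eligible batch without leakage", {
  pp <- preprocess(generate_dataset(synthetic_config(
    n_batches = 4, mice_per_group_per_batch = 2, cells_per_mouse = 10,
    axis_step = 4)))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  ev <- batchwise_cv(agg, n_pcs = 5, seed = 1)
  expect_equal(length(ev$fold_confusions), 4)
  expect_setequal(names(ev$fold_confusions), unique(agg$meta$batch_id))
  # content-hash leakage guard: test-batch spectra never train their fold
  for (b in names(ev$fold_confusions)) {
    test_hashes <- apply(agg$intensity[agg$meta$batch_id == b, ], 1,
                         rlang::hash)
    train_hashes <- apply(agg$intensity[agg$meta$batch_id != b, ], 1,
                          rlang::hash)
    expect_length(intersect(test_hashes, train_hashes), 0)
  }
})

test_that("single-class batches leave the fold rotation but stay in training", {
  pp <- preprocess(generate_dataset(tiny_config(n_batches = 3,
                                                cells_per_mouse = 10)))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  skewed <- agg
  drop <- skewed$meta$batch_id == "batch3" & skewed$meta$group == "sham"
  skewed <- skewed[!drop]
  expect_warning(ev <- batchwise_cv(skewed, n_pcs = 5, seed = 1), "batch3")
  expect_setequal(names(ev$fold_confusions), c("batch1", "batch2"))
  # batch3's sick spectra stay available to the other folds' training splits
  expect_equal(sum(ev$confusion), sum(skewed$meta$batch_id != "batch3"))
  expect_error(batchwise_cv(agg[agg$meta$batch_id == "batch1"]), "2 batches")
})

test_that("cross-validation is bit-for-bit reproducible under a fixed seed", {
  pp <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 10)))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  a <- kfold_cv(agg, k = 5, n_pcs = 5, seed = 17)
  b <- kfold_cv(agg, k = 5, n_pcs = 5, seed = 17)
  expect_identical(glance(a), glance(b))
  expect_identical(a$predictions$score, b$predictions$score)
  c1 <- batchwise_cv(agg, n_pcs = 5, seed = 17)
  c2 <- batchwise_cv(agg, n_pcs = 5, seed = 17)
  expect_identical(glance(c1), glance(c2))
})

test_that("the LD loading lives on the axis and flags the class-effect bands", {
  pp <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 15)))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  model <- fit_model(agg, n_pcs = 5)
  ld <- ld_loading(model)
  expect_equal(ld$wavenumber, agg$wavenumber)
  # sick-elevated nucleic-acid band at 1094: negative (sick-side) extremum
  sel <- ld$wavenumber >= 1050 & ld$wavenumber <= 1150
  pos <- ld$wavenumber[sel][which.min(ld$loading[sel])]
  expect_lt(abs(pos - 1094), 8)
  rf <- fit_model(agg, n_pcs = 5, classifier = "RF", seed = 1)
  expect_error(ld_loading(rf), "LDA")
})

test_that("identical classes give a loading at the noise floor", {
  pp <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 10,
                                                effect_scale = 0)))
  agg <- aggregate_spectra(pp, group_size = 5, seed = 1)
  m0 <- fit_model(agg, n_pcs = 5)
  pp1 <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 10)))
  agg1 <- aggregate_spectra(pp1, group_size = 5, seed = 1)
  m1 <- fit_model(agg1, n_pcs = 5)
  # projecting the loading onto the class-mean difference: the null model
  # carries no aligned structure
  d0 <- colMeans(agg$intensity[agg$meta$group == "sham", ]) -
    colMeans(agg$intensity[agg$meta$group == "sick", ])
  d1 <- colMeans(agg1$intensity[agg1$meta$group == "sham", ]) -
    colMeans(agg1$intensity[agg1$meta$group == "sick", ])
  a0 <- abs(sum(ld_loading(m0)$loading * d0)) /
    sqrt(sum(ld_loading(m0)$loading^2) * sum(d0^2))
  a1 <- abs(sum(ld_loading(m1)$loading * d1)) /
    sqrt(sum(ld_loading(m1)$loading^2) * sum(d1^2))
  expect_gt(a1, a0)
})

test_that("higher effect scale never hurts cross-validated accuracy", {
  bas <- vapply(c(0, 0.5, 1), function(es) {
    pp <- preprocess(generate_dataset(tiny_config(cells_per_mouse = 15,
                                                  effect_scale = es,
                                                  seed = 31)))
    agg <- aggregate_spectra(pp, group_size = 5, seed = 31)
    kfold_cv(agg, k = 5, n_pcs = 5, seed = 31)$metrics$balanced_accuracy
  }, numeric(1))
  expect_true(all(diff(bas) >= 0))
})
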