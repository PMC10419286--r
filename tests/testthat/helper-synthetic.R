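# small, fast generator configurations used across the suite
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_batches = 2, mice_per_group_per_batch = 2,
         cells_per_mouse = 5, axis_step = 4),
    list(...))
  do.call(synthetic_config, args)
}

# a tiny hand-built dataset: 3 spectra on a 5-channel axis
toy_spectra <- function() {
  raman_spectra(
    intensity = rbind(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), c(2, 2, 2, 2, 2)),
    wavenumber = c(400, 500, 600, 700, 800),
    meta = tibble::tibble(
      spectrum_id = c("s1", "s2", "s3"),
      batch_id = c("b1", "b1", "b2"),
      mouse_id = c("m1", "m2", "m3"),
      group = c("sham", "sick", "sham"),
      model = "PCI", cell_id = c("c1", "c2", "c3")
    )
  )
}

# independent brute-force metric oracles working from label vectors
labels_from_cm <- function(cm) {
  labs <- rownames(cm)
  truth <- c(); pred <- c()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    k <- cm[i, j]
    truth <- c(truth, rep(labs[i], k))
    pred <- c(pred, rep(labs[j], k))
  }
  list(truth = truth, pred = pred)
}

brute_balanced_accuracy <- function(cm) {
  v <- labels_from_cm(cm)
  mean(vapply(unique(v$truth), function(cl) {
    mean(v$pred[v$truth == cl] == cl)
  }, numeric(1)))
}

brute_kappa <- function(cm) {
  v <- labels_from_cm(cm)
  labs <- union(v$truth, v$pred)
  po <- mean(v$truth == v$pred)
  pe <- sum(vapply(labs, function(cl) {
    mean(v$truth == cl) * mean(v$pred == cl)
  }, numeric(1)))
  if (pe >= 1) 0 else (po - pe) / (1 - pe)
}
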