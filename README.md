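# scraman

Single-cell Raman chemometrics for immune-cell classification.

`scraman` implements a complete analysis pipeline for single-cell Raman
spectra of immune cells (e.g. splenic T-lymphocytes from murine sepsis and
endotoxemia models), for spectroscopists and computational biologists who
need to ask: *do the cells of sick and healthy animals differ chemically,
and can an animal be classified from its cells' spectra?*

The pipeline covers:

- **Preprocessing** — cosmic-spike removal (narrow-outlier detection
  against a running-median smooth, repaired by interpolation), SNIP
  baseline subtraction (iterative peak clipping, optionally in the
  log-log-square-root compressed domain), clipping to the fingerprint
  (400–1800 cm⁻¹) and CH-stretch (2800–3050 cm⁻¹) regions, and vector
  (unit L2) normalization.
- **Wavenumber calibration** against a 4-acetamidophenol reference:
  peak detection with sub-channel refinement, polynomial fit of measured →
  literature positions.
- **Chemometrics** — aggregation of spectra within batch × mouse × group
  strata, PCA followed by LDA / random forest / SVM on the first *k*
  component scores, stratified 10-fold and leave-one-batch-out
  cross-validation, balanced accuracy

  `BA = (sensitivity + specificity) / 2`

  Cohen's kappa `κ = (p_o − p_e) / (1 − p_e)`, animal-level majority
  voting, and LD loadings back-projected into wavenumber space.
- **Difference-spectrum profiling** — group mean spectra, sick − sham
  differences, signed peak detection, and annotation against a shipped
  catalogue of biochemical band assignments (nucleic acids, proteins,
  lipids, amino acids).
- **A synthetic-data generator** with full ground truth (clean signals,
  class templates, spike positions) emulating the hierarchical
  batch → mouse → cell → spectrum structure, so the entire pipeline is
  testable end to end with no external data.

## Worked example

```r
library(scraman)

# a synthetic sepsis-like study: 4 batches, 4 mice/group/batch, 50 cells
ds  <- generate_dataset(synthetic_config(seed = 1))
pp  <- preprocess(ds)                                # despike, SNIP, clip, normalize
agg <- aggregate_spectra(pp, group_size = 10, seed = 1)

kf <- kfold_cv(agg, k = 10, n_pcs = 5, seed = 1)
kf
#> <raman_eval> 10-fold (10 folds, 160 spectra)
#>       predicted
#> truth  sham sick
#>   sham   80    0
#>   sick    0   80
#>   balanced accuracy 1, kappa 1, majority-vote BA 1

bw <- batchwise_cv(agg, n_pcs = 5, seed = 1)
glance(bw)$balanced_accuracy
#> [1] 1

d <- difference_spectrum(pp, group == "sick", group == "sham")
subset(tidy(d), position > 1080 & position < 1110)
#> # A tibble: 1 × 6
#>   position amplitude prominence  sign category      band
#>      <dbl>     <dbl>      <dbl> <dbl> <chr>         <chr>
#> 1     1095    0.0108     0.0127     1 Nucleic Acids 1085-1106
```

The difference peak at ~1095 cm⁻¹ is the amplified nucleic-acid band the
generator plants in the sick class; its positive sign means it is elevated
in the first selection (sick). On this strong-effect synthetic design the
cross-validated balanced accuracy is 1.0 under both schemes; with the
effect turned off (`effect_scale = 0`) it falls to chance (~0.5).

`autoplot()` methods draw mean spectra, difference spectra and LD-score
plots; `tidy()`/`glance()` return tibbles for downstream use. The whole
chain can also be driven from one seeded configuration:

```r
res <- run_pipeline(run_config(seed = 1), out_dir = "run1")
res$metrics$kfold_balanced_accuracy
```

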