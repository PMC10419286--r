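---
title: "Methods: single-cell Raman preprocessing and chemometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell Raman preprocessing and chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scraman)
```

## The problem

Single-cell Raman spectroscopy records, for each cell, an inelastic light
scattering spectrum whose bands report on the cell's molecular makeup:
nucleic acids, proteins, lipids, amino acids. In an infection-model study
the question is whether immune cells (here: splenic T-lymphocytes) from
sick animals — bona fide polymicrobial sepsis ("PCI") or sterile
LPS-driven endotoxemia — differ chemically from sham controls, and whether
an *animal* can be classified from the spectra of its cells. The data are
hierarchical: experimental batches (acquisition days) contain mice,
mice contribute cells, and cells contribute one or more spectra. Batch
effects (laser power drift, alignment, substrate) are confounded with
biology unless validation respects the hierarchy.

`scraman` implements the full chain — preprocessing, wavenumber
calibration, PCA-based classification with batch-aware validation,
animal-level majority voting, and difference-spectrum profiling — plus a
synthetic generator with ground truth so every stage is testable without
access to instrument data.

## Preprocessing

Stages run in a fixed, logged order: **despike → baseline → calibrate →
clip → vector-normalize**. Normalizing after clipping is deliberate: the
excluded silent region carries no biology and must not influence the
spectrum's scale.

### Cosmic-spike removal

Cosmic rays hit the CCD as 1–2-channel spikes far above shot noise. A
channel is a spike candidate when its residual from a running-median
smooth (window `despike_window = 5` channels) exceeds
`despike_zscore_threshold = 8` times the MAD of the residuals; candidate
runs wider than `despike_max_width = 2` channels are *not* treated as
spikes, because real Raman bands are broad. Flagged channels are repaired
by linear interpolation across the flanking clean channels, and every
repair is reported. The detector is intentionally conservative: at the
default threshold the false-alarm rate on clean synthetic spectra is well
below 1% of channels, and unflagged channels pass through bit-identical.

### SNIP baseline

Fluorescence and substrate background are estimated by iterative peak
clipping: at half-window $p$ every channel is replaced by
$\min\{y_i, (y_{i-p}+y_{i+p})/2\}$, sweeping $p$ over
$1 \ldots m$ with `snip_max_halfwidth` $m = 60$ channels. The default
sweeps wide-to-narrow (`snip_decreasing = TRUE`), the low-artifact variant,
and runs in the log-log-square-root compressed domain
(`snip_lls = TRUE`), which protects strong bands on count-scaled data.
Two numerical facts matter:

- In the raw domain the clipping operator is *exactly* shift-equivariant
  (`baseline(x + c) = baseline(x) + c`) and leaves a straight-line
  baseline untouched; the test suite asserts both.
- The double-log compression is nonlinear, so under LLS these identities
  hold only approximately; on a steep linear ramp the low-intensity end
  can retain a bias of order 10% of the ramp range. On realistic curved
  fluorescence baselines the practical recovery is excellent (the class
  mean of corrected synthetic spectra correlates > 0.99 with the
  generator's clean templates), so LLS remains the default.

The window is defined in *channels*: at the 1 cm⁻¹ default grid the
maximum window spans 60 cm⁻¹, comfortably wider than the 6–30 cm⁻¹
cellular bands. On a coarser grid the same channel count covers more
wavenumbers and the baseline estimate becomes smoother; quantitative
recovery statements in the tests are therefore made at the 1 cm⁻¹ study
resolution.

### Clipping and normalization

Only the fingerprint (400–1800 cm⁻¹) and CH-stretch (2800–3050 cm⁻¹)
regions are retained, boundaries inclusive; the 1800–2800 cm⁻¹ silent
region of biological samples is discarded. Spectra are then scaled to
unit Euclidean norm, removing overall intensity differences (cell size,
focus, laser power) while preserving band ratios.

## Wavenumber calibration

Dispersive spectrometers drift day to day, so a reference substance
(4-acetamidophenol) is measured per acquisition day. For each literature
band position (shipped as an editable CSV) the measured peak is located by
a windowed maximum (±10 cm⁻¹) with parabolic sub-channel refinement; a
candidate is rejected unless it rises at least five noise standard
deviations above the local median, so an overwhelmed reference fails
loudly rather than silently. A degree-2 polynomial (offset plus mild
dispersion nonlinearity; degree is configurable) maps measured to
literature positions by least squares, and the dataset's axis is corrected
and resampled onto a uniform 1 cm⁻¹ grid by linear interpolation —
monotone, artifact-free, and exact for the linear features it is applied
to. Extrapolation beyond the recorded axis is refused. A fit needs at
least `degree + 1` matched peaks.

## Chemometrics

### Aggregation

Single-cell spectra are noisy; averaging random disjoint groups of
`group_size` spectra (10 by default; 12 suits denser imaging-mode data)
before modelling trades sample count for signal-to-noise. The "type"
within which spectra may be averaged is the batch × mouse × group stratum:
aggregates never mix animals, so downstream cross-validation cannot leak
a mouse's identity across folds through a shared average. The partition is
seeded, disjoint, and discards the remainder; strata smaller than the
group size are dropped with a warning.

### Models

PCA is fitted on mean-centred training spectra only — no per-channel
scaling, since vector-normalized spectra already share a scale and
variance scaling would distort band ratios. The scores of the first
`n_pcs` components (5 by default; more when the class effect is subtle)
feed one of three classifiers:

- **LDA** — the default; linear, interpretable via loadings.
- **RF** — 500 trees, seeded.
- **SVM** — RBF kernel, C = 1, bandwidth from the median
  pairwise-distance heuristic.

The discriminant score sign is fixed so that the sick class mean is
negative; consequently the LD loading — the discriminant direction
back-projected through the PCA basis into wavenumber space — shows
*negative* extrema at bands elevated in sick cells and positive extrema at
sham-elevated bands.

### Validation

Two schemes are provided. Stratified 10-fold CV (folds balanced by class
at the spectrum level; a `by_mouse` option assigns whole animals to folds
for the stricter reading) estimates within-distribution accuracy.
Leave-one-batch-out CV holds out an entire acquisition session — spectra,
mice, and PCA-fitting data — and measures generalization across days,
which batch effects make genuinely harder. Batches containing only one
class cannot be scored in a balanced way; they are excluded from the fold
rotation with a warning but still strengthen the training splits of other
folds. A content-hash check in the tests verifies that no test-batch
spectrum ever appears in its own training split.

Metrics are computed on the pooled out-of-fold confusion matrix: balanced
accuracy (mean per-class recall — insensitive to imbalance), sensitivity,
specificity, and Cohen's kappa. For symmetric balanced 2×2 tables kappa
reduces to `2·BA − 1`, a useful consistency check the suite asserts
exhaustively on small tables against a brute-force oracle.

### Majority voting

Each mouse receives the label of the majority of its spectrum-level
predictions; exact ties go to *sick* (a screening context favours
sensitivity; the rule is a documented argument). When spectrum-level
errors are roughly independent and the per-spectrum accuracy exceeds
chance, the vote concentrates exponentially: at ~0.75 balanced accuracy
and 100 spectra per animal the probability of misclassifying a mouse is
below 10⁻⁶. The voting test fixes exactly that scenario — a weak class
effect (`effect_scale = 0.3`), low animal-level jitter so errors are
approximately iid, 100 cells per mouse — and observes perfect mouse-level
votes across ten seeds while the spectrum-level accuracy averages ~0.75.
When animal-level heterogeneity dominates (large `mouse_sdlog`), errors
correlate within a mouse and the binomial argument fails; that regime is
deliberately outside the voting test's conditions.

## Difference spectra and band assignment

Group mean spectra are subtracted channelwise (sick − sham by
convention); the operation is antisymmetric and additive, both asserted as
properties. Peaks are local extrema of either sign whose prominence
exceeds 3× a robust noise scale; because the silent region is clipped
away, noise is estimated from the median absolute channel-to-channel
increment of the difference itself (scaled to a Gaussian sd), which is
insensitive to the broad real features. Detected peaks are annotated
against the shipped band catalogue — single positions and ranges mapped to
Nucleic Acids / Proteins / Lipids / Lipids and Proteins / Amino Acids —
matching the nearest band within ±5 cm⁻¹ (tolerance 0 means exact range
containment); equally close multi-category overlaps report all categories,
and anything else is `unassigned`.

## The synthetic generator

Each spectrum is built as

> Σ Gaussian bands × (class factor)^`effect_scale` × mouse jitter ×
> batch gain + baseline + noise + spikes

on a 350–3100 cm⁻¹ grid (1 cm⁻¹ default step). The band template follows
the catalogue: nucleic-acid bands at 785, 1094 and 1334 cm⁻¹ elevated in
sick cells; amino-acid bands at 527 and 641 cm⁻¹ and the 1754 cm⁻¹ lipid
ester band elevated in sham — the directions reported for septic
T-lymphocytes. Fingerprint bands are 6–16 cm⁻¹ wide, CH-stretch bands
20–28 cm⁻¹. Hierarchy and nuisance terms:

- lognormal per-mouse, per-band amplitude jitter (`mouse_sdlog = 0.06`) —
  biological heterogeneity between animals, which is what makes
  leave-one-batch-out meaningfully harder than pooled k-fold;
- lognormal per-batch gain and a correlated baseline tilt
  (`batch_effect_sd = 0.05`) — acquisition-session drift;
- a per-spectrum quadratic baseline plus a broad random Gaussian hump
  (scale 400 counts) — fluorescence;
- white Gaussian noise (sd 4 counts) and Poisson-placed cosmic spikes
  (rate 0.3/spectrum, 50× noise, 1–2 channels wide).

The default design — 4 batches × 4 mice per group per batch × 50 cells —
mirrors a screening-mode experiment at a desk-scale size and separates
cleanly after aggregation by 10. Ground truth (clean signals, class
templates, spike positions) ships with every dataset, enabling
known-truth oracles throughout the suite.

What the generator does **not** emulate: instrument line-shape and
spectral response, fluorescence photobleaching kinetics, within-cell
spatial structure of imaging-mode data, correlated (non-white) noise, and
real biological band covariance. Passing tests therefore demonstrate that
the algorithms recover what the generative model plants — not that real
sepsis data would reach any particular accuracy.

## Problem sizes and numerical choices

The suite and the acceptance script run on: the 1600-spectrum default
design (strong effect and null), a 200-spectrum spike-recovery set, a
1200-spectrum weak-effect voting scenario on a 4 cm⁻¹ grid (ten seeds),
and exhaustive small-table metric grids. Tolerances worth noting: axis
equality for prediction is enforced at 10⁻⁸ cm⁻¹; shift-equivariance of
raw-domain SNIP at 10⁻⁶ relative; metric agreement with brute force at
10⁻¹²; kappa is defined as 0 when the expected agreement is 1; empty
selections, single-class training sets, extrapolating resampling and
fold-back calibration polynomials are errors, not silent repairs.

## Known limitations

- The despiking "k-means" variant used by some commercial pipelines is
  unpublished; the two-stage MAD-threshold detector here reproduces its
  intent (narrow outlier removal) with documented, testable parameters.
- SNIP iteration depth and LLS bias are resolution-dependent; the window
  is specified in channels, so users on non-1 cm⁻¹ grids should rescale
  `snip_max_halfwidth`.
- Aggregation discards remainder spectra; with small strata this loses
  data, and `group_size` should be reduced accordingly.
- The package makes no claim about the accuracies attainable on real
  instrument data; all quantitative statements are about the synthetic
  conditions above.
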