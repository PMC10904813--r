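---
title: "Detecting data drift in imaging cohorts: models, designs, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting data drift in imaging cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A classifier deployed on a stream of medical images is usually monitored
through its aggregate performance (macro AUROC, F1, and so on). That signal
requires gold labels, which are often late, expensive, or themselves
affected by changes in the population — and, more fundamentally, many
clinically meaningful changes in the input distribution leave aggregate
discrimination untouched. `mmdrift` implements the complementary,
label-free approach: reduce each image to a low-dimensional representation
and test whether a recent *target* sample of these representations is
distributed like an earlier *source* sample.

Three representations are supported:

* **TAE** — bottleneck features of a trained autoencoder, mean-pooled over
  spatial positions to one vector per image (covariate-shift detector on
  the image marginal);
* **BBSD** — the deployed classifier's predicted per-label probabilities,
  used as a black-box reduction (no gold labels consumed);
* **TAE + BBSD** — each block z-scored per dimension on the source sample
  and concatenated.

Source and target are compared with the unbiased estimator of the squared
maximum mean discrepancy (MMD²) under an RBF kernel,

$$\widehat{\mathrm{MMD}^2_u} =
\frac{1}{n(n-1)}\sum_{i \ne j} k(x_i, x_j) +
\frac{1}{m(m-1)}\sum_{i \ne j} k(y_i, y_j) -
\frac{2}{nm}\sum_{i,j} k(x_i, y_j),$$

with $k(a,b) = \exp(-\lVert a-b\rVert^2 / 2\sigma^2)$. Significance comes
from a permutation test: group labels are shuffled across the pooled
sample, the statistic recomputed, and
$p = (1 + \#\{\text{permuted} \ge \text{observed}\}) / (N + 1)$.

## Numerical choices in the test

* **Bandwidth.** $\sigma$ is the median of the pairwise Euclidean
  distances over the pooled sample (excluding self-distances). A zero
  median falls back to the smallest positive distance; a fully degenerate
  pool returns bandwidth 1 together with $p = 1$ and a warning. The
  bandwidth is estimated once on the pooled sample and held fixed across
  permutations, which keeps the permutation null exchangeable.
* **Add-one p-values.** The observed statistic is counted into its own
  null, so $p \in [1/(N+1), 1]$ and $p = 0$ is impossible. Default $N$ is
  1000 for experiments; the test suite and the acceptance script use 200,
  which resolves $p$ well below the 0.05 decision threshold.
* **Rejection direction.** Rejection is for large MMD² only. The
  population MMD is non-negative, and a permutation test on a distance
  statistic is directionless in *which way* the distributions differ, so a
  one-sided rejection region is the coherent reading of a "two-sided"
  distributional comparison.
* **No multiplicity correction** is applied anywhere: a monitoring stream
  is a sequence of individually interpreted tests, and correction policy
  is the deployer's choice.
* The unbiased estimator may be negative (e.g. identical two-point
  samples give $k(a,b) - 1 \le 0$); tests cover these closed forms, and an
  explicit double-loop oracle pins the vectorized implementation to
  $10^{-10}$.

## The synthetic cohort generator

Nothing in the drift machinery depends on real radiographs, but its
premises do: covariates must shift the image marginal, and labels must add
learnable structure that is independent of the covariates. The generator
enforces exactly these premises:

* Each record carries demographic covariates (sex, institution, ICU flag,
  patient class, device, view) and an age drawn from a two-component adult
  mixture (floored to years, truncated to [18, 100]); sex, age, and
  institution are constant within a patient.
* Fourteen binary pathology labels are drawn with configurable base
  prevalences; an odds-multiplier list induces label correlations (label
  *i* present multiplies the odds of label *j*), so enrichment of one
  pathology drags correlated pathologies along — the situation the
  non-target shift audit is built to catalogue.
* Images (default 32×32) are a fixed two-ellipse "lung field" template
  plus **global** per-covariate intensity offsets, a fixed per-device
  pattern, an age-scaled border, **localized** additive Gaussian blobs per
  positive label, and pixel noise. Because covariate effects are global
  and label effects local and additive, the label-conditional image
  component is covariate-independent by construction, which the tests
  assert by differencing renders of the same record under two covariate
  settings.
* Every record draws from a private RNG stream keyed by `(seed,
  study_id)`, so subsetting a cohort never changes the surviving records'
  draws.

**Effect sizes.** The covariate image effects are free parameters with no
real-data anchor; they were chosen once so that sex-enrichment drifts
between δ = 0.05 and δ = 0.5 span the range from statistically
undetectable to reliably detectable at sample sizes of 500–2000 per group
(sex offset 0.02, institution 0.03, ICU 0.05, patient class up to 0.035,
device pattern amplitude 0.03, age border 0.06, label blobs 0.30, noise sd
0.08, all in units of pixel intensity on [0, 1]). With these defaults a
δ = 0.4 drift at n = 500 sits near the detection boundary while n = 2000
detects it essentially always — the regime in which the sample-size
dependence of drift detection is visible at all. What passing tests on
this generator show is that the *pipeline* behaves as designed under known
shifts; they cannot show that real radiograph populations produce
representations with comparable separability.

The temporal regime change emulates the arrival of a novel bilateral
pattern: after an onset date, records acquire a `novel_pattern` flag with
probability ramping linearly to a peak prevalence (default 0.3 over 30
days), non-novel encounters are dropped with a volume-suppression
probability (default 0.3), and flagged images are re-rendered with a
bilateral effect (amplitude 0.10, calibrated so the pattern is immediately
visible to the kernel test while leaving macro AUROC within 0.05 of its
baseline — the regime the methodology is designed to expose). The novel
pattern is deliberately *not*
one of the fourteen labels, and the classifier is never trained on it.

## The reducers

Production radiograph pipelines use large pretrained backbones (ResNet- or
DenseNet-class networks on 224×224 images). At 32×32 with purely synthetic
structure that capacity is unnecessary, so the package uses two small,
fully configurable models trained with full-batch Adam written in plain
matrix algebra:

* the **autoencoder** is one convolutional layer with kernel = stride = 8
  (a patch-wise linear map into 32 latent channels) and a linear decoder;
  its 4×4×32 bottleneck map is mean-pooled to the TAE vector, mirroring
  the pooled-bottleneck design at desk scale. Training must beat an
  untrained-weights baseline on held-out images or the model is flagged.
* the **classifier** is a dense network with one tanh hidden layer (24
  units) and 14 sigmoid heads, early-stopped on a validation split that is
  patient-disjoint by construction (hash of `patient_id`). Single-class
  labels in the training split are flagged rather than fatal. On default
  synthetic cohorts it reaches held-out macro AUROC ≈ 0.98, comfortably
  above the 0.8 sanity gate the experiments assume.

Both models are deterministic given their seeds. The model-training pool
is split from the evaluation pool at the patient level and never reused
downstream.

## Sampling designs

**Enrichment (categorical drift).** The source is a stratified random
sample over the joint cells of sex × institution × ICU × age group ×
patient class, with largest-remainder allocation (cells emptied by the
cohort are dropped with renormalization; `round()`'s half-even convention
fixes the enriched-count arithmetic, e.g. 500 at δ = 0.10 → 450 + 50).
The target sample draws a `1 − δ` fraction the same way and a `δ` fraction
exclusively from the target category, excluding the source's records *and
patients*. The expected enriched-level proportion is
$(1-\delta)p_0 + \delta$, which the tests verify at n = 4000.

**Rolling windows (temporal drift).** Evaluations step through the
calendar (default every 30 days); at each step the target window covers
one 30-day bucket, the source window an earlier bucket separated by a
one-bucket buffer, 500 records sampled from each. A window short of its
sample size is widened by whole buckets — backwards for the source,
forwards for the target — and an evaluation that cannot be filled even
then is skipped with a logged gap. Realized window extents travel in each
pair's provenance.

**Null calibration.** The stratified enrichment design at δ = 0 is
*conservative*: largest-remainder allocation pins both samples' cell
compositions, so the permutation null (which lets compositions vary)
overestimates the statistic's spread and p-values pile up near 1. This is
a real property of the design, not a bug; the package therefore measures
pipeline false-alarm rates with `run_null_calibration()`, which draws two
patient-disjoint uniform samples (one record per patient) — the
exchangeable no-drift analogue of a window comparison. Under that design
the measured false-alarm rate at p ≤ 0.05 is ≈ 0.05–0.07, and the δ = 0
enrichment cells are asserted to be no worse than α (conservative
direction allowed).

## Performance monitoring baseline

`compute_metrics()` reports per-class AUROC (midrank ties; verified
against an all-pairs concordance oracle), precision, recall, F1 at a
configurable threshold (default 0.5), and the Brier score, with unweighted
macro averages over non-excluded classes. A class is excluded when its
gold column or its thresholded predictions are single-class (minimum count
configurable). `sampling_bias_fp_ratio()` reproduces the worked
sampled-evaluation example: per-group alert rates re-scaled to a
population mix, returning `100 · Σ incorrect / Σ correct`; with counts
M: 83/7 and F: 8/2 it gives 9.89% under a 90/10 male mix and 23.12% under
the flipped mix (full precision is reported; the printed 9.8%/23% values
round differently than these reconstructions).

## Experiment harnesses and problem sizes

`run_magnitude_sweep()`, `run_sample_size_sweep()`, and
`run_temporal_monitor()` orchestrate the three designs over any subset of
methods, fanning one master seed out to cohort, training, repetition, and
permutation streams so reruns are exact. Summaries report mean ± 1 sd of
the p-value per cell and the detection rate at α = 0.05 (the reference
line used throughout; configurable).

The shipped tests and the acceptance script run the designs at desk
scale: an ~12,600-record imaging cohort (25% reserved for model
training), 20 repetitions per cell, 200 permutations per test, n = 1000
for the magnitude sweep (δ ∈ {0.05, 0.2, 0.5}), n ∈ {500, 2000} at
δ = 0.4 for the size sweep, n = 2000 at δ = 0.5 for the AUROC-stability
check, and 200 repetitions of the null calibration at n = 200 per group.
A separate ~19,500-record metadata-only cohort backs the n = 4000
composition checks. These sizes were chosen so the full suite runs on a
laptop-class single core in well under half an hour while leaving every
comparison at least 3 Monte-Carlo standard errors of resolution.

## Known limitations

* The generator's images are caricatures: global covariate offsets and
  additive label blobs. Real covariate effects are nonlinear and
  entangled with pathology appearance; detectability thresholds measured
  here do not transfer to real data.
* The classifier and autoencoder are far smaller than deployed networks;
  BBSD's sensitivity profile depends on the classifier's inductive
  biases, so method rankings (e.g. TAE + BBSD vs BBSD alone) should be
  re-measured per deployment rather than taken from the synthetic study.
* Alternative two-sample tests (Kolmogorov–Smirnov per dimension,
  chi-squared on binned outputs) and alternative reductions (PCA) are out
  of scope; the batch interface accepts any feature matrices, which is
  where such extensions would plug in.
* `p`-values from overlapping rolling evaluations are serially dependent;
  the package reports them uncorrected and leaves alerting policy (e.g.
  consecutive-detection rules) to the deployer.
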