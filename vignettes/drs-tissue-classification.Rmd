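---
title: "Methods: DRS tissue classification with landmark/slope features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DRS tissue classification with landmark/slope features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diffuse reflectance spectroscopy (DRS) injects broadband light into tissue
through a fiber-optic probe and measures the diffusely reflected fraction as
a function of wavelength. Because absorption by blood, water, lipid and
collagen differs between tumor and benign tissue, the shape of the
reflectance spectrum carries diagnostic information. In the setting this
package targets — margin assessment during prostate cancer surgery — each
patient contributes a handful of point measurements, each labeled tumor or
healthy where the measurement location could be matched to histology with
confidence, and the task is to classify the tissue type of a measurement
from its spectrum while generalizing to *unseen patients*.

`drsclassify` implements that workflow end to end and pairs it with a
synthetic cohort generator, so every stage is testable without access to
clinical measurements (none are publicly deposited).

## The measurement model

Two spectrometers cover the visible (200–1160 nm) and near-infrared
(900–1750 nm) ranges. Raw counts $S(\lambda)$ are calibrated against a white
Spectralon reference $W(\lambda)$ and a dark reference $D(\lambda)$:

$$R(\lambda) = \frac{S(\lambda) - D(\lambda)}{W(\lambda) - D(\lambda)}.$$

The instrument literature names the references but rarely prints the
equation; this ratio is the universal DRS convention, and it makes
calibration invariant to a common rescaling of all counts.

The two calibrated channels are stitched into one continuous spectrum on
400–1600 nm. Vendor software does not document how it reconciles the
channels where they overlap, so the package declares a policy rather than
reconstructing one: a **linear cross-fade** over the overlap (VIS weight
falling 1 → 0), which guarantees continuity without inventing gain matching;
a hard cut at a splice wavelength is available as an alternative. All
spectra are then resampled by linear interpolation onto the canonical grid
of 400–1600 nm at 1 nm — exactly 1201 wavelengths, endpoint-inclusive. No
smoothing happens at this stage.

## Preprocessing: standard normal variate

Probe contact pressure, source drift and coupling efficiency scale and
offset spectra in ways unrelated to tissue type. Standard normal variate
(SNV) normalization removes both by z-scoring each spectrum against itself:

$$z(\lambda) = \frac{x(\lambda) - \bar{x}}{s_x},$$

with the sample SD ($n-1$ divisor, so `snv_normalize(c(1,2,3))` is exactly
`c(-1, 0, 1)`). SNV is idempotent and invariant to positive affine
transforms of the input; a constant spectrum is an error, not a silent
zero-division. SNV is applied over the full 400–1600 nm range, after
stitching and resampling and before any feature computation — normalization
is fixed as the first analysis step; whether the original analysis trimmed
the range first is not stated, and the full range is the simpler default.

## Features: landmarks and slopes

With 1201 wavelengths and on the order of 150 labeled measurements, a
classifier on raw wavelengths would overfit. The feature set is therefore
derived from the **class mean spectra**: per-wavelength mean ± SD of the SNV
spectra for tumor and for healthy tissue.

* **Landmarks** are local minima/maxima of each class mean spectrum. The
  mean spectrum is smoothed with a centered moving average (default full
  width 15 nm) and interior extrema are kept if their topographic prominence
  is at least 0.05 SNV units. Both parameters are undocumented in the
  original analysis; the defaults were chosen once so that the major
  water/lipid band extrema survive the generator's instrument noise while
  sub-noise ripples are suppressed, and both are config keys. Endpoints are
  never reported as extrema.
* **Slope pairs** connect landmark wavelengths: every pair of consecutive
  landmarks (union over both classes, deduplicated), plus each minimum
  paired with its flanking maxima. Pairs closer than 20 nm are dropped to
  avoid near-degenerate difference quotients. This pairing rule is a
  declared reconstruction of "slopes between wavelength pairs", not a
  verbatim reproduction of any published pairing.

Each measurement is then summarized by the SNV intensity at every landmark
and the per-nm difference quotient over every pair. Intensities at the
extrema are themselves features — an assumption, flagged here, since the
original description does not say whether they were. Feature extraction is
deterministic: same input, same table, bit for bit.

## Feature selection: ReliefF

ReliefF is implemented from scratch (it is the methodological core of the
selection stage). For each instance $i$, its $k$ nearest hits (same class)
and $k$ nearest misses (other class) under Manhattan distance on
min–max-scaled features update each feature weight:

$$W_f \leftarrow W_f - \sum_{h \in H_i} \frac{\mathrm{diff}(f,i,h)}{mk}
              + \sum_{m' \in M_i} \frac{\mathrm{diff}(f,i,m')}{mk},
\qquad \mathrm{diff}(f,a,b) = \frac{|x_{af} - x_{bf}|}{\max_f - \min_f}.$$

Choices the original analysis leaves open, fixed here for reproducibility:

* all instances are used ($m = n$; no sampling), so ranking is
  deterministic — seeded subsampling is available but off by default;
* $k = 10$ neighbors (standard ReliefF practice), clamped to
  (smallest class − 1) with a warning on small tables;
* neighbor-distance ties break by row order; min–max scaling uses the table
  the ranker is given (which, inside the pipeline, is always a training
  fold);
* constant features receive weight exactly 0;
* equal weights in top-$k$ selection break by feature declaration order.

The top 20 features by weight are selected; the restricted feature spec
preserves declaration order. The test suite pins the implementation to an
exhaustive brute-force oracle on all small tables (up to 8 rows × 4
features) at 1e-12.

## Classification and evaluation

* **Patient-wise 70/30 split**: patients, not measurements, are partitioned
  (`round(0.7 · n_patients)` in training), so no patient contributes to both
  sides. If a class is entirely absent from either side the split is
  redrawn from a derived seed, with a retry cap.
* **Linear SVM**: hinge loss with L2 penalty (libsvm via `e1071`), features
  standardized with training statistics stored in the model. The cost C is
  chosen from {0.01, 0.1, 1, 10, 100} by mean accuracy under tenfold CV
  stratified by class (folds clamped to the smallest class on tiny inputs),
  then the model is refit on the full training set. The C grid and the
  stratification are this package's choices; only "tenfold" is given.
  Decision values are oriented so larger means more tumor-like.
* **Metrics**: tumor is the positive class. The headline sensitivity,
  specificity and accuracy are computed at the classifier's native threshold
  (decision value 0); the ROC curve is built threshold-free by sweeping the
  decision value, AUC is the trapezoidal area (equal to pairwise concordance
  with ties counted ½), and the Youden-optimal cutoff
  (argmax of sensitivity + specificity − 1) is reported alongside. Which
  threshold produced the originally reported operating point is not stated,
  so both are exposed.
* **Ten iterations**: the whole chain — split, class profiles, feature
  derivation, ReliefF, top-20, SVM — is re-run per iteration on the training
  side only. Re-deriving features per split is the leakage-safe reading of
  "ten iterations" (the alternative, freezing features once on all data,
  would let test patients influence feature choice). Metrics are aggregated
  as mean and sample SD (n−1); a single iteration reports SD 0 by
  convention. An exact-equality test verifies that deleting all
  test-patient rows before training changes nothing in the fitted model.

Every stage seeds its randomness from the base seed through a fixed counter
scheme (`base_seed + 1000·iteration` for the split, +1 for fold
assignment), so individual iterations are reproducible in isolation and
identical configs produce byte-identical report files.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not prostate optics:

* **Chromophores**: fixed, version-stamped absorption templates built from
  Gaussians at the familiar band positions (hemoglobin Soret/Q bands,
  water 970/1190/1450 nm, lipid 930/1210 nm, a broad collagen term), in
  relative units. These are qualitative stand-ins, not literature extinction
  coefficients.
* **Forward model**: a diffusion-style surrogate
  $R = S\,e^{-\mu_{\mathrm{eff}}\rho}/\rho^2$ with
  $\mu_{\mathrm{eff}} = \sqrt{3\mu_a(\mu_a + \mu_s')}$,
  $\mu_s' = a(\lambda/500)^{-b}$ and $\rho$ = 2 mm. It is smooth, positive,
  monotone-decreasing in absorption, and sufficient to carry chromophore
  band structure into spectra; it is explicitly not a quantitative photon
  transport model.
* **Cohort shape**: 59 patients, 5–10 measurements each, tumor probability
  0.53 per location, and a label-certainty of 152/542 ≈ 0.28 — only that
  fraction of measurements keeps its tumor/healthy label, the rest become
  `unlabeled` (the histology-correlation filter's data consequence). Truth
  is retained separately for every measurement.
* **Variability**: a patient-level log-normal effect on concentrations and
  scattering (relative SD 0.10) shared by all of a patient's measurements,
  within-patient jitter (SD 0.05), multiplicative instrument noise
  (SD 0.02) and small additive noise (SD 5e-4). These magnitudes were fixed
  once as plausible for a contact-probe system dominated by biological
  rather than shot noise.
* **Class contrast**: tumor compositions get more blood and water and less
  lipid, scaled by δ ∈ [0, 1]; δ = 0 makes the class-generating
  distributions identical and δ = 1 (the default, the "easy" preset) gives
  clearly separable classes. The *direction* of the contrast is a generator
  assumption, not a claim about prostate biology — the original study
  publishes no compositional contrast, which is also why the package's
  acceptance checks are recovery/null properties on synthetic data and
  never the clinical study's real-data metrics.
* An optional two-channel mode renders each spectrum on separate VIS/NIR
  grids with independent noise and runs it through stitching and resampling,
  exercising the I/O path end to end; the default emits canonical-grid
  spectra directly.

What passing tests show — and what they do not: the pipeline recovers
separable structure (mean AUC ≥ 0.9 at δ = 1 over ten iterations), is
calibrated at chance when no signal exists, and does not leak test patients.
They do not show that real prostate spectra are separable, that the
chromophore templates match tissue, or that the reported clinical
performance is reproduced — no real data ship with the package.

One measurement-design note: the null calibration is estimated over 20
*independent* δ = 0 cohorts (one split each) rather than 20 resplits of a
single cohort. A single finite cohort carries a chance label–spectra
association that persists across resplits, making resplit AUCs correlated
and the single-cohort mean a poor estimate of the generator-level null;
independent replication estimates it with a standard error of about 0.02.

## Numerical choices and degenerate inputs

* Linear interpolation everywhere a grid change happens; refusal (not
  extrapolation) outside the source span.
* SNV tolerances: output mean and SD are within 1e-10 of 0 and 1.
* Calibration fails loudly, naming the wavelength, if $W - D \le 0$.
* A constant feature column is an error for the SVM (after standardization
  it is undefined) but weight-0 for ReliefF (defined by diff ≡ 0).
* `select_top_k` with k above the candidate count is an error at the
  operation level; the pipeline clamps with a warning instead, so a
  "select-all" configuration still completes.
* Percentages in dataset summaries are round-half-up to integers, matching
  80/152 → 53% and 72/152 → 47%.

## Problem sizes

The shipped analysis and the acceptance script use the default cohort
(59 patients, ≈ 450 measurements, ≈ 125 labeled), ten evaluation
iterations, and 20 independent null cohorts; the property tests use smaller
cohorts (20–30 patients) and exhaustive oracles on tables of at most 8 × 4.
These sizes were chosen so the full study, including its repeated-
evaluation loops, reruns from scratch in about a minute on one CPU.

## Interfaces

The package's functions plus the numbered scripts under `analysis/`
(simulate → preprocess → featurize/rank → evaluate) are the interface; each
script is a thin narrative driver over exported functions and writes its
tables under `results/`. There is no separate command-line binary: the
orchestration surface (`pipeline_config()`, `run_pipeline()`,
`summarize_dataset()`) covers configuration, logging and reproducible
reports, and unknown config keys are rejected to guard against typos.

## Known limitations

* The forward model and chromophore templates are qualitative; absolute
  reflectance scales and band depths are not physical.
* The generator assigns tissue class per location independently; real
  cohorts have patient-level tumor burden correlation, which would make
  patient-wise splitting matter even more than it does here.
* ReliefF is the binary Kononenko variant; multi-class prior weighting,
  RReliefF and SURF-family variants are out of scope.
* Gleason-grade structure, heterogeneous measurement volumes and
  probe-pressure effects are not modeled.
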