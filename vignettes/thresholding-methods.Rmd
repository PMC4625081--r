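---
title: "Methods: thresholding, empty voxels and contrast classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thresholding, empty voxels and contrast classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, numerical choices and design decisions
behind `threshsim`, in the spirit of a methods section: what each stage
computes, which knobs matter, what the synthetic cohort does and does not
emulate, and where the design was genuinely open.

## 1. The question the pipeline answers

Given two statistical maps of the same task contrast built from *disjoint*
groups of subjects, an unthresholded query map should be more similar to
the equivalent contrast's map than to any other contrast's map. The
pipeline measures how that retrieval accuracy behaves as the target maps
are increasingly thresholded (`|Z| > T` two-sided, or `Z > T`
positive-only) and as the empty voxels created by thresholding are handled
by either complete case analysis (CCA: intersection of usable voxels) or
single-value imputation (SVI: empties replaced by 0 over the whole brain
mask).

## 2. Synthetic cohort model

Subject `s` in family `f(s)` contributes, for contrast `c`, the volume

    y(s, c, v) = A · template_c(v) + F_{f(s),c}(v) + E_{s,c}(v) + B(v)

* `template_c` — a sum of smooth Gaussian blobs, 5 positive and 4 negative,
  unit peak height, blob σ = min(grid)/10 voxels, centers kept at least
  2.2 σ apart inside a central ellipsoid. Keeping peaks from stacking
  bounds the template near ±1, which in turn bounds the group-level Z
  range (see §4).
* `F` (family field, sd `family_noise_sd` = 0.15) — drawn once per family
  per contrast and shared by its members. This is what makes between-group
  relatedness dangerous: two groups sharing a family would share signal
  that is not contrast-specific, which is exactly what the family-disjoint
  subsampling constraint protects against.
* `E` (subject field, sd `subject_noise_sd` = 0.4) — independent per
  subject per contrast.
* `B` (shared background, sd `background_shared_sd` = 0.05) — one field per
  cohort, common to *all* subjects and contrasts. It survives group
  averaging identically in every map, giving statistically unrelated
  contrasts a faint common structure, so near-zero voxels behave as
  correlated noise between otherwise independent maps — the mechanism by
  which light thresholding can *help* classification.

All random fields are Gaussian white noise smoothed to
`smoothing_fwhm_vox` = 3 voxels FWHM and standardized by the exact
per-voxel sd of the smoothing operator (the row 2-norms of the separable
convolution matrices). The standardization matters: normalizing by the
field's global empirical sd leaves interior voxels with substantially
smaller pointwise sd than edge voxels (truncated, renormalized kernels),
which inflates t-statistics at interior signal peaks by a factor of 2–3
and distorts the Z range.

Within each task, one pair of contrasts is engineered to share a fraction
(≥ `overlap_frac` = 0.5 of the smaller support; 5 of 9 blobs by default) of
its blob layout. This emulates redundant task contrasts — a condition and
its generalization — and is the designed source of "hard" confusions.

**What the generator does not emulate:** acquisition and preprocessing
artifacts, spatially varying smoothness, surface data, kinship beyond
binary family membership, non-Gaussian noise, and inter-subject anatomical
variability. Passing tests therefore demonstrate the behavior of the
*analysis machinery* under a controlled signal model, not a quantitative
prediction for any real dataset.

## 3. Scale of the default study

The emulated large-cohort design has 47 contrasts, 465 subjects, groups
of N = 46 on a 2 mm whole-brain grid, and 500 subsamples. The
package defaults use a desk-scale twin: 12 contrasts over 4 tasks, a 24³
grid with an ellipsoidal "brain" of ≈ 4,300 voxels, 48 subjects in 24
families of two, groups of N = 12, and 20 subsamples with thresholds
Z = 0…6. These sizes keep a complete experiment (and the test suite) in
the tens of seconds on a single CPU while preserving every qualitative
feature: near-ceiling accuracy at light thresholds, graceful degradation,
collapse to chance when thresholds empty the maps, and overlap-pair
confusions. The full-size design is accepted by the same configuration
surface (`experiment_config()` with the full-size values) and is simply
a larger computation.

## 4. Calibration of the effect amplitude

`effect_amplitude` = 0.85 with total subject-level noise sd
√(0.4² + 0.15²) ≈ 0.43 puts the expected peak t around
`0.85/0.43 · √12 ≈ 6.9` at df = 11, i.e. typical peak Z ≈ 4–4.5 after the
t→Z transform's tail compression. This was chosen as a realistic
scaled-down analogue of large-cohort group maps (whose Z range reached
about ±12 at N = 46): strong focal signal, clearly separable from the
unit-variance Z noise floor, with both directionalities achieving ≥ 0.9
retrieval accuracy at light thresholds. Note that the *maximum* observed
|Z| over a whole run (hundreds of maps × thousands of voxels) is an
extreme order statistic and lands noticeably higher (≈ 6.2–6.7), driven by
voxels whose sample variance happens to be small at df = 11; this is a
genuine property of one-sample t maps at modest group size, not a
generator artifact.

## 5. Group statistics and the t→Z transform

The one-sample t-test is parametric (`t = x̄/(s/√n)`, unbiased s). Large-cohort
analyses of this kind often compute the same statistic through a
permutation tool; since only the t-statistic image is consumed downstream,
the parametric computation is identical where it matters.
Zero-variance voxels cannot carry a finite t; they become *empty* rather
than ±∞ (infinities would poison every later correlation), and are counted
on the map object.

The transform `Z = Φ⁻¹(F_t(t; df))` is evaluated tail-wise in
log-probability space: for `t ≤ 0`, `qnorm(pt(t, df, log.p = TRUE),
log.p = TRUE)`; for `t > 0` symmetrically through the upper tail with a
sign flip. This makes the transform exactly antisymmetric and finite for
any finite t: a naive linear-space composition loses tail precision and
saturates to +Inf once the upper-tail probability rounds to 1 in double
precision (near t ≈ 13 at df = 45), squarely inside the range real group
maps reach.

## 6. Thresholding semantics

* Strict inequalities: a value exactly at ±T is removed. The retention
  wording "above +T, below −T" reads most naturally as strict; nothing
  downstream is sensitive to the measure-zero boundary, but the choice is
  fixed and documented.
* `T = 0`, two-sided: a no-op ("no threshold applied"), exact zeros
  included.
* Positive-only at any level, including `T = 0`, removes every value ≤ 0:
  directionality means *eliminating negative values entirely*, independent
  of level, and exact zeros are never part of a positive-only comparison.
  This is deliberately not a no-op at `T = 0` and is the one place the two
  directions differ at the same level.
* Thresholds compose (`T₁` then `T₂ ≥ T₁` equals `T₂`), are idempotent,
  and may only increase on a given map.

## 7. Similarity and the direction filter

One genuinely open design point: when the analysis is positive-only,
should the *unthresholded query* also drop its negatives, or only the
target? The package applies the positive-only filter to **both** images
before building the comparison set, treating directionality as a property
of the analysis rather than of one image — a researcher who "only cares
about activations" ignores deactivations on both sides. The choice is
localized in `build_comparison_set(direction =)` and easy to revisit.

Scoring uses `stats::cor` (Pearson; Spearman via average ranks). A pair is
*not comparable* (`NA`) when no voxels survive, fewer than three usable
voxels remain, or either vector has zero variance. Not-comparable scores
rank below every real score in prediction; an all-not-comparable row
yields *no prediction*, which counts as incorrect and is tallied in a
dedicated `<none>` confusion column so confusion row sums stay equal to
the number of subsamples.

Prediction ties on |score| (measure-zero with real data) break to the
lowest column index and are flagged; determinism matters more than the
specific rule.

## 8. Aggregation

Per condition (threshold × direction × strategy × metric): overall
accuracy is the mean of subsample accuracies with a 95% interval
`mean ± 1.96·sd/√n` (normal approximation on the subsample distribution;
with hundreds of folds the approximation is innocuous, and at the
package's 20-subsample scale the interval is reported as what it is). A
single subsample yields a degenerate interval plus a warning. Per-contrast
means/sds are computed over the 0/1 correctness indicators, so the
confusion-matrix diagonal exactly recovers the overall accuracy.

## 9. Reproducibility plumbing

All randomness flows from one master seed through fixed substreams
(`substream_seed`, a Lehmer-style mixing of seed and stream counter):
stream 0 → cohort generation (templates, then maps), stream `10 + 8s + r` →
subsample `s` group draw, attempt `r`. Serial, resumed, or staged
executions therefore agree exactly; the staged disk pipeline writes
float64 NIfTI and reproduces the in-memory run bit-for-bit (this is
tested). Group draws that cannot complete (cohorts where group A's
families exhaust the unrelated pool) raise a typed error; the pipeline
retries with a fresh substream a bounded number of times.

Empty voxels are `NA` in memory; NIfTI exports write 0 at empties with the
mask and a JSON sidecar (df, threshold) alongside, and imports restore
zeros-inside-mask as empty. Since Z values are continuous, an exact 0 in a
real map occurs with probability zero; the round-trip is exact in
practice and exercised in the tests.

## 10. Known limitations

* Relatives *within* a group are permitted; only between-group relatedness
  is excluded (matching the subsampling procedure being emulated).
  "Related" means "same family identifier" — no kinship degrees.
* The CCA comparison is asymmetric (intersection against a thresholded
  target with an unthresholded query); comparing two thresholded maps is
  out of scope, as is any cluster-extent/RFT thresholding, additional
  similarity metrics, or statistical comparison between conditions.
* SVI's comparison universe is the brain mask, not the rectangular grid;
  mask size is the ceiling on comparable voxels.
* At df = 11 the maps' extreme |Z| values are dominated by
  sample-variance fluctuations (§4); analyses that depend on the absolute
  Z range at small n should keep this in mind.
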