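---
title: "Wavelet texture analysis of tumor ROIs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet texture analysis of tumor ROIs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavetex)
```

## The problem

After neoadjuvant chemoradiotherapy for locally advanced rectal cancer,
a fraction of patients reach pathological complete response (pCR): no
residual tumor cells in the resected specimen.  Identifying those
patients from post-treatment MRI would let them avoid surgery (the
"watch and wait" strategy).  The texture of the residual lesion on a
T2-weighted slice carries information that the radiologic eye does not
quantify; `wavetex` implements a radiomics pipeline that turns a
grayscale tumor region of interest (ROI) into wavelet-texture features
and a discriminant score (DS) that thresholds into a pCR prediction.

The pipeline has five stages:

1. **Decomposition** (`wavedec2()`): a separable 2D discrete wavelet
   transform of the rectangular ROI crop, repeated to three dyadic
   levels, with ten mother wavelets (`db1`, `db2`, `db4`, `coif1`,
   `coif5`, `bior2.2`, `bior3.3`, `sym2`, `sym3`, `sym5`).
2. **Feature summarisation** (`extract_features()`): at each level the
   approximation (low-pass) coefficients are summarised by mean,
   median, signed maximum and sample SD, giving
   10 wavelets x 3 levels x 4 statistics = 120 named features such as
   `db2dec2sd` or `bior33dec1max`.
3. **Univariate screening** (`univariate_screen()`): per-feature
   normality checks (Lilliefors) and two-sample t-tests between the
   pCR and non-pCR groups.  Screening is descriptive; it does not gate
   the multivariate stage.
4. **Discriminant modelling** (`stepwise_select()`, `fit_lda()`): a
   two-class Fisher linear discriminant on a small feature subset,
   reported as an affine DS formula, with the decision cutoff chosen
   by ROC analysis (Youden's J).
5. **Validation** (`loocv()`): leave-one-out cross-validation with the
   coefficients and cutoff refit in every fold.

## The discriminant score

For selected features $x_1, \dots, x_p$ the score is the affine map

$$\mathrm{DS} = c + \sum_{j=1}^{p} \beta_j x_j,
\qquad \beta \propto S_w^{-1}(\bar{x}_{\mathrm{pCR}} - \bar{x}_{\mathrm{non}}),$$

where $S_w$ is the pooled within-class covariance.  The coefficients
are scaled to the *unstandardised canonical* convention of mainstream
discriminant software: the pooled within-class variance of DS is 1 and
the weighted grand-mean DS is 0.  This convention was chosen because
the reference model shipped with the package (see below) has a cutoff
near zero and roughly symmetric group-mean scores, which is the
signature of centred canonical scores.  Classification is
$\mathrm{DS} \ge \text{cutoff} \Rightarrow$ pCR; a score exactly at the
cutoff is classified positive (an arbitrary but documented tie rule).

A pre-fitted four-variable reference model for pCR prediction ships as
a fixture (`ds_reference_model()`), with constant $-541.1768021$,
coefficients $+0.2456044$ (`db2dec2sd`), $+1.1709781$
(`bior33dec1max`), $+0.0399379$ (`bior33dec3mn`), $-0.0691719$
(`sym5dec2mn`) and cutoff $-0.6299$.  The source that reports this
model prints the `sym5dec2mn` slope with a positive sign in its
coefficient table but subtracts the term in the score formula; only
the negative sign places the published group-mean feature vectors on
opposite sides of the published cutoff, so the package uses the
negative sign and reads the table as reporting magnitudes.

## Numerical conventions of the transform

Neither boundary handling nor downsampling phase is standardised
across DWT implementations, and coefficient *statistics* (especially
maxima and SDs) are sensitive to both.  `wavetex` fixes every
convention by bit-level agreement with the PyWavelets reference
implementation in `symmetric` mode, enforced by oracle-equality tests:

* **extension**: half-point symmetric reflection (the edge sample is
  repeated), bouncing repeatedly when a filter is longer than the
  signal — so the 30-tap `coif5` bank is usable on small ROI crops;
* **phase**: after full convolution the output keeps samples
  `flen, flen + 2, ...` (0-based);
* **size**: each subband dimension is `floor((n + flen - 1) / 2)`;
* **filter taps**: double-precision literals from the standard
  published tables, stored in the package (no runtime dependency on
  the oracle library).

Perfect reconstruction (`waverec2()`, max abs error < 1e-8) and, for
the orthogonal families, energy conservation are verified in the test
suite; the inverse transform exists only for those tests.

Statistics are computed over the **approximation** subband at each
level rather than the detail subbands.  The magnitudes of the
published feature tables fix this choice: a level-1 approximation
maximum of a bright 8-bit image sits near $2 \times 255$ and a level-2
maximum near $4 \times 255$ (the 2D DC gain is 2 per level), matching
the reported values of roughly 429 and 866, whereas detail subbands
centre on zero.  A `subband = "detail"` switch pools the three detail
subbands per level for sensitivity analysis.

The rectangular bounding box of the ROI mask is what gets decomposed;
the irregular mask is not applied to coefficients, because subband
coefficients have no one-to-one pixel mapping.  This is a documented
divergence risk against workflows that zero out non-mask pixels.

## Statistical choices

**t-test variant.**  The default is Welch (unequal variances,
Satterthwaite df).  The published group summaries for `db1dec2max`
(866.46 +/- 1.86, n = 7 vs 860.27 +/- 5.51, n = 15) reproduce the
published p = 0.001 under Welch (p ~= 0.00095) but not under the
pooled form (p ~= 0.0096); the pooled variant remains available.

**Normality.**  The KS test uses the Lilliefors correction because the
normal parameters are estimated from the sample.  Its p-value
approximation is slightly liberal (about 6% rejection at nominal 5% in
the calibration test), which is inherent to the approximation, not to
the pipeline.

**Multiplicity.**  No multiple-testing correction is applied in the
screening stage because the original analysis applied none; a
Bonferroni-adjusted column is appended to the report as an extra,
clearly not part of the decision path.  Zero-variance features are
reported as untestable rather than silently dropped.

**Stepwise selection.**  Forward selection minimising Wilks' lambda
with the classic thresholds (F-to-enter 3.84, F-to-remove 2.71) is the
default, because the reference analysis mode uses them.  Users should
know its failure mode at radiomics dimensions: with ~120 candidates
and ~22 subjects the largest *null* partial F exceeds 3.84 almost
surely, so noise features chain-enter up to the feature cap.
`alpha_enter` adds a Bonferroni-adjusted entry gate
(`qf(1 - alpha/m, 1, n - 2 - p)`) that holds the family-wise false
entry rate and keeps null selections empty, at a documented cost: the
partial F of a feature that duplicates an already-selected
discriminant direction saturates near $n - 2 - p$ — right at the
adjusted critical value — so redundant true features are admitted
conservatively.  At these sample sizes that trade-off is fundamental,
not tunable: no F-threshold rule can simultaneously keep 120-candidate
null selections empty and reliably admit a third or fourth mutually
redundant true feature whose partial F is capped near the null
maximum.

**ROC cutoff.**  Candidate thresholds are the midpoints between
adjacent sorted unique scores plus infinite sentinels; the cutoff
maximises Youden's J, with ties broken toward the candidate nearest
the pooled score median.  Optimality is certified against a
brute-force sweep in the tests.  AUC uses the Mann-Whitney pair-count
identity (ties count one half).

**Leave-one-out.**  By default the feature set is held fixed across
folds and only the coefficients and the Youden cutoff are refit — the
leave-one-out classification convention of mainstream discriminant
software, and the reading most consistent with the reference analysis.
`refit_selection = TRUE` reruns the stepwise search inside every fold;
it is the statistically stricter variant, and the honest one whenever
selection itself is part of the claimed procedure.  A fold whose
selection comes back empty predicts its training majority class.

## The synthetic cohort generator

No imaging data accompany the study this package operationalises, so
all pipeline-level tests run on `generate_cohort()`: two classes of
tumor-like textured 8-bit images.  Each image is a Gaussian random
field (white noise smoothed with a separable Gaussian kernel at
`correlation_length` pixels, rescaled to `contrast` gray levels) plus
`base_intensity` and pixel noise, multiplied by a soft elliptical
tumor support and quantised.  Defaults mirror the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_pos` / `n_neg` | 7 / 15 | the study's arm sizes |
| `image_size` | 64 px | a typical ROI crop scale |
| `base_intensity` | 120 (negative class) | mid-gray lesion interior |
| `contrast` | 30 | smooth texture amplitude, gray levels |
| `correlation_length` | 3 px | texture grain |
| `noise_sd` | 10 | acquisition-like pixel noise |
| `effect` | 1 (= +30 base gray levels) | class separation |

The positive class interpolates from the negative-class parameters
toward `params_pos` via `effect`; `effect = 0` gives exchangeable
classes (verified by permutation), and the default `effect = 1` is a
deliberately *strong* separation — tens of pooled SDs on the coarse
approximation-mean features — because it stands in for the published
perfectly-separated cohort.  Clipping at the 8-bit boundaries stays
below 1% at the defaults.  Per-subject child seeds are derived by
integer mixing (`seed * 1009 + index * 9973 mod 2^31 - 1`) so cohorts
are reproducible across platforms.

`generate_feature_cohort()` bypasses imaging and draws the 120-feature
table directly: unit-variance features, a designated informative
subset (default: the four reference-model features) mean-shifted by
`effect` within-class SDs in the positive class, optionally with
exchangeable correlation `rho` through a subject-level factor.  The
default `rho = 0` keeps the null features independent — the clean
calibration condition for false-positive-rate and selection tests;
redundancy studies should set `rho` explicitly.

What the generator does *not* emulate: MRI physics (bias fields,
Rician noise), anatomically shaped lesions, inter-observer ROI
variability, and the feature-feature correlation structure of real
wavelet features (which is far stronger than exchangeable).  Passing
tests on synthetic cohorts therefore demonstrate that the *algorithms*
behave as specified, not that the clinical discrimination result
generalises; the published 100% accuracy is echoed here only as a
scaled-down synthetic analogue.

## Degenerate inputs and tie rules

* images must be at least 8 x 8 after ROI cropping; empty masks and
  sub-minimal crops are errors;
* `coefficient_stats()` refuses fewer than 2 values (SD undefined);
* constant features are reported as untestable in screening, and a
  singular pooled covariance in `fit_lda()` is an error naming the
  collinear features;
* classification at exactly the cutoff is positive;
* duplicate subject identifiers are integrity errors, not warnings.

## Problem sizes in the test suite

The suite exercises reconstruction and oracle equality on images up to
64 x 64 across all ten wavelets, pipeline runs on 7-vs-15 and 5-vs-8
cohorts, and simulation-based calibration checks on 8-50 seeded
replicates per property — sizes chosen to make every distributional
claim testable in seconds while keeping the cohort geometry identical
to the study conditions.

## Known limitations

* The approximation-subband reading of the feature definitions is
  inferred from published magnitudes, not stated by the source; the
  detail-pooled mode exists to probe that uncertainty.
* BMP support covers uncompressed 8-bit palette and 24-bit files only.
* The discriminant stage is strictly two-class and linear; no
  regularisation is provided, so feature subsets must stay below
  `n - 2`.
* Stepwise selection at radiomics dimensions overfits by construction
  (see above); the package exposes the honest knobs rather than hiding
  the problem.
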