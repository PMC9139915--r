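---
title: "Methods: PET radiomics pipelines for predicting non-response to chemoradiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomics pipelines for predicting non-response to chemoradiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling approach

About a quarter to a third of esophageal cancer patients do not respond to
neoadjuvant chemoradiotherapy (nCRT), and identifying them before treatment
would open the door to earlier surgery or alternative therapy. Intratumoral
heterogeneity — spatial variation in glucose metabolism visible on a baseline
^18^F-FDG PET scan — is a candidate imaging marker of non-response.
`petromics` implements an end-to-end radiomics machine-learning pipeline for
this prediction task:

1. **Input**: an SUV-calibrated 3-D PET volume per patient, a binary tumor
   mask (VOI), clinical covariates (histology, clinical T- and N-stage), and
   a binary non-response label (the minority class, prevalence roughly 29%).
2. **Harmonized geometry**: image and VOI are resampled to a 2 mm isotropic
   grid by trilinear interpolation; interpolated mask values are rounded to
   binary.
3. **Features**: 143 radiomic features per VOI — morphology, first-order SUV
   statistics (including the conventional metrics volume, SUVmax, SUVpeak,
   SUVmean, TLG), intensity-volume histogram, discretized intensity
   histogram, and textural features from four matrix families (GLCM, GLRLM,
   GLSZM, NGTDM). Textural features are computed on volumes discretized as
   $X_{d} = \lfloor X_{SUV} / 0.25 \rfloor + 1$ and accumulated in three
   dimensions with 26-voxel connectivity into a *single merged* matrix per
   family (not direction-wise matrices averaged afterwards).
4. **Normalization** (training rows only): features with sample skewness
   $|g_1| \le 0.5$ are robustly scaled, $(x - \mathrm{median}) / \mathrm{IQR}$;
   more skewed features get a maximum-likelihood Yeo-Johnson power transform
   followed by standardization.
5. **Selection cascade**: (i) removal of features with poor multivendor
   reproducibility (ICC < 0.6, from an editable manifest), (ii) removal of
   radiomic features with $|\rho| > 0.8$ Pearson correlation against a
   conventional metric, then per strategy (iii) optional PCA keeping the
   minimal component set explaining > 95% of variance, (iv) one of six
   univariable filters (logistic, ANOVA, Fisher score, Relief, T-score, Gini)
   with a tuned cut, and (v) optional LASSO. The $\{PCA\} \times \{6
   \text{ filters}\} \times \{LASSO\}$ grid yields 24 strategies.
6. **Classifiers**: logistic regression, SVM, random forest, Gaussian naive
   Bayes, a single-hidden-layer neural network, and k-nearest neighbours —
   144 pipelines in total — compared by mean average precision (AP) over a
   stratified 2-fold cross-validation repeated 5 times on the 70% training
   subset, with the full cascade refit inside every fold.
7. **Aggregation and evaluation**: the best pipeline and a soft-voting
   ensemble (arithmetic mean of the top-10 pipelines' positive-class
   probabilities) are refit on the training subset and scored once on the
   held-out 30% by AP and ROC AUC. AP is the right headline metric for this
   imbalanced problem: a chance classifier's AP equals the positive
   prevalence, so any value above the test prevalence indicates signal.

## Why average precision

With ~29% positives, accuracy and even AUC can look respectable while the
model is useless for the clinical question, which concerns the positive
(non-responding) minority. AP integrates precision over recall, ignores true
negatives, and has an interpretable chance level (the prevalence). We use
step interpolation over descending unique-score thresholds; tied scores form
one threshold group, which removes any dependence on sample order.

## The synthetic cohort generator

The patient data behind the modelled study are not publicly deposited, so the
package ships a generator that emulates the cohort's structure and makes
every stage testable:

* **Cohort frame**: 199 patients by default; exactly
  `round(n * prevalence)` = 57 non-responders allocated count-then-shuffle
  (deterministic prevalence makes split arithmetic exact for every seed).
  Clinical covariates are allocated per class by largest-remainder counts
  from the per-class marginal tables of the emulated cohort and shuffled
  within class, so at n = 199 the subgroup sizes are deterministic:
  177 adenocarcinomas and 161 clinical T3–4a patients (38 T1–T2).
* **Images**: ellipsoidal tumors (radius 8–20 mm, per-axis eccentricity
  0.8–1.2) filled with a base SUV drawn from 4–12, on a near-zero background,
  at the PET acquisition spacing 3.1819 × 3.1819 × 2 mm, with additive
  Gaussian noise (SD 0.3 SUV).
* **Planted effect**: intratumoral texture is a Gaussian random field
  (white noise smoothed with a Gaussian kernel whose width is the correlation
  length), the simplest controllable heterogeneity that GLCM-family features
  detect. One unit of `heterogeneity_effect` adds 0.35 SUV to the field
  amplitude and 1.5 mm to the correlation length of non-responder tumors
  (responders: 0.4 SUV, 3 mm). At effect 0 the label is independent of the
  images.
* **Tabular twin**: `generate_feature_table()` skips image synthesis and
  draws standardized features from correlated blocks (shared-factor
  construction) with an optional class mean shift on a subset of features.
  It emulates the strong feature redundancy of a radiomic matrix and is what
  the multi-seed calibration studies use.

**What the generator does *not* emulate** — and therefore what passing tests
do and do not show. It contains no scanner physics, reconstruction protocol,
partial-volume effect, delineation uncertainty, or biological covariate
structure; its planted effect is a stand-in mechanism, not a claim about
non-responder biology, and at the default effect size it is far *stronger*
than any clinical radiomic signal (the demonstration workflow reaches
near-perfect test AP, whereas the clinical study this emulates reported a
test AP of 0.66 against a 0.28 baseline). Green tests therefore certify that
the machinery is correct — exact arithmetic, oracle-equivalent texture
matrices, leak-free validation, chance-level behaviour under the null — not
that any particular clinical performance is attainable.

## Numerical choices

* **Mask rounding**: interpolated VOI values of exactly 0.5 round *up*; an
  inclusive boundary avoids dropping thin structures.
* **Discretization** is fixed-bin-size anchored at SUV 0 (not min-shifted);
  the floor-plus-one formula puts SUV 0 in bin 1 and is monotone.
* **Surface area** uses voxel-face counting: deterministic and exactly
  checkable against hand counts. Its known limit on smooth shapes is 1.5×
  the true area (staircase effect), so face-count sphericity of a digital
  ball converges to 2/3 rather than 1; tests assert that estimator-consistent
  limit. A marching-cubes mesh would converge to 1 but would not be
  hand-checkable; shape features remain internally comparable across tumors
  because all use the same estimator.
* **SUVpeak** is the maximum over VOI voxels of the mean SUV in a 1 cm³
  sphere (radius 6.204 mm) clipped at the image border; when the VOI itself
  is smaller than the sphere, SUVpeak falls back to SUVmean with a warning.
* **Zero denominators** (constant VOI: NGTDM coarseness, GLCM correlation,
  coefficient-of-variation-type features) return 0 with a warning; degenerate
  phantoms must not crash a cohort run.
* **Yeo-Johnson** lambda is fitted by profile maximum likelihood on
  $[-5, 5]$; the transformed feature is additionally standardized to training
  mean 0 / SD 1 so both normalization branches land on comparable scales for
  PCA and penalized models. The skewness boundary $|g_1| = 0.5$ is assigned
  to the robust branch (the two published conditions overlap only there).
  A constant feature gets an identity transform; a zero IQR falls back to
  unit scale — both with warnings.
* **Perfect separation**: a univariable logistic filter fit with essentially
  zero deviance has a collapsed Wald statistic (Hauck–Donner effect); such
  features score `Inf` so that a perfectly separating feature ranks first,
  as it does under every other filter.
* **Ties** are broken lexicographically by feature name everywhere a ranking
  is produced, and by `(strategy, classifier)` name on the leaderboard;
  every stochastic step (splits, folds, LASSO fold ids, stochastic learners)
  takes an explicit seed. Two runs with the same configuration are
  byte-identical.
* **Empty LASSO support** falls back to the single strongest path feature so
  a downstream classifier always has at least one input.

## Design decisions where the design was open

* **Strategy factorization**: the cascade is decomposed as
  $\{PCA\ on/off\} \times \{6\ filters\} \times \{LASSO\ on/off\} = 24$;
  when PCA is on, filters and LASSO operate on the principal components
  (clinical covariates included in the PCA, which is centred but not
  re-scaled since inputs are already normalized; ordinal stages and the
  binary histology indicator are left un-normalized and enter as-is).
* **Clinical encoding**: histology → binary adenocarcinoma indicator;
  T-stage (T4a → 4) and N-stage → integer ordinals, preserving order.
* **Hyperparameter grids** (tuned by the same repeated CV that selects the
  model, not nested): filter cut k ∈ {2, 5, 10, 20, all}; SVM cost
  {0.1, 1, 10} × {radial, linear}; random forest {100, 300} trees ×
  depth {3, unlimited}; KNN k ∈ {3, 5, 11}; neural net hidden width
  {8, 32}; LASSO penalty by internal 3-fold CV on the fold's training half.
  A `"reduced"` preset (one point per classifier, k ∈ {5, all}) exists for
  multi-seed calibration studies and the packaged acceptance script; the
  vignette-scale studies in `analysis/` and the tests use it so a full
  144-pipeline sweep stays in the tens of seconds on one core.
* **ICC manifest**: the multivendor reproducibility values behind the ICC
  preselection come from an external phantom study that is not deposited;
  the packaged manifest (`icc_manifest_synthetic.csv`) is a clearly labelled
  synthetic stand-in that flags exactly 22 of the 143 features below 0.6, so
  the preselection arithmetic (143 → 121) is exercised by real code. Supply
  your own manifest for real data.
* **Class imbalance** is addressed only through the AP selection metric —
  no resampling or class weighting — matching the modelled pipeline.
* **Problem sizes** used by the tests and the acceptance script: tabular
  cohorts of n = 199 with 30 features for the null (20 seeds) and
  planted-signal checks; image cohorts of 14–16 patients for end-to-end
  determinism; brute-force texture oracles on ≤ 6³ grids; exhaustive AP/AUC
  oracles on all label vectors of length ≤ 8.

## Known limitations

* The feature registry totals 143 by construction; the exact composition of
  the original 143-feature list is not public, so feature-by-feature value
  comparisons with the modelled study are not meaningful — only the counts,
  the processing conventions, and the pipeline arithmetic are.
* Filter and classifier hyperparameters are tuned in the same repeated CV
  used for model selection (as in the modelled pipeline), so leaderboard AP
  is optimistically biased; the held-out test subset is the honest estimate.
* Delineation is threshold-based (default 40% of SUVmax); manual-correction
  workflows are out of scope and externally corrected masks are simply
  ingested.
* No DICOM/SUV calibration, no CT radiomics, no wavelet features, no
  harmonization across scanners beyond the ICC manifest mechanism.
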