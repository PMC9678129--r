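---
title: "Methods: dried-milk-spot DIMS metabolomics with model triangulation"
author: "milkDIMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dried-milk-spot DIMS metabolomics with model triangulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkDIMS)
```

# The problem and the workflow

Direct-infusion mass spectrometry (DIMS) of dried milk spots produces one
composite spectrum per sample per ionisation polarity: a peak list of
(m/z, intensity) pairs with no chromatographic dimension. The question the
package addresses is whether such profiles discriminate lame from healthy
dairy cows, and — more demandingly — which ions do so *reliably*, rather
than as artefacts of one particular model family.

The workflow is, in order:

1. **Feature extraction** — intensity thresholding, ppm-window alignment of
   peak lists into a feature matrix, a missingness filter, k-nearest
   neighbour imputation, and low-level fusion of the two polarities.
2. **Chemometrics** — TIC normalisation, log transform, Pareto scaling;
   PCA for structure; OPLS-DA with VIP scores and an S-plot; leave-one-out
   Q²; a label-permutation test; per-feature Student's t-tests with
   Benjamini–Hochberg FDR; discriminative ions = VIP > 1 ∧ p < 0.05 ∧
   q < 0.05; per-ion ROC curves.
3. **ML triangulation** — random forest, elastic net, PLS-DA and linear
   SVM under leave-one-cow-out cross-validation with recursive feature
   elimination; ions selected only by PLS-family models are flagged
   *model-dependent*.
4. **Stability selection** — elastic net, Lasso and MCP logistic
   regressions refit on stratified bootstrap resamples; per-feature
   selection percentages; a permutation-derived selection threshold; and
   sign-based bootstrap p-values.
5. **Annotation** — adduct mass calculus against a local compound table
   with a signed ppm error.

# The synthetic study generator

No public instrument data accompany this design, so `generateStudy()` is a
first-class, tested component, not a fixture. Its defaults emulate the
study design the analysis assumes:

* 10 lame and 11 control cows, each extracted on day 8 and day 16, plus 3
  pooled-QC acquisitions per day — 48 observations per polarity;
* 500 true features per polarity drawn uniformly over m/z 70–1050 with a
  guaranteed 30 ppm minimum spacing (so alignment has a well-defined
  truth);
* log-normal intensities: per-feature mean levels `Normal(log 8e5, 1.2)`
  on the natural-log scale and residual scatter `sd = 0.4` (a ~40%
  coefficient of variation, typical for direct-infusion intensities);
* planted class effects as additive shifts on the log scale
  (`log2FoldChange` × log 2), default 1.5;
* a day-16 attenuation centred on ×0.7 with a per-feature log-normal
  spread (`dayEffectSd = 0.3`): storage loss is compound-dependent, and a
  purely global factor would be cancelled exactly by TIC normalisation,
  leaving no day structure for PCA to find;
* Normal m/z jitter with 1 ppm standard deviation (Orbitrap-like mass
  accuracy);
* missing-not-at-random dropout: a peak is lost with probability
  `maxRate · plogis(−(log I − mid)/width)` (defaults 0.4, log 1.5e5, 0.6),
  monotone decreasing in intensity — this is what makes the >20%
  missingness filter and the knn imputation genuinely exercised;
* QCs as the day's mean biological profile times a deterministic
  sinusoidal drift (amplitude 0.05) and multiplicative noise (sd 0.02), so
  they fall centrally in PCA score space as pooled QCs should.

What the generator deliberately does **not** emulate: isotope patterns,
chimeric/overlapping peaks, profile-mode peak shapes, electrospray matrix
effects, and between-cow biological covariance beyond the class shift.
Passing tests therefore demonstrate the statistical machinery, not
robustness to every artefact of real spectra.

# Feature extraction choices

The alignment algorithm pools all peaks of one polarity, sorts by m/z,
splits at consecutive gaps wider than the window (5 ppm, computed against
the lower value), refines each block against its intensity-weighted
centroid and re-splits at the widest internal gap until every member is
within the window. When one sample contributes several peaks to a feature
the most intense is kept and the centroid is recomputed from kept peaks.
This is deterministic and order-independent, and on jitter-free data it
recovers the generator's feature count exactly (tested).

The intensity threshold (100 000) is read as *strictly above*; the
missingness filter (20%) as *strictly more than*, with QCs included in the
denominator. Imputation is feature-wise kNN (k = 10): a missing cell is
the unweighted mean of the k nearest features by Euclidean distance over
mutually observed samples, neighbours restricted to features observed in
the target sample, ties broken by feature order. An exhaustive-enumeration
oracle validates it over a randomised sweep of small matrices.

# Chemometrics

Preprocessing is TIC normalisation (rows sum to 1), then `log(x·1e6 + 1)`
(the 1e6 rescale keeps the pseudo-count of 1 on a count-like scale), then
Pareto scaling (centre, divide by √sd). Inside any cross-validation the
Pareto statistics are refit on the training fold only; TIC and log are
per-sample and leak nothing.

OPLS-DA uses the orthogonal-filtering NIPALS sequence for a single binary
response coded 0/1 (first factor level = control = 0): the predictive
weight is the X–y covariance direction; each orthogonal component removes
the part of the X loading orthogonal to that weight; the single predictive
component is then fit on the filtered matrix. Predictions follow the
standard O-PLS path (strip orthogonal variation, project, regress), with a
0.5 decision cut and ties going to the control class. For one response,
OPLS-DA with 1+1 components is a rotation of 2-component PLS; the test
suite verifies prediction equality against an independent NIPALS PLS1
implementation to 1e-8.

VIP is computed from the predictive component only (`vipOrthogonal = TRUE`
switches to the total variant), so the mean squared VIP is exactly 1 and
"VIP > 1" means "above-average contribution to the class separation". The
S-plot reports the covariance and Pearson correlation of each centred
input feature with the predictive score.

Q² is true leave-one-out (not k-fold): `1 − PRESS/SS`, preprocessing
refit per fold. The permutation test refits the model (and its LOOCV Q²)
under label permutations and uses the `(1 + b)/(1 + m)` empirical p-value,
which cannot be exactly zero. The t-test defaults to the pooled-variance
Student form with a Welch option; FDR control is Benjamini–Hochberg via
`p.adjust`, cross-checked against an independent step-up implementation.

PCA is run on all 48 observations including QCs (structure check); OPLS-DA
and everything downstream use the 21 first-day study cows only. Both
polarities are aligned jointly across days before any modelling.

# Machine-learning triangulation

The four classifiers are used off the shelf (randomForest, glmnet, e1071's
linear SVM) except PLS-DA, which reuses the in-package NIPALS code.
Hyperparameters are deliberately plain — RF 500 trees, elastic-net mixing
0.5 with the penalty from inner cross-validation, SVM cost 1, PLS 2
components — all configurable. Standardisation for ML is TIC followed by
per-feature z-scoring, refit inside every training fold.

Recursive feature elimination halves the feature set down to 20 and then
steps by one, re-ranking by model-specific importance (impurity for RF,
|coefficient| for the elastic net, weights-based VIP for PLS, |w| for the
linear SVM) after each cut. Two readings of "elimination outside the CV"
are possible; the default nests the elimination inside each training fold
(no selection bias), and `nested = FALSE` gives the literal
rank-once-on-all-data variant for comparison. Repeated evaluation of
stochastic learners is supported through `nRepeats` (averaged LOOCV); the
reported importance tables come from full-data fits.

A conventionally selected ion supported only by PLS-family methods (the
PLS-DA top-k and/or the OPLS-based selection itself) is flagged
model-dependent; support from any of RF, elastic net or SVM makes it a
consensus candidate with its support count.

# Stability selection

The outcome model is penalised *logistic* regression (the outcome is a
class, and a linear mode remains available). Per fit, the penalty strength
comes from inner 5-fold cross-validation with the 1-SE rule; "selected"
means a non-zero coefficient. Bootstraps are stratified by class —
at n = 21 an unstratified resample is single-class too often — with
resample counts 500 (scores), 20 permutations × 50 bootstraps
(threshold) by default. The threshold is the *maximum* stability score any
feature attains in any permuted dataset (a family-wise null bound); a
quantile alternative exists. Bootstrap p-values are the minority-side
proportion of a feature's non-zero signed coefficients, zeros excluded,
hence ≤ 0.5 by construction.

MCP has no solver among the installed dependencies, so the package ships a
coordinate-descent implementation (C++): columns standardised internally,
penalty on the standardised scale, firm-threshold updates with
Breheny–Huang adaptive rescaling so any γ > 1 is admissible for the
logistic family, and a damped proximal-Newton outer loop — the IRLS
quadratic is frozen, solved by coordinate descent, and the step is halved
whenever the penalised objective would rise. Convergence is declared on
the penalised objective (relative change < 1e-5), with two guards that
matter at n = 21: iteration stops when the deviance falls below 1% of the
null deviance (quasi-separation leaves no finite optimum), and the inner
loop stops when per-sweep progress on its surrogate objective becomes
negligible (coefficients can slide along a near-collinear valley long
after the fit has stopped changing). On orthonormal designs the gaussian
path reproduces the closed-form firm-threshold operator to 1e-6, and as
γ → ∞ the MCP solution matches glmnet's Lasso to 1e-4 (both tested).

# Annotation

Monoisotopic masses use the IUPAC table (carbon-12 exact); adduct m/z is
`(M + Δ)/|z|` with one electron mass subtracted per positive charge and
added per negative charge folded into Δ. The electron correction is not
cosmetic: omitting it shifts a sodiated hexose-amine by roughly 3 ppm,
larger than the 5 ppm tolerance's useful resolution. Mass error is
reported signed as `(measured − theoretical)/theoretical × 1e6`; the
absolute value is carried alongside because sign conventions differ across
software. The default tolerance is 5 ppm; an absolute ±0.001 m/z mode
serves lipid-style searches, and multiply charged adducts (e.g.
`[M+2Na]2+`) are included for lipids. A small curated compound table for
the dairy-lameness application is bundled; live database queries are out
of scope by design.

# Problem sizes used by the test suite

The shipped tests run the full machinery at reduced, documented sizes
chosen to keep the default suite fast while preserving every contract:
generator studies of 20–150 features per polarity; stability selection at
100 bootstraps with a 10 × 25 permutation threshold (the 500/20/50
defaults remain available and are the pipeline defaults); RFE on matrices
of up to ~190 fused features; the end-to-end reproducibility run at 120
features per polarity. The parameter-recovery experiment plants three
log2-fold-change-1.5 effects among 40 positive-mode features at n = 21 and
repeats the full score-plus-threshold procedure over 20 seeded replicates.

# Known limitations

* The OPLS-DA implementation targets a single binary response; no
  multi-class or O2-PLS variants.
* The permutation threshold is a conservative maximum; with few
  permutations it is itself noisy. More fundamentally, at n = 21 the
  per-resample CV that picks the penalty treats bootstrap duplicates as
  independent, so even permuted datasets select their chance-best feature
  very stably: the null maximum sits in the 80–100% range and can saturate
  at exactly 100%, where the strict "above threshold" rule can select
  nothing at all. Genuine effects (which also score near 100%) and the
  null maximum therefore overlap — the procedure is a conservative
  screen at this sample size, not a guaranteed detector. A stricter
  grouped-CV variant (`stabilityScores(groupedCv = TRUE)`), which keeps
  all copies of one observation in a single inner-CV fold, de-saturates
  the threshold but admits markedly more false selections; the reference
  behaviour is the default.
* The MCP objective is non-convex: the solver returns a stationary point,
  and which one can depend on the lambda path and warm starts. Selection
  sets are stable in practice (tested), coefficient values near threshold
  boundaries less so.
* kNN imputation treats features as exchangeable neighbours; it does not
  model the censoring mechanism that produced the missingness.
* The generator's independence assumptions (features independent given
  class and day) make the synthetic task easier than correlated real
  spectra; triangulation behaviour on strongly correlated blocks is only
  lightly exercised.
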