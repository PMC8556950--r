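---
title: "Staging hepatocytes from single-cell Raman spectra: methods and design"
author: "ramanstage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging hepatocytes from single-cell Raman spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanstage)
```

## The problem

Primary human hepatocytes (PHH) can be driven into a proliferating,
progressively progenitor-like state (ProliHHs); the stage of that
dedifferentiation — passage 0 (PHH), passage 1 (P1), passage 4 (P4) —
matters for drug-metabolism work and cell-therapy quality control, but
staging by RT-qPCR or wet-lab assays is slow. Single-cell Raman
spectroscopy of the fingerprint region (300–1800 cm⁻¹) reads out the
biochemical composition of a fixed cell in seconds, and the stages differ
reproducibly in a small set of bands: glycogen (480 cm⁻¹), tyrosine
(831 cm⁻¹), polysaccharide (840–860 cm⁻¹), phenylalanine (1003 cm⁻¹),
phospholipid (1080 cm⁻¹), tyrosine C–H bend (1172 cm⁻¹), hydroxyproline
(1206 cm⁻¹), collagen/α-helix (1265 cm⁻¹), lipids (1300, 1440,
1744 cm⁻¹), amide III (1337 cm⁻¹) and amide I (1658 cm⁻¹).

`ramanstage` implements the full analysis chain for this setting:
preprocessing, band-area semi-quantification with Student's t-tests,
PCA/Fisher-LDA discrimination, and a two-layer stacked classifier
evaluated through prediction-by-reference confusion matrices. Because no
public single-cell hepatocyte Raman data set is deposited, the package
ships a synthetic generator that emulates the study's class structure;
every claim the test suite makes is made against that generator's known
ground truth.

## The synthetic generator

A spectrum is built as

$$ y(\nu) \;=\; \sum_{b} A_{c,b}\, J_b\, G(\nu;\,\nu_b,\,\mathrm{fwhm})
   \;+\; B(\nu) \;+\; \varepsilon(\nu) \;+\; S(\nu), $$

with $G$ a Gaussian line of 15 cm⁻¹ FWHM (a typical solid-phase Raman
linewidth; the lineshape is a generator choice), $A_{c,b}$ the
class-by-band mean amplitude, $J_b$ a per-cell lognormal jitter with 10 %
coefficient of variation, $B$ a nonnegative degree-3 polynomial
fluorescence background whose mean height equals the tallest peak
(`baseline_scale = 1`), $\varepsilon$ additive Gaussian noise with s.d.
5 % of the tallest peak, and $S$ Poisson-count cosmic-ray spikes
(rate 0.3/spectrum, height 10–100× the tallest peak, width 1–2 channels).
The axis is 300–1800 cm⁻¹ at 1 cm⁻¹ (1501 channels). Metadata mimic the
acquisition design: 3 replicate batches, alternating center/periphery
sampling positions, two spectra per cell.

`default_profiles()` encodes the reported trend directions with a 1.35×
amplitude ratio between adjacent classes on trending bands: decreasing
PHH > P1 > P4 at 840–860, 1080, 1265, 1300, 1440, 1658 and 1744 cm⁻¹;
increasing at 1003, 1206 and 1337 cm⁻¹; PHH above both ProliHHs stages at
480 and 831 cm⁻¹; and P4 elevated at 1172 cm⁻¹. The ratio, the 10 %
amplitude CV and the baseline/noise levels are generator choices, not
measurements — the publication reports no within-class variance — chosen
once so that every encoded trend is statistically detectable at 100
spectra per class with 5 % noise, which is far fewer cells than a real
acquisition (≈ 600 per class) would provide. The whole data set is a pure
function of its configuration, including the seed.

What the generator does *not* emulate: instrument response and wavenumber
calibration drift, batch-correlated intensity effects, cell-to-cell
morphology (sampling location has no effect on the synthetic signal),
Mie scattering ripples, and the heavy-tailed, spatially correlated
backgrounds of real cytoplasm. Passing tests therefore demonstrate that
the *pipeline* recovers what it is designed to recover — not that real
hepatocytes are this easy to classify; the synthetic classes are cleaner
and more separable than real cells, and test-set accuracies on synthetic
data routinely exceed the ~85 % reported for real spectra.

## Preprocessing

The chain is fixed: resample (optional) → despike → baseline correction →
area normalization, mirroring the usual normalization of single-cell
Raman spectra.

**Despiking.** Cosmic rays are 1–2 channel transients. Channels touching a
first-difference whose modified z-score ($0.6745\,(d-\tilde d)/\mathrm{MAD}$)
exceeds the threshold (default 8) become candidates; candidate runs wider
than `despike_window` (default 5 channels) are dismissed as genuine band
edges — on low-noise spectra the flanks of real peaks produce large
z-scores, and the width rule is what keeps them intact — and surviving
runs are replaced by linear interpolation across their clean neighbours.
The operation is idempotent and reports the flagged wavenumbers.

**Baseline.** Asymmetric least squares: a Whittaker smoother (second
difference penalty, smoothness $\lambda = 10^5$) with weights $p = 0.01$
above the current estimate and $1-p$ below, iterated 10 times. This is
the standard fluorescence-background remover for Raman spectra; a
degree-5 iterative polynomial fit is available behind the same interface
(`baseline_method = "poly"`). One numerical subtlety is documented rather
than hidden: under additive noise the asymmetric weights settle the
smoother on the *lower noise envelope*, about 1.3 noise s.d. below the
true background. With `baseline_offset = TRUE` (default) the estimate is
shifted back by the mean residual over non-peak channels, making it
unbiased and bringing the RMSE against the generator's true baseline to
≈ 3.5 % of the mean background (vs ≈ 7 % uncorrected). The uncorrected
estimate (`baseline_offset = FALSE`) retains the classic lower-envelope
property (below the signal at ≥ 90 % of channels); the corrected one, by
construction, does not — an unbiased curve runs through the middle of the
noise. The two behaviours cannot coexist in one estimator, so the choice
is a flag and the default favours accuracy of the recovered background.
Corrected + baseline always reconstructs the input exactly, and negative
corrected intensities are kept (clipping would bias band integrals).

**Area normalization.** Each spectrum is scaled so its trapezoid integral
over the axis is 1 (probability-density convention); band areas then read
as dimensionless fractions of total scattering. The operation is
idempotent and scale-invariant.

Re-running the whole chain on its own output is *approximately* stable:
no spikes are found and intensities move only through the baseline
estimator's residual response to noise (mean change well under 1 % of the
peak scale, band areas within a few percent — the second pass digs
slightly under the strongest peaks). A noise-responsive baseline
estimator cannot return exactly zero on its own output, so exact
idempotence of the chain is not attainable; preprocess raw spectra once.

## Band quantification

Band areas are trapezoid integrals over closed wavenumber windows, with
interpolated endpoints when a window edge falls between channels. The
publication prints only band centers, so single-center bands get ±10 cm⁻¹
windows — wide enough for a 15 cm⁻¹ FWHM line, narrow enough that no two
windows overlap; the 831 cm⁻¹ window is truncated to [821, 839] where it
would abut the 840–860 cm⁻¹ interval. Because the true windows are
unknown, absolute area values are not comparable to the published
figures; only trend directions and significances are. Groups are
summarised by medians (as in the source study) and compared per band with
the two-sided pooled-variance Student's t-test, annotated
ns / * / ** / *** / **** at the 0.05 / 0.01 / 0.001 / 0.0001 thresholds
(p = 0.05 is "ns"), with no multiple-testing correction — each band is
read as its own pre-specified univariate comparison, as in the original
analysis.

## PCA and Fisher LDA

With ~1500 channels and a few hundred spectra per class, within-class
scatter is singular in channel space, so the package uses the standard
PCA–LDA remedy: centered-SVD PCA retaining a cumulative
explained-variance target (default 99 %), then Fisher LDA in score space
via the generalized eigenproblem $S_w^{-1} S_b$, with at most
(classes − 1) axes. If $S_w$ is still ill-conditioned it is ridge
regularized with $\varepsilon = 10^{-8}\,\mathrm{tr}(S_w)/d$ and the
epsilon recorded on the model. Discriminant directions are mapped back to
channel space, unit-normalized, and sign-fixed (largest-magnitude loading
positive) so results are deterministic; ties in the top-loading ranking
break toward the lower wavenumber. `top_loading_wavenumbers()` returns
the `ceiling(fraction × channels)` channels with the largest absolute
loadings on an axis — the usual reading of *which* spectral features
drive a separation. Class posteriors use a shared (pooled) Gaussian in
discriminant space with training priors.

Whether the original analysis fitted LDA on raw channels or PCA scores,
and with what regularization, is not stated; published score coordinates
are therefore not reproducible and nothing in the test suite asserts
them.

## The two-layer stacked classifier

`fit_stacked()` is the package's headline model:

1. **Split.** 75 % training / 25 % test (`split_train_test()`), stratified
   by default; an unstratified mode reproduces the kind of split whose
   per-class test totals drift from exact 25 %.
2. **First layer.** Six base learners on the preprocessed full-spectrum
   channel vectors: k-nearest neighbours (k ∈ {3,5,7,9,11}), PCA-LDA
   (99 % variance), PLS-DA (2–20 components, one-hot response, argmax
   decision), linear SVM (cost ∈ {0.01, 0.1, 1, 10}), RBF SVM
   (cost ∈ {0.1, 1, 10} × γ ∈ scale-heuristic × {0.1, 1, 10}) and random
   forest (500 trees, mtry ∈ {√p, 0.1 p}). Hyperparameters are tuned by
   repeated stratified k-fold cross-validation (default 10 folds × 5
   repeats) maximizing accuracy. The SVMs standardize channels internally
   with training statistics (their cost grids assume unit-variance
   inputs) and are tuned on margin decisions. Their class probabilities
   are, by default, a softmax over the summed pairwise decision values
   (`svm_probability = "softmax"`); libsvm's cross-validated Platt
   scaling is available (`"platt"`) but is an order of magnitude more
   expensive per fit and statistically fragile on small, cleanly
   separable folds, where the sigmoid fit degenerates.
3. **Meta-features.** At the tuned values the same folds are replayed to
   produce out-of-fold class-probability predictions for every training
   spectrum, averaged over repeats, so no learner ever scores a spectrum
   it was fitted on within a repeat. The layout is 6 learners × classes
   columns. Probabilities are used rather than hard labels to preserve
   information; `meta_mode = "label"` provides the hard-label variant.
4. **Second layer.** A gradient-boosting machine (xgboost,
   `multi:softprob`, learning rate 0.1, trees ∈ {50, 100, 150},
   depth ∈ {1, 2, 3}) is tuned by the same repeated CV on the
   meta-features and fitted on all of them.

Every random draw — folds, Platt scaling, forests, boosting — derives
from the `cv_spec()` seed, so an identical configuration reproduces the
model, its tuned values and its predictions bit for bit. Evaluation
produces the prediction-by-reference confusion matrix (rows =
prediction, columns = reference) with per-class sensitivity
(100 · correct/reference-total), specificity (100 · true-negatives /
negatives) and overall accuracy (100 · trace/total), each to one decimal.

`make_table2_fixture()` hard-codes the published stacked-model test
confusion matrix (462 spectra) as a known-answer fixture. One
inconsistency in the source is handled explicitly: the printed PHH
specificity is 81.2 %, but the printed counts give
100 · (307 − 27)/307 = 91.2 %; the package reports what the counts
determine and flags the discrepancy rather than guessing which printed
number is wrong.

## Problem sizes used by the tests

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make each property measurable with comfortable margins on a
single CPU: trend recovery at 100 spectra/class and 5 % noise (all 36
encoded monotone orderings recovered with p < 0.05); the
stacked-vs-best-single-learner comparison over 10 generator seeds at 200
spectra/class and 15 % noise with 5-fold × 2-repeat CV and single-point
hyperparameter grids (tuning is not the question there, the ensemble
combination is); preprocessing
invariants at 90 spectra with default spike and noise rates; and
determinism through two complete pipeline runs at 40 spectra/class with
single-point grids. Larger sizes change none of the conclusions, only
the wait.

## Known limitations

* The published real-data accuracies (overall 84.6 %, per-model and
  center/periphery variants) depend on undeposited spectra and cannot be
  reproduced; the package reproduces the *metric arithmetic* exactly and
  the *pipeline properties* on synthetic data.
* The original study's vendor preprocessing (despiking and baseline
  algorithms and their parameters) is unspecified; results on real
  spectra will depend on how closely these defaults match it.
* Band windows are a reasoned convention (±10 cm⁻¹), not the study's.
* PLS-DA probabilities are a softmax of one-hot regression scores —
  adequate for stacking, not calibrated probabilities.
* The synthetic location flag (center/periphery) carries no signal, so
  location-robustness checks on synthetic data verify only that the
  pipeline introduces no location artifact of its own.

## A minimal session

```{r example, eval = FALSE}
gen <- generate_dataset(synthetic_config(n_per_class = 100, seed = 1))
clean <- preprocess(gen$spectra)

bt <- band_table(clean)
head(compare_groups(bt, "PHH", "P4"))

lda <- fit_lda(clean)
top_loading_wavenumbers(lda, clean$wavenumber, axis = 1)[1:10]

sp <- split_train_test(clean, seed = 1)
model <- fit_stacked(sp$train, cv = cv_spec(folds = 5, repeats = 2, seed = 1))
evaluate(model, sp$test)
```
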