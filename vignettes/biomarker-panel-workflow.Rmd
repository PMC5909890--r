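---
title: "From untargeted m/z features to a replicated biomarker panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From untargeted m/z features to a replicated biomarker panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzpanel)
```

## The problem

Untargeted LC-MS plasma metabolomics reports relative abundances for
thousands of m/z features per electrospray ionization mode (NEG and POS,
scan range 50–1200 m/z), most of which are unidentified. Turning such
tables into a diagnostic biomarker panel — here, for mild traumatic brain
injury (concussion) against non-concussed controls — takes a chain of
steps, each with quiet statistical pitfalls: naming features by mass,
normalizing semi-quantitative abundances, selecting a small analyte panel,
estimating its classification performance honestly, and showing that the
panel replicates in an independent cohort measured in a different analytic
batch. `mzpanel` implements that chain as composable, seed-deterministic
functions.

## Annotation by monoisotopic mass

A singly charged ion observed at m/z $x$ in NEG mode corresponds to a
neutral monoisotopic mass $M = x + 1.007276$ Da ($[M-H]^-$); in POS mode
$M = x - 1.007276$ ($[M+H]^+$). `match_features()` compares each feature's
implied neutral mass against a compound library and assigns annotations by
*stepwise best matching*: all (feature, compound, mode) pairs within a
threshold (default 0.01 Da; 0.05 is the looser conventional choice) are
candidates, and candidates are consumed greedily in ascending absolute
mass error. Each compound can be claimed once per mode and each feature
once; remaining in-threshold candidates are *flagged* as secondary matches
rather than silently dropped, and unmatched features are removed entirely
— the data reduction that takes a few thousand raw features down to a few
hundred named metabolites.

Ties are broken by ascending m/z and then compound name, which makes the
output independent of input row order. The greedy result is identical to a
sequential minimum-error assignment oracle (tested exhaustively on small
instances). Charge state 1 is assumed throughout, and only the
protonation/deprotonation adducts are modeled: all six confirmed marker
metabolites' published (m/z, monoisotopic mass) pairs are consistent with
the ±1.007276 Da offsets to within 0.0041 Da, so richer adduct sets are
unnecessary for this workflow.

The shipped library (`default_library()`) contains the six MS/MS-confirmed
markers with their published masses and database IDs, plus ~300 synthetic
records (prefixed `Syn`) spanning 60–1190 Da whose only purpose is to make
simulations realistically crowded; they are not real metabolites and the
file says so in its name.

## Normalization

Raw relative abundances are non-negative, right-skewed, and contain
non-detect zeros. The pipeline uses:

* **half-minimum imputation** (`impute_missing()`): zeros become half the
  feature's minimum positive value; all-zero features are dropped;
* **generalized log** (`glog_transform()`):
  $x \mapsto \log_2\!\big((x + \sqrt{x^2 + a^2})/2\big)$, strictly
  increasing, finite at zero, and converging to $\log_2 x$ for $x \gg a$.
  The offset $a$ (default 1, on the relative-abundance scale) only shifts
  the monotone scale; it is recorded in the transform parameters;
* **auto-scaling** (`autoscale()`): per-feature standardization with the
  $n-1$ standard deviation. Zero-variance features are dropped with a
  warning. The operation is idempotent, and fitted means/sds are recorded;
  replication cohorts are scaled with their own fitted parameters, since
  the two cohorts come from different analytic batches.

## Batch adjustment

`batch_correct()` applies a per-feature location–scale adjustment on the
glog scale: within each batch, each shared feature is recentred and
rescaled to the pooled grand mean and the pooled *within-batch* standard
deviation. Per-batch means become exactly equal, and two identical batches
pass through unchanged. This is deliberately simpler than empirical-Bayes
shrinkage (ComBat-style): with dozens of samples per batch the per-feature
estimates are stable, the adjustment is transparent, and the scientific
use here is a sensitivity analysis — showing that the replication
conclusion does not flip when the batch effect is removed. `pca_scores()`
provides the standard before/after diagnostic: with a multiplicative
batch shift the cohorts separate on PC1 before adjustment and mix after.

## Panel selection

Five selectors rank the annotated analytes; each returns an ordered
`ranked_feature_list` and `build_panel()` takes the top $k$ (default 10,
the a-priori panel size, refined downstream):

* `univariate_stats()`: per-feature Mann–Whitney AUC (folded to ≥ 0.5),
  Welch $t$, and raw-scale log2 fold change;
* `lasso_selection_frequency()`: stability selection — 100 stratified
  draws of 80% of each group, L1-penalized logistic regression with the
  penalty chosen by internal cross-validation (1-SE rule), features ranked
  by the percentage of draws with a nonzero coefficient;
* `linear_svm_ranking()`: recursive feature elimination on a linear-kernel
  SVM (cost fixed once by inner 5-fold CV), dropping the lowest-weighted
  tenth per step; rank is elimination order;
* `plsda_vip()`: PLS-DA variable importance in projection (2 components by
  default); the mean squared VIP equals 1 by construction;
* `random_forest_importance()`: permutation importance over 500 trees.

Targeted-kit variants are expressed as a compound-class whitelist
(`filter_by_class()`) applied before ranking rather than as a separate
algorithm. All stochastic selectors take explicit seeds and are
reproducible bit for bit.

## Evaluation and replication

`logistic_scores()` fits maximum-likelihood logistic regression on the
panel. When the fit separates (detected by the usual fitted-probability
warnings or a vanishing residual deviance), a ridge-stabilized fit
(`ridge_lambda = 0.05` on autoscaled features) replaces it and the result
is flagged. The penalty is deliberately *not* vanishingly small: with a
near-ML fallback, separated training folds emit saturated probabilities
whose fold-to-fold miscalibration corrupts the pooled cross-validated ROC.

Three evaluation modes mirror the published workflow:

* **discovery** (`evaluate_discovery()`): full-data fit and ROC;
* **internal validation** (`evaluate_cv10()`): seeded stratified 10-fold
  CV, refitting per fold and pooling the held-out probabilities into one
  ROC — one internal-validation AUC per panel rather than an average of
  ten noisy per-fold AUCs (folds shrink automatically when a class is
  too small to stratify);
* **replication** (`evaluate_replication()`): the panel's labels are first
  reduced to those present in the external cohort (`intersect_common()`,
  the step that turned 10-analyte discovery panels into the 6- and
  8-analyte common panels), then the coefficients are *refit* on the
  external cohort, matching the convention that replication is analyzed
  like training/discovery. Applying the frozen discovery coefficients
  instead is available via `apply_fitted` as a sensitivity analysis.

`roc_curve_auc()` computes the AUC as the Mann–Whitney statistic with ties
counted 1/2, the standard error by the Hanley–McNeil formula
($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$), a normal-approximation 95% CI
(a stratified bootstrap CI is available by flag), and the
sensitivity/specificity at the Youden-optimal threshold with ties broken
toward higher specificity.

Two independent ROC AUCs are compared with
`compare_independent_rocs()`:
$z = (A_1 - A_2)\big/\sqrt{SE_1^2 + SE_2^2}$, two-tailed $p$, conclusion
at $\alpha = 0.05$. The group sizes behind the published comparisons are
27 cases / 36 controls (internal validation) and 31 / 53 (replication);
with those sizes the three published z-statistics recompute as 0.292,
0.502 and 0.633 — the second and third agree with the printed values
exactly at three decimals, the first differs by half a unit in the last
printed digit (the computed 0.2925 was evidently rounded half-up upstream).
`reproduce_published_stats()` recomputes all of these lines, the two sex-ratio
chi-square statistics, the six marker mass matches and two formula masses,
and reports pass/fail at one unit in the last printed digit.

## The synthetic study conditions

`synthetic_config()` fixes the generator's defaults to the study design:
a discovery cohort of 27 cases vs 36 controls and a replication cohort of
31 vs 53, measured as two batches; 1400 noise features per ESI mode on top
of the ~300 library compounds; the six confirmed markers spiked at
standardized effect $|d| = 1.5$ on the log2-abundance scale with signs
matching each marker's direction of change with TBI (down, up, down, up,
down, up); log-normal abundance noise; m/z measurement error with SD
0.002 Da; a 2× multiplicative batch shift on the replication cohort; and
four non-marker labels dropped from the replication cohort so that
10-analyte discovery panels shrink on intersection, as the published
panels did.

Choices the generator makes where the design was open:

* **Effects act on the log scale** (multiplicative in raw abundance),
  consistent with LC-MS relative-abundance behavior. Single-marker AUC is
  therefore the binormal $\Phi(d/\sqrt 2) \approx 0.86$ at $d = 1.5$
  (`theoretical_auc()`), and simulated per-marker AUCs match it within
  0.02 at $n = 500 + 500$.
* **Markers are correlated** (`marker_correlation`, default $\rho = 0.5$,
  via a shared latent factor signed by each marker's effect direction).
  Co-regulated lipid species are strongly correlated in real plasma, and
  the correlation is what keeps the six-marker panel's multivariate AUC in
  the published 0.75–0.90 band: six *independent* markers at $|d| = 1.5$
  would give a panel AUC near 0.995, saturating replication fits at
  exactly 1.0 and degenerating the Hanley–McNeil SE to zero. With
  $\rho = 0.5$ the panel's population AUC is
  $\Phi\!\big(d\sqrt{6/(1+5\rho)}/\sqrt{2}\big) \approx 0.92$ while each
  marker's marginal AUC is unchanged.
* **Noise features are guaranteed unannotatable** by rejection sampling:
  candidate noise m/z values are redrawn until they sit at least three
  matching thresholds away from every library compound's expected m/z in
  the feature's mode (both adducts of every compound are guarded, since
  the matcher considers all compounds in each mode). Annotation-reduction
  counts in tests are therefore exact, not probabilistic.
* **Determinism**: every cohort is a pure function of the config seed
  (cohort 2 uses a fixed large offset); compound baselines are drawn from
  the seed alone so the two cohorts share them.

What the generator does *not* emulate: retention-time structure, isotope
envelopes, in-source fragments, heteroscedastic instrument drift,
non-Gaussian outliers, or correlated noise outside the marker block.
Passing the end-to-end tests therefore shows that the pipeline's logic is
sound under the assumed statistical structure, not that any particular
real-data performance figure is reproduced — the study's plasma feature
tables were never deposited, so the published AUC values themselves are
not recomputable.

## Numerical choices and degenerate inputs

* Matching threshold default 0.01 Da (the stricter of the two conventional
  values); non-positive thresholds, empty libraries and unknown ESI modes
  are errors.
* glog offset $a > 0$ enforced; transform states may only move
  raw → glog → autoscaled, and each stage validates its input state.
* All-zero features are dropped at imputation; zero-variance features at
  autoscaling; both with warnings naming the features.
* Panels larger than the ranked list truncate with a warning; `k` below 1
  is an error.
* AUC ties count 1/2 everywhere; Youden ties resolve toward higher
  specificity; `hanley_mcneil_se(1, ...)` is exactly 0, and comparing two
  equal AUCs with zero SEs yields $z = 0$, $p = 1$.
* Stratified folds shrink (with a warning) when the smaller class cannot
  fill 10 folds; degenerate one-class subsamples in stability selection
  are redrawn up to 10 times.

## Problem sizes used in the shipped tests

The test suite exercises the full default study conditions (1400 noise
features per mode, the published group sizes) in the end-to-end recovery
test over 10 generator seeds, and uses reduced feature counts (30–100
noise features) where only correctness of a single stage is at stake.
Null-distribution and optimism properties use 40–200 simulation repeats;
the bootstrap-SE comparison uses 1000 resamples per configuration. A full
default pipeline run takes well under a minute on one CPU.

## Known limitations

* Annotation is by mass alone; it is *preliminary* by construction.
  MS/MS spectral confirmation, retention-time matching and isotopologue
  grouping are out of scope.
* The Hanley–McNeil comparison assumes independent cohorts; correlated-ROC
  designs need DeLong's method, which this package deliberately omits.
* The location–scale batch adjustment assumes the batch effect is
  feature-wise affine on the glog scale.
* The internal-validation AUC pools out-of-fold probabilities; averaging
  per-fold AUCs is a defensible alternative the package does not
  implement.
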