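---
title: "Harmonizing and comparing multi-site ROI morphometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing and comparing multi-site ROI morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmon)
```

## The problem

Consortium studies of brain morphometry pool region-of-interest (ROI)
measurements — cortical thickness, surface area, subcortical volume — from
many scanners. Each site contributes a systematic shift in location and a
systematic change in residual spread that have nothing to do with biology.
Three analytic strategies deal with this:

* **RE-Meta** (random-effects meta-analysis). Per site and ROI, an ordinary
  linear model `y = a_site + X b_site + e` with diagnosis, age, and sex;
  the diagnosis coefficient becomes a Hedges' *g*, and per-site *g* values
  are pooled with inverse-variance weights `w_i = 1 / (var_i + tau^2)`,
  where `tau^2` is the between-site heterogeneity.
* **ME-Mega** (mixed-effects mega-analysis). One model on the pooled
  subjects per ROI, `y = a + X b + gamma_site + e`, with the site intercept
  random.
* **ComBat-Mega**. First remove the site effects with ComBat, then analyze
  the harmonized values with ordinary linear models and no site term.

ComBat assumes `y = alpha + X beta + gamma_site + delta_site * e`, i.e.
both an additive (`gamma`) and a multiplicative (`delta`) site effect per
ROI, and — crucially — that the per-site effects of different ROIs share a
common distribution. That sharing is what the empirical-Bayes (EB) step
exploits: per-site, per-ROI estimates are shrunk toward a per-site normal
prior (additive effects) and inverse-gamma prior (variance effects), with
hyperparameters estimated from the spread of the raw estimates across ROIs
by the method of moments.

## The fit/apply split and missing data

`combat_fit()` estimates all parameters; `combat_apply()` removes the site
effects from data using a previously fitted model. The split matters when
parameters must come from a training set and be applied to held-out data;
applying a model to a site that was absent at fit time is an error by
design, not a silent refit.

ROI tables in practice have holes. `combat_fit()` therefore completes the
matrix before fitting: each missing cell is replaced by the fitted value of
a per-site, per-ROI least-squares model of the observed cells on the
covariates (diagnosis included). These imputations are *temporary* — they
exist only so the parameter estimation has a complete matrix, are never
written back, and `combat_apply()` never imputes: a missing cell stays
missing in the harmonized output. A site/ROI pair with missing cells needs
at least `#covariates + 2` observed cells for its local model (an error
names the pair otherwise); if the local design is degenerate (say, a
single-sex site) the site/ROI mean stands in. ROIs whose observed values
have no variance at all are dropped from harmonization and passed through
unchanged, with a warning, so output tables stay column-stable.

Numerical details that are fixed rather than tunable: the grand intercept
and covariate coefficients come from a pooled least-squares fit with
per-site intercepts under a sample-size-weighted sum-to-zero constraint
(the canonical ComBat identifiability choice); the EB posterior effects are
solved by the standard fixed-point iteration with tolerance `1e-4` on the
maximum relative change and a 1000-iteration cap, mirroring the reference
implementation in the sva package so the two agree to numerical identity on
complete data (the test suite asserts `<= 1e-6` relative difference).
Nonparametric priors are out of scope.

## Effect sizes and multiplicity

All pipelines report Hedges' *g*: the diagnosis coefficient divided by the
model residual SD, corrected for small-sample bias with
`J = 1 - 3/(4 df - 1)` where `df` subtracts one per covariate, and variance
`J^2 ((n1+n2)/(n1 n2) + d^2/(2(n1+n2)))`. For ME-Mega the standardizer is
the *residual* (within-site) SD by default — comparable with ComBat-Mega,
where site variance has been removed — with the total SD available as an
option. Confidence intervals are `g ± 1.96 sqrt(var_g)`. `tau^2` is
estimated by REML by default (DerSimonian–Laird selectable); the pooled
estimate is tested against a standard normal, OLS coefficients against t,
and mixed-model coefficients against t with Satterthwaite degrees of
freedom. Holm's step-down correction is applied across the full ROI family
of a run (thickness, area, and volume jointly when present).

One implementation note: the pooling step defaults to an internal profiled
REML solver rather than `metafor::rma()` because the permutation machinery
below refits tens of thousands of small meta-analyses; `engine = "metafor"`
selects the metafor path, and the test suite asserts the two agree to
around `1e-6`.

## Permutation-based method comparison

To ask whether pipeline A is systematically more significant than pipeline
B beyond chance, p-values are placed on the logit scale,
`logit(p) = ln(p/(1-p))`, which is equally sensitive across the range
(0.6 vs 0.4 gives a difference of 0.8; 0.003 vs 0.001 gives 1.1); p-values
are clipped to `[1e-15, 1 - 1e-15]` so numerical underflow cannot produce
infinities. The observed statistic is the *median over ROIs* of
`logit(p_A) - logit(p_B)`. Its null distribution comes from Draper–Stoneman
permutations: diagnosis labels are shuffled within each site, measurements
and covariates stay fixed, and both pipelines are rerun on the identical
permuted data; only the ROI-median difference is kept, which is what makes
a multiplicity correction unnecessary. The reported probability is
one-sided with +1 smoothing, `(1 + #{null <= observed})/(n_perm + 1)`, so
it can never drop below the permutation granularity floor. A degenerate
self-comparison (A = B) yields observed = null = 0 and probability 1 under
this convention.

Two companion evaluations reuse the same permutation stream (counter-based
child seeds from one master seed, so nested loops are reproducible and
order-free):

* **Empirical FWER**: the proportion of permutations in which at least one
  ROI reaches a Holm-adjusted p < 0.05, per pipeline.
* **Small-subset power**: the pipelines are rerun on random subsets of
  sites; detection is Holm-adjusted p < 0.05, counted over ROIs that were
  strongly significant (Holm p < 0.001) on the full data under *all*
  pipelines — the joint filter stands in for "ROIs with true effects".
  Per-ROI powers are compared between pipelines with a Wilcoxon signed-rank
  test (R's default conventions: exact when feasible, normal approximation
  with tie correction otherwise, zero differences dropped).

A diagnostic connects the two: `variance_ratio()` computes, per ROI, the
pooled within-site residual variance over the total residual variance
(both after covariate adjustment — the covariate-adjusted decomposition is
our reading; an unadjusted variant would differ only through covariate
imbalance). The smaller this ratio, the more variance site explains, and
the larger the significance gain harmonized pooling shows.

## The synthetic generator

No consortium dataset ships with this package, so evaluation runs on
synthetic data drawn from the same generative model the harmonization
assumes: per-ROI intercepts and covariate effects, additive site effects
`gamma ~ Normal(site mean, tau^2)` with site means spread across sites,
squared multiplicative effects `delta^2 ~ InverseGamma(shape, scale)`
(shape > 2 enforced so moment-based recovery checks are meaningful;
`shape = Inf` plants exactly no scale heterogeneity), diagnosis effects
specified on the Hedges'-g scale, and missing cells completely at random.
`delta` multiplies the residual, consistent with the residual-scaling role
of the multiplicative effect in the harmonization model. Defaults describe
a mid-sized consortium arm: 20 sites of 100 subjects, 40 thickness-like
ROIs, residual SD 1 (so g and the raw effect coincide), additive site SD
around 0.42 in total (site-mean spread 0.3, within-prior tau 0.3) and
`delta^2 ~ IG(6, 5)` (mean 1, variance 0.25) — site effects big enough
that harmonization visibly matters, as in the consortium data the model
targets. `enigma_like_preset()` scales the structure up to 33 sites of
unequal size (log-uniform 30–400, rescaled to about 6038 subjects), 48%
cases, 156 ROIs split 70/70/16 across thickness, area, and volume, true
effects uniform on −0.45 to 0.28, and the female fraction higher among
controls (49%) than cases (34%).

What the generator does *not* emulate: spatial correlation between
neighboring ROIs, site-by-age confounding, non-MCAR missingness, and
non-normal residuals. Passing tests therefore demonstrate correctness of
the machinery under the model's own assumptions, not robustness to every
way real consortium data can deviate from them.

## Study sizes used by the shipped evaluations

The test suite and the acceptance script size their simulations for a
single desktop core: FWER control is checked on 20 sites × 100 subjects ×
40 ROIs over 200 permutations; parameter recovery on 10 sites × 500
subjects × 50 ROIs (correlation ≥ 0.95 against the identifiable transform
of the planted effects — additive effects centred by the weighted per-ROI
site mean, multiplicative effects per-ROI scale-normalised, since a
per-ROI constant shift or scale is absorbed into the intercept and pooled
variance); the power ordering on 20 sites × 60 subjects with 8-site
subsets and 100 replicates; and p-value calibration on 20 sites × 30
subjects × 20 ROIs over 500 within-site permutations.

## Known limitations

* The RE-Meta pooled test uses a normal reference with estimated `tau^2`
  (metafor's default convention). At desk-scale site counts its null
  p-values are measurably *conservative* — the fraction below 0.05 runs a
  little under 0.05 and a Kolmogorov–Smirnov test against uniformity
  rejects at 10^4 pooled null p-values — consistent with the below-nominal
  empirical FWER this pipeline shows. This is a property of the method,
  not a defect of the implementation; users wanting better-calibrated
  few-site meta-analyses should consider Knapp–Hartung-type adjustments,
  which are out of scope here.
* Harmonization protects only the covariates it is told about; a
  confounder correlated with site that is omitted from `combat_fit()` will
  be partially absorbed into the site effects.
* The EB priors pool across all ROIs supplied in one fit. When thickness,
  area, and volume are harmonized in a single pass their site effects
  share priors; `harmonize(groups = ...)` fits them separately, and on
  synthetic data the two choices give downstream effect sizes within
  ±0.02 of each other.
* Sites present only at apply time are an error; refit with all sites
  instead.
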