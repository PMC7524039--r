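# harmon

Harmonization and case–control comparison of multi-site ROI brain
morphometry.

Consortium neuroimaging studies pool region-of-interest (ROI) tables —
cortical thickness, surface area, subcortical volumes — from dozens of
scanners. Every site adds its own shift in location and its own change in
residual spread, and how those site effects are handled decides how much
statistical power the pooled case–control analysis keeps. `harmon`
implements the three standard strategies side by side, plus the machinery
to compare them:

* **ComBat harmonization with a fit/apply split.** The model
  `y_r = alpha_r + X beta_r + gamma_{r,site} + delta_{r,site} eps` is
  estimated by empirical Bayes: per-site additive effects `gamma` are
  shrunk toward a per-site normal prior and multiplicative effects `delta`
  toward an inverse-gamma prior, both shared across ROIs. `combat_fit()`
  learns the parameters (tolerating missing cells through temporary
  per-site, per-ROI covariate-based imputation, and dropping zero-variance
  ROIs); `combat_apply()` removes the site effects from the same or a new
  dataset without ever imputing — missing cells stay missing.
* **Three pipelines** (`run_pipeline()`): random-effects meta-analysis
  (`remeta`, per-site models pooled with weights `1/(var_i + tau^2)`),
  mixed-effects mega-analysis (`memega`, random site intercept,
  Satterthwaite p-values), and ComBat mega-analysis (`combatmega`,
  harmonize then plain OLS). Each reports per-ROI Hedges' *g* (with the
  `J = 1 - 3/(4 df - 1)` small-sample correction), its variance, 95% CI,
  and raw plus Holm-adjusted p-values.
* **Method evaluation**: Draper–Stoneman within-site permutation comparison
  of significance on the logit-p scale (`compare_significance()`),
  small-subset power with Wilcoxon signed-rank contrasts
  (`subset_power()`), empirical familywise error rate
  (`empirical_fwer()`), and the intra-site/total variance-ratio diagnostic
  (`variance_ratio()`).
* **A synthetic multi-site generator** (`generate_dataset()`,
  `enigma_like_preset()`) that draws data from the harmonization model
  with known ground truth, for power studies and recovery tests.

## Worked example

```r
library(harmon)

cfg <- synth_config(n_sites = 12, n_per_site = 80, n_thickness = 8,
                    n_volume = 4, g = c(-0.4, 0.1), seed = 42)
sim <- generate_dataset(cfg)
dataset <- sim$data
dataset
#> <roi_dataset> 960 subjects x 12 ROIs, 12 sites, 0.0% missing cells
#> covariates: dx, age, sex

model <- combat_fit(dataset, covariates = c("dx", "age", "sex"))
model
#> <combat_model> 12 sites, 12/12 ROIs harmonized, covariates: dx, age, sex
harmonized <- combat_apply(model, dataset)

results <- run_pipeline(dataset, pipeline = "combatmega",
                        covariates = c("age", "sex"))
dplyr::arrange(tibble::as_tibble(results), p_holm)
#> # A tibble: 12 × 9
#>   roi            pipeline         g   var_g ci_low ci_high       p  p_holm  tau2
#>   <chr>          <chr>        <dbl>   <dbl>  <dbl>   <dbl>   <dbl>   <dbl> <dbl>
#> 1 roi01_vol      ComBat-Mega -0.326 0.00422 -0.453  -0.198 5.52e-7 6.63e-6    NA
#> 2 roi01_thickavg ComBat-Mega -0.312 0.00421 -0.440  -0.185 1.54e-6 1.69e-5    NA
#> 3 roi04_vol      ComBat-Mega -0.308 0.00421 -0.435  -0.181 2.09e-6 2.09e-5    NA
#> 4 roi02_vol      ComBat-Mega -0.274 0.00420 -0.401  -0.147 2.50e-5 2.25e-4    NA
#> 5 roi05_thickavg ComBat-Mega -0.231 0.00419 -0.358  -0.104 3.64e-4 2.91e-3    NA
#> # i 7 more rows
```

Each row is one ROI: `g` is the standardized case–control difference on
the harmonized values (negative = smaller in cases), `p` the two-sided
p-value from the covariate-adjusted model, and `p_holm` the familywise
Holm correction over all 12 ROIs. The generating effects ranged from
−0.4 to 0.1, and the strongly negative ROIs surface at the top.

Does harmonized pooling buy statistical significance over meta-analysis on
these data?

```r
cmp <- compare_significance(dataset, "combatmega", "remeta",
                            n_perm = 99, seed = 7)
cmp
#> <significance_comparison> combatmega vs remeta
#>   observed median logit-p difference: -0.994
#>   null range over 99 permutations: [-0.473, 0.440]
#>   one-sided prob (A more significant): 0.01
```

The observed median logit-p difference (−0.99, i.e. ComBat-Mega's p-values
are systematically smaller) lies far outside anything produced by 99
within-site label permutations, with the one-sided permutation probability
at its granularity floor, `(1+0)/(99+1) = 0.01`.

A command-line front end wrapping the same functions ships at
`inst/cli/harmon.R` (`simulate`, `fit`, `apply`, `compare`, `evaluate`
subcommands; run it with `Rscript`).

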