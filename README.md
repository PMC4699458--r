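# misslong

Missing-data workflows for small longitudinal immunology cohorts.

Infant immunophenotyping studies lose data for logistical, not clinical,
reasons: limited blood volumes, triaged assay panels, specimens that never
reach the laboratory. The result is a cohort — here, two
antiretroviral-therapy arms (deferred vs early initiation) seen at two
semester visits plus single-visit HIV-exposed-uninfected controls — where
flow-cytometry and ELISA panels are missing for 30–45% of recorded visits
while the priority CD4⁺ T-cell percentage is always measured. `misslong`
implements the complete analysis workflow for such data, for
biostatisticians and immunologists who need arm-effect estimates that use
every observed cell:

- **Synthetic cohort generator** calibrated to the published per-arm,
  per-visit summary table: Gaussian-copula sampling with moment-matched
  truncated-normal marginals, nested visit retention (24/42 enrolled, 12/22
  retained, 23 controls), and panel-structured MCAR/MAR/MNAR missingness
  (a failed blood draw removes a whole assay panel).
- **EM for incomplete multivariate normal data** (`em_fit()`): observed-data
  maximum likelihood with a per-iteration monotonicity guard, an optional
  shrinkage prior for near-singular regimes, Gaussian conditioning
  (`conditional_dist()`), and an over-dispersed multi-start check
  (`disperse_check()`).
- **Little's MCAR test** (`little_mcar_test()`):
  d² = Σ_J n_J (ȳ_J − μ̂)ᵀ Σ̂⁻¹_{O_J} (ȳ_J − μ̂) over missingness patterns J
  against χ² with df = Σ_J p_J − p.
- **Multiple imputation** (`emb_impute()`): bootstrap-EM with conditional
  Gaussian draws, m = 5 by default; `overimpute()` re-imputes known cells as
  a model diagnostic; `rubin_pool()` combines per-imputation fits with
  T = Ū + (1 + 1/m)B and df = (m − 1)(1 + Ū/((1+1/m)B))².
- **One-step Bayesian model** (`fit_bayes()`): data augmentation sampling the
  missing responses jointly with the parameters — conjugate Gibbs under the
  normal likelihood, adaptive Metropolis under the Poisson — with
  Gelman–Rubin R-hat, effective sample size, and DIC (= D̄ + pD).
- **Concordance reporting** (`estimate_concordance()`, `run_pipeline()`):
  per-variable agreement between the two inference routes and between
  distributional assumptions, Pearson regression with R².

Everything takes and returns tibbles, chains with the pipe, and exposes
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(misslong)

coh <- reference_cohort(seed = 20151215)   # fixture geometry + panel masking
missingness_map(coh)$panel_rates
#> # A tibble: 5 × 2
#>   panel     rate
#>   <chr>    <dbl>
#> 1 cd4      0
#> 2 clinical 0
#> 3 elisa    0.191
#> 4 flow     0.338
#> 5 vl       0.485

little_mcar_test(coh)
#> Little's MCAR test: d2 = 57.738  df = 59  p = 0.5221
#>   caveat: some patterns have fewer than 5 cases

rep1 <- run_pipeline(seed = 314,
                     mcmc = list(n_iter = 4000, burn_in = 1000,
                                 n_chains = 2, thin = 1))
dplyr::filter(rep1$mi_estimates, response == "cd4_pct")
#>   response  family estimate     se p_value df b    ubar predicted_early
#> 1  cd4_pct  normal    5.866 2.6059  0.0314 32 0 6.79091            38.8
#> 2  cd4_pct poisson    0.164 0.0741  0.0343 32 0 0.00549            38.8

rep1$concordance[, 1:6]
#>                comparison       quantity  slope intercept r_squared  p_value
#> 1      mi_vs_bayes_normal     difference -0.529   10.3391    0.6757 1.70e-04
#> 2      mi_vs_bayes_normal predicted_mean  1.009   -0.1091    1.0000 4.42e-33
#> 3     mi_vs_bayes_poisson     difference  1.226    0.0363    0.8598 6.60e-07
#> 4     mi_vs_bayes_poisson predicted_mean  1.014   -0.4406    1.0000 4.08e-32
#> 5    mi_normal_vs_poisson     difference 28.127   -6.8388    0.1024 2.45e-01
#> 6 bayes_normal_vs_poisson     difference  7.648   10.7794    0.0319 5.24e-01
```

The masked panel rates land on the per-assay design (CD4 never missing,
ELISA ~20%, flow ~31-34%, viral load ~45% of recorded visits), and Little's
test reads the injected panel missingness as completely at random, as
constructed. The MI rows give the pooled ART-Early − ART-Def effect on CD4⁺%
at visit 2: +5.9 percentage points under the normal assumption and a log
mean ratio of 0.16 under the Poisson one, each with its Rubin-combined
standard error and adjusted df (CD4% is never masked in the fixture, so the
between-imputation variance `b` is 0 and pooling collapses to the
complete-data fit — exactly as Rubin's rules prescribe). The concordance
table shows the two inference routes agreeing essentially perfectly on the
per-variable predicted mean responses (slope ≈ 1.01, R² ≈ 1.0) under either
distributional assumption, while the difference estimates — and especially
comparisons *across* distributional assumptions, which live on different
scales — correlate far less on a single 34-subject realisation. That
contrast is the point of reporting all of them.

`vignettes/missing-data-methods.Rmd` documents the models, priors, default
parameters and known limitations.

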