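---
title: "Missing-data methods for a longitudinal infant immunology cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-data methods for a longitudinal infant immunology cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misslong)
library(dplyr)
```

## The problem

Longitudinal immunophenotyping studies of infants accumulate missingness for
reasons that have little to do with the infants themselves: blood volumes are
small and safety assays take priority, so flow-cytometry or ELISA panels are
frequently triaged away, specimens arrive at the laboratory in insufficient
volume, and visits in resource-constrained settings get skipped. The result
is a small dataset — here, two antiretroviral-therapy arms (deferred
initiation, "ART-Def", versus early initiation, "ART-Early") observed at two
semester visits, plus a single-visit cohort of HIV-exposed-uninfected ("HEU")
controls — in which some assay panels are missing for 30–45% of recorded
visits while the priority CD4⁺ T-cell percentage is always measured.

Discarding incomplete records (listwise deletion) is unbiased when the
missingness is completely at random but wastes most of the information in a
cohort this small. `misslong` implements the workflow that keeps all observed
cells: diagnose the missingness mechanism, then estimate treatment-arm
effects by two independent routes — multiple imputation with Rubin's-rules
pooling, and a one-step full-Bayesian model that samples the missing
responses jointly with the parameters — under both a normal and a Poisson
distributional assumption, and finally quantify how well the routes agree.

## The synthetic cohort generator

No individual-level data ship with the package; `generate_cohort()` creates
cohorts with the statistical structure the analysis assumes, and
`reference_cohort()` pins the study geometry: 24 ART-Def and 42 ART-Early
infants at visit 1, of whom 12 and 22 return at visit 2 (retention is nested:
every visit-2 subject has a visit-1 record), plus 23 HEU controls. Seventeen
measurement columns are generated per subject-visit: CD4⁺%, twelve
flow-cytometry percentages, CD38 mean fluorescence intensity, serum IL-7,
log₁₀ viral load and birth weight.

Sampling uses a Gaussian copula: a latent multivariate normal with
exchangeable correlation (default ρ = 0.3) across the T-cell variables is
pushed through each variable's truncated-normal marginal. The published
per-(group, visit) means and SDs are *moment-matched* through the
truncation — the latent location and scale are solved so that the truncated
distribution itself has the target moments. Naive truncation would not do:
for a variable like the plasmacytoid-dendritic-cell percentage, whose lower
bound sits less than one SD below the mean, truncation alone inflates the
mean by a third. IL-7 is additionally interval-censored to its ELISA
detection range (0.25–16 pg/mL) after sampling, so its sampled moments are
compressed relative to the targets; the generator's calibration tests
therefore assert the 2%-relative moment accuracy on non-censored variables.
ART-initiation days come from log-normals quantile-matched to the published
median and IQR (ART-Early 54 [46, 61] days; ART-Def 220 [171, 341]); a
log-normal is the natural positive right-skewed family fitting three
quantiles.

Missingness is injected at the *panel* level by default
(`missingness_spec()`): one Bernoulli hit removes every variable of a panel
for that visit, emulating a failed blood draw — this is what makes the
missingness map blocky rather than speckled. Default MCAR rates follow the
observed per-assay pattern (CD4 0%, ELISA 20%, flow 31%, viral load 45%).
MAR masks with probability `plogis(a + slope · driver)` for a fully observed
driver, MNAR with the variable's (or panel anchor's) own standardised value
as driver; in both cases the intercept `a` is calibrated on the realised
driver values so the marginal rate hits its target exactly in expectation.

What the generator does **not** emulate: within-subject correlation across
visits (visit-2 values are drawn from their own calibrated marginals,
independent of visit 1 given the group), assay measurement error structure,
non-Gaussian tail shapes, and any relation between ART-initiation timing and
the immune variables. Passing tests therefore demonstrate that the
*inference machinery* is calibrated under the cohort's first- and
second-moment structure and missingness geometry — not that it would be
calibrated under every feature of real immunology data.

## Estimation for incomplete multivariate normal data

`em_fit()` is the computational engine shared by Little's test and the
imputation stage: expectation-maximisation over the observed-data likelihood
of an incomplete multivariate normal, with rows grouped by missingness
pattern and the E-step computed from the conditional Gaussian of each
pattern's missing block. The covariance MLE uses denominator *n*. The
observed-data log-likelihood is asserted non-decreasing at every iteration
(any decrease raises an error rather than a silent wrong answer);
convergence is declared when its change falls below `tol` (default 1e-6,
`max_iter` 500 — the method itself fixes no tolerances, these are the
package's choices). Columns are standardised internally for numerical
conditioning; the fit is affine-equivariant so results are mapped back
exactly.

Two stabilisers handle degenerate regimes, both flagged in the returned
object rather than applied silently. A ridge (1e-8) keeps an exactly
singular covariance positive definite. More importantly, when rows do not
comfortably outnumber columns — the bootstrap-EM resamples of a 68-record,
19-column imputation model are the motivating case — the unpenalised
likelihood can degenerate along near-singular covariance directions. For
that regime `em_fit(prior_df = )` adds an inverse-Wishart-type shrinkage of
the covariance toward its starting diagonal with weight `prior_df`
pseudo-observations; the penalised objective is then the monotone quantity.
The imputation routines default to `prior_df = 0.05 · n` when `n < 10p` and
to plain maximum likelihood otherwise.

`disperse_check()` re-runs EM from several over-dispersed starting points
and reports whether all runs reach the same optimum — the standard guard
against a local maximum masquerading as convergence.

## Little's MCAR test

`little_mcar_test()` computes
d² = Σ_J n_J (ȳ_J − μ̂_{O_J})ᵀ Σ̂_{O_J O_J}⁻¹ (ȳ_J − μ̂_{O_J}),
summing over distinct missingness patterns J, with (μ̂, Σ̂) the EM MLE, against
χ² with df = Σ_J p_J − p. Fully observed variables stay in every observed
set (they sharpen the reference estimate); complete data make the test
inapplicable (single pattern, df = 0) and are flagged rather than given a
fake p-value; patterns with fewer than 5 cases attach a small-sample caveat.

Simulated operating characteristics (`little_calibration()`, also re-run by
the acceptance suite) on six exchangeably correlated variables in two
assay-style panels: empirical size ≈ 0.04–0.05 at α = 0.05 (n = 100, 30%
panel masking); power against a MAR driver rises steeply with the logistic
slope (≈ 0.67 at slope 0.5, ≈ 1 at slope 1, n = 200). Against *self-masking*
MNAR the test is intrinsically weak — the selected values are precisely the
ones never observed, so the signal is only the complement-selection shift in
the observed cells: power ≈ 0.4 at self-slope 1 and ≈ 0.75 at slope 2 under
the most detectable design we found (half the variables self-masked at the
cell level; masking *all* variables largely cancels the signal because the
EM reference shifts with every pattern). A non-significant Little's test is
evidence against MAR-style structure, not proof against MNAR; that is a
property of the test, not of this implementation.

## Multiple imputation: bootstrap EM, overimputation, Rubin's rules

`emb_impute()` creates m (default 5) completed datasets: for each
imputation, rows are bootstrap-resampled, EM is fit to the resample (this is
where parameter uncertainty enters), and every incomplete row of the
original table has its missing block drawn from its conditional Gaussian
given its observed values. The imputation model uses all 17 measurements
plus numeric arm indicators and visit age. Observed cells are never altered
(the test suite hashes them before and after). Draws outside a variable's
declared bounds are clipped and counted — clip-and-log rather than redraw,
because it is simple and auditable; a clipping rate above 2% escalates to a
warning. On the reference fixture the rate is a few percent, driven by
variables like CD38⁺% that sit within one SD of the 100% bound; percent
variables are imputed on their raw scale (no logistic transform) as the
simplest model consistent with the analysis stage.

`overimpute()` is the diagnostic that the imputation model earns its
intervals: each observed cell of a variable is treated as missing in turn
and re-imputed under `draws_per_cell` bootstrap-EM parameter draws; a 90%
interval is the 5th–95th percentile of the draws, computed with the type-6
quantile estimator (positions p·(n+1)) because the default interpolation
systematically undercovers at 20 draws. Under a correctly specified model
coverage lands near 0.90.

`rubin_pool()` combines per-imputation fits: Q̄ = mean estimate, Ū = mean
squared SE, B = between-imputation variance (denominator m − 1),
T = Ū + (1 + 1/m)B, df = (m − 1)(1 + Ū/((1 + 1/m)B))², and a two-sided p
from the t reference. B = 0 (nothing was missing) collapses T to Ū with the
complete-data residual df, flagged. The identity T ≥ Ū holds by
construction and is property-tested.

The per-imputation fits themselves (`glm_fit()`) are ordinary `lm()` under
the normal assumption. The Poisson assumption uses quasi-Poisson log-link
IRLS via `glm()`: the percent-scale responses are continuous, so a
dispersion-scaled quasi-likelihood is the honest way to use a Poisson-shape
mean-variance relation; with a single two-level arm covariate the arm
coefficient is then exactly the log ratio of group means. The default
response coding is the raw percent scale; the literal `log(100·proportion)`
coding is kept as an option (`coding = "log100"`), with non-positive
responses raising an error (or an explicit logged shift) rather than
disappearing silently.

Baseline (visit-1 infected vs HEU) comparisons use the Welch
unequal-variance t-test from group summaries, with Bonferroni flags at
α/M over the family of all tested rows: the Welch form, not the
pooled-variance form, reproduces the published baseline p-values from the
published summary statistics. `stepwise_logistic()` runs backward AIC
elimination within each imputation and keeps variables retained in more than
half of them (majority vote), then refits and pools the final model — the
cross-imputation selection rule is underdetermined in standard practice, and
majority vote is this package's documented choice.

## The one-step Bayesian model

`fit_bayes()` samples the missing responses *jointly* with the parameters
(data augmentation), so imputation and analysis happen in a single model
rather than in MI's two steps. Under the normal likelihood the sampler is
pure Gibbs: conjugate multivariate-normal coefficient updates, an
inverse-gamma(0.001, 0.001) residual-variance update, and each missing
response redrawn from N(x'β, σ²) every sweep. Under the Poisson likelihood
responses are rounded to counts on their natural percent scale (a proper
likelihood needs integers; the rounding error is far below assay noise),
coefficients move by adaptive random-walk Metropolis (scale tuned during
burn-in toward ~30% acceptance, with the proposal shaped by a
quasi-likelihood curvature estimate), and missing responses are drawn from
Poisson(exp(x'β)).

Priors are weakly informative and data-derived: each coefficient gets
N(0, (10 · s)²) where s is the SD of the observed response under the
identity link and the SD of log(1 + y) under the log link — the prior scale
must live on the scale of the coefficients. Defaults follow the reference
procedure: 100 000 iterations (any smaller value is supported; the pipeline
and tests use shorter chains), burn-in 4000, two chains with over-dispersed
starts so the Gelman–Rubin statistic is always computable. R-hat is computed
as √((W + B/n)/W) — exactly 1 for indistinguishable chains, always ≥ 1,
and equal to the classic PSRF up to O(1/n); a coefficient R-hat above 1.1
flags the whole fit non-converged. Wald-style p-values come from the
posterior mean/SD against a normal reference, matching the reference
analysis's significance convention. DIC = D̄ + pD with pD = D̄ − D(θ̄)
evaluated on the observed-data deviance; in a diffuse-prior linear model pD
recovers the sampled parameter count (coefficients + variance) to within a
few percent.

Only response missingness is augmented: the covariates (arm, visit) are
complete by design in this cohort, matching the univariate arm-effect
models.

## Concordance and the pipeline

`estimate_concordance()` regresses one per-variable estimate vector on
another (OLS slope, Pearson r, R², two-sided p), optionally after a natural
log per axis. `run_pipeline()` chains everything — simulate → missingness
map + Little's test (per visit and stacked) → m = 5 imputations → pooled
GLMs (normal + Poisson) → Bayesian fits (normal + Poisson) → concordance —
on the visit-2 records of infected subjects seen at both visits, with the
arm indicator as the single model covariate, and reports every section per
response variable or an explicit skip. Because the published comparison
figures do not state whether difference estimates or predicted means were
correlated, nor the axis transformation, the pipeline computes concordance
for both quantities and, within method, across distributional assumptions.
A master seed makes the JSON report byte-identical across runs.

On the reference fixture the Bayesian-vs-MI concordance of the per-variable
*predicted mean responses* under a common distributional assumption is
essentially perfect (slope ≈ 1.01, R² ≈ 1.0; the acceptance suite asserts
≥ 0.9). The concordance of the *difference estimates* is weaker and
seed-dependent on a single 34-subject realisation — the two routes use the
auxiliary variables differently, so their per-variable arm effects differ by
amounts comparable to their standard errors, and the largest-scale variable
(CD38 MFI) dominates an untransformed regression. The across-distribution
comparisons mix an identity-scale and a log-scale estimand and are reported
without assertion.

## Problem sizes and numerical choices

The simulation-backed checks run at sizes chosen to give stable Monte-Carlo
bands on a single core: Little's-test size at 1000 replicates (99% binomial
band ±0.018 around 0.05), its power curves at 100–200 replicates per slope,
the arm-effect recovery experiment (`coverage_experiment()`) at 200
replicates with 10 000-iteration chains, and overimputation at n = 300.
In the recovery experiment the injected CD4⁺% effect (δ = 4, the magnitude
of the reference arm difference) is combined with MCAR masking of the
response itself at the flow-panel rate 0.31 — in the fixture CD4% is never
missing, which would make the experiment vacuous for the missing-data
machinery, so the coverage design masks the analysed response deliberately.
Both routes' 95% intervals cover δ at ~0.94–0.95 with mean bias ≲ 0.3
percentage points.

Tie-breaks and degenerate inputs are handled explicitly throughout:
all-missing rows are dropped from EM with a warning but retained in tables;
a constant column is ridged and flagged; a singular observed block falls
back to a pseudo-inverse with a warning; zero within-chain variance makes
R-hat NA rather than 1; an empty candidate set gives an intercept-only
stepwise model.

## Known limitations

The imputation model is jointly normal; bounded percent variables are
clipped rather than transformed, which slightly distorts tail draws for
variables near their bounds. The Poisson mode's rounding to counts is an
approximation the reference procedure left unspecified. The generator omits
within-subject longitudinal correlation, so the pipeline's operating
characteristics say nothing about estimators that would exploit it. Little's
test has low power against self-masking MNAR at realistic slopes, and a
non-significant result should be read accordingly. Stepwise AIC selection
across imputations is a pragmatic screen, not a coherent joint model.
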