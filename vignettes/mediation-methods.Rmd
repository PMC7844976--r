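---
title: "Decomposing cohort differences in hearing thresholds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing cohort differences in hearing thresholds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htmediate)
```

## The scientific question

Pure-tone hearing thresholds of adults improved markedly between two
cross-sectional waves of a large Norwegian health survey collected about
twenty years apart.  `htmediate` asks *how much* of that improvement is
transmitted through four modifiable risk factors measured in both waves:
educational attainment, occupational noise exposure, recurrent ear
infections and daily smoking.  The exposure X is the wave indicator
(0 = first wave, 1 = second wave), the outcomes Y are hearing thresholds
in dB averaged over both ears in a low band (0.5, 1, 2 kHz) and a high
band (3, 4, 6 kHz), the mediators M are the four risk factors, and the
baseline covariates C are age and sex.  A negative effect means better
hearing in the more recent wave.

Education plays a dual role.  It is a mediator of interest, but it is
also a cause of the behavioural mediators (noise exposure, smoking) and
of the outcome, and it is itself affected by the wave: an
*exposure-induced intermediate confounder* L.  Its presence blocks the
usual identification of natural effects for the behavioural mediators
and motivates the G-computation machinery below.

## Effects and estimators

On the difference scale we decompose the total effect into a natural
direct effect (NDE) and natural indirect effects (NIE):

* the **joint NIE** of all mediators together requires no assumptions
  about the structure among mediators.  It is estimated with the
  *imputation-based natural effect model*: fit
  E[Y | X, M, C] with all X-by-M interaction terms, duplicate each
  subject at both hypothetical exposure levels x, impute the nested
  counterfactual Y(x, M(x*)) keeping the observed mediators (drawn under
  the factual exposure x*), and regress the imputations on (x, x*, C).
  The x coefficient is the NDE, the x* coefficient the NIE, and because
  the natural effect model is additive in x and x*, NDE + NIE equals
  the total effect exactly (this identity is asserted to 1e-8 in the
  tests).  We do not include an x-by-x* term by default; the flag exists
  in the code but the additive model matches the symmetric intervals the
  study design reports.
* the **traditional difference method** (exposure coefficient with
  versus without the mediators) is run alongside for comparison.  It
  coincides with the natural effect model in linear no-interaction
  systems and diverges under exposure-mediator interaction, and the test
  suite demonstrates both regimes.
* **mediator-specific NIEs** come from parametric G-computation with
  Monte Carlo simulation: multinomial-logit models for L given (X, C)
  and for the focal mediator given (X, L, C), a linear model for Y, and
  counterfactual means computed by drawing baseline covariates from the
  empirical distribution (the nonparametric part) while summing exactly
  over the confounder and mediator categories (so Monte Carlo error
  comes only from the covariate draw; it is reported as `mc_error`).
  The specific NIE contrasts E[Y(1, M(1))] with E[Y(1, M(0))], the
  mediator's cross-world draw conditioning on its own-world confounder;
  the cross-world confounder draws are taken independent.
* **education's partial NIE** holds a controlled co-mediator (noise by
  default, smoking as an alternative) at its natural law under x = 1
  and education's second-wave level, so no effect leaks through the
  co-mediator.

With L present, natural effects for the behavioural mediators are
identified only under one of two extra parametric assumptions, and the
package implements both: `no_XM_interaction` omits exposure-mediator
interactions from the outcome model (exposure-confounder interaction
still allowed), while `linear_L_effect` enters the confounder as a
linear ordinal score with no exposure-confounder interaction
(exposure-mediator interaction allowed).
`test_identification_assumptions()` fits the saturated model, reports
joint Wald tests for the X-by-M and X-by-L blocks and a likelihood-ratio
test of dummy-coded versus linear-score confounder, and recommends a
strategy per stratum; when both assumption sets are violated it picks
the smaller violation (larger p-value) and flags the result, with ties
going to `no_XM_interaction` because it is the weaker restriction on L.

Age is adjusted with a restricted cubic spline with five knots at the
0.05, 0.275, 0.50, 0.725 and 0.95 quantiles (the standard placement);
`lrt_spline_vs_linear()` reproduces the spline-versus-linear
likelihood-ratio comparison with 3 degrees of freedom.  All models
adjust for sex, and every analysis can be stratified by sex, in which
case sex is a row filter rather than a covariate.  Mediated proportions
are NIE divided by the covariate-adjusted cohort effect, printed to two
decimals in tables and whole percents in summaries; the pipeline
suppresses the ratio when the total effect is within two standard
errors of zero, where it is meaningless.

## Inference and sensitivity

Standard errors come from a nonparametric subject-level bootstrap
(1000 draws in the study design; smaller values are used in examples
and tests), with normal-approximation 95% intervals as primary output
and percentile intervals alongside.  Waves are resampled jointly from
the pooled data because the wave indicator is a fixed covariate, not a
sampling stratum.

Unmeasured mediator-outcome confounding is probed through the residual
correlation rho between the mediator-equation and outcome-equation
errors.  Writing beta for the naive mediator coefficient and
sigma_M, sigma_Y for the two residual standard deviations, the
correlated-errors identity gives the bias-corrected coefficient

beta(rho) = beta - rho * sigma_Y / (sigma_M * sqrt(1 - rho^2)),

and the NIE curve alpha * beta(rho), where alpha is the
exposure-to-mediator effect.  (The sqrt(1 - rho^2) factor arises
because the observed outcome-residual variance shrinks by 1 - rho^2
under correlated errors; with it, the reported `rho_zero` recovers the
generating residual correlation exactly in the constructed
unmeasured-confounder test, to the 0.02 tolerance asserted there.)
Categorical mediators are linearised on their ordinal score, which the
output flags as an approximation; the mediator equation keeps only
exposure and baseline covariates so alpha captures the whole
exposure-to-mediator path, while the outcome equation adjusts for the
intermediate confounder when one is declared.

## The synthetic cohort generator

The real subject-level data are under legal access restrictions, so the
package ships a generator whose *defaults* (`hunt_config()`) emulate the
published study conditions: two waves with truncated-normal age (means
50.1 and 53.2 years, SD 16.9, range 20-101), 53% and 56% women, and
per-wave, per-sex marginal distributions of education and the three
behavioural risk factors taken from the published distribution tables
(each normalised to sum to one).  Mediators follow categorical-logit
models whose baselines reproduce those cells exactly; optional
coefficients on centred education score and centred age let structural
simulations couple the mediators to the confounder, at the price of
shifting the marginals (the defaults leave them at zero so the
published margins hold exactly, which also means the secular shift in
the mediator distributions *is* the mediation mechanism, as in the
study).  Outcomes are linear in wave, sex, a smooth quadratic age trend,
education level and mediator levels with Gaussian noise; the
coefficient defaults are illustrative plausible dB values, not
estimates from the restricted data, which the study does not publish.
Missingness blanks one uniformly chosen behavioural mediator for 9% of
subjects, mirroring the study's complete-case loss; it is
missing-completely-at-random, matching listwise deletion's assumption.

`true_effects()` returns the exact population effects implied by a
configuration via path enumeration: expectations over mediator and
confounder categories are finite sums because the outcome is linear in
category indicators, and age integrals use Simpson quadrature on the
truncated-normal law, so there is no Monte Carlo error in the truth.
The target population is the equal mixture of the two waves' covariate
distributions, which is what estimators conditioning on the pooled
empirical covariates estimate in a balanced two-wave sample.

What the generator does *not* emulate: real audiograms (the two
band-averaged outcomes are emitted directly; `average_ht()` serves
users holding per-ear thresholds), ear asymmetry, age-normative
threshold referencing, non-random missingness, dependent mediators
(excluded by the specific-effect estimators' assumptions), and
selection or participation bias.  Passing recovery tests therefore
demonstrates correctness of the estimators under the parametric
families they assume, not robustness to violations of them.

## Numerical choices and problem sizes

Multinomial models are fitted by `nnet::multinom` with a relative
log-likelihood tolerance of 1e-8 and at most 200 iterations;
categories observed fewer than five times trigger a warning suggesting
collapse.  Rank-deficient outcome designs are an error naming the
collinear columns rather than a silent drop; in small strata a
bootstrap resample can lose a rare category and make an interaction
column collinear, so the bootstrap tolerates up to 5% failed resamples
before erroring.  G-computation defaults to
`mc_replicates = max(n, 100000)` covariate draws and warns below 1000.
The rho grid defaults to -0.5 to 0.5 in steps of 0.01 and `rho_zero`
is located by linear interpolation between the bracketing grid points.
Reproducibility is seed-exact: identical configuration and seed give
bit-identical cohorts, Monte Carlo draws and bootstrap resamples.

The test suite validates the estimators at problem sizes chosen to keep
a full run on one CPU in the tens of minutes: method-agreement checks
use cohorts of 50,000 subjects over 20 seeds with bootstrap standard
errors estimated once under the same design; end-to-end recovery runs
the study-like default at 2,000 subjects per wave over 50 replications
against a single 200-draw bootstrap; assumption-test size and power use
500 null and 100 alternative replications; bootstrap coverage uses 500
replications of 200 draws at 1,000 subjects.  Tolerances are stated in
sampling standard errors, so validation at these sizes carries the same
logic as at larger ones.

## Worked example

```{r example, eval = FALSE}
cfg <- hunt_config(n_per_wave = 20000, seed = 1)
data <- generate_cohort(cfg)
report <- run_full_analysis(data, config = list(
  strata = "all", bootstrap = 200, mc_replicates = 20000, seed = 2))
print(report)
true_effects(cfg, "ht_low")   # the generator's exact truth, for comparison
```

## Known limitations

The difference method is reported for comparison only and is biased
under exposure-mediator interaction.  The rho sensitivity analysis
linearises categorical mediators and treats a single focal mediator at
a time.  Specific effects assume mediators are conditionally
independent given wave, sex, age and education; settings with multiple
dependent mediators are out of scope, as are interventional-analogue
effects, longitudinal repeat measurements, survey weights and
measurement-error corrections.
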