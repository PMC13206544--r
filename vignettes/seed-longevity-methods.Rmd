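---
title: "Methods: probit seed-longevity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probit seed-longevity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedlongevity)
```

## The model

Controlled (artificial) ageing exposes orthodox seeds to elevated
temperature and humidity — here 45 °C and 60 % relative humidity — so that
years of storage deterioration compress into days. Germination is scored on
replicate dishes withdrawn at increasing ageing durations, and seed
viability is assumed to decay linearly on the probit scale:

$$\Pr(\text{viable at } t) = \Phi\!\left(K_i - t/\sigma\right),$$

where $\Phi$ is the standard normal CDF, $K_i$ is the initial viability in
probits (the intercept), and $\sigma$ is the number of days of ageing needed
for viability to fall by one probit — the longevity trait of interest,
because unlike $p_{50}$ it does not depend on how viable the seeds were at
the start. The probit scale used throughout is the plain normal equivalent
deviate (no +5 offset), which makes two identities exact:

* $\sigma = -1/\text{slope}$ of the fitted probit regression, and
* $p_{50} = K_i \cdot \sigma$, the time to 50 % viability, obtained by
  solving $\Phi(K_i + \text{slope}\, t) = 1/2$.

The second identity is why lots with equal $\sigma$ but initial viabilities
of 85 % and 99.9 % differ three-fold in $p_{50}$
($\Phi^{-1}(0.999)/\Phi^{-1}(0.85) \approx 2.98$): `p50()` reproduces this
directly.

### Quasibinomial probit fitting

`fit_probit()` maximises the binomial likelihood by iteratively reweighted
least squares with the dish seed counts as prior weights. Replicate dishes
of seeds are more variable than binomial sampling allows (seeds within a
dish share micro-environment and handling), so inference is
quasi-likelihood: the Pearson dispersion
$\hat\phi = \chi^2_{\text{Pearson}}/(n-p)$ scales the coefficient
covariance, with no flooring at 1. Slope tests are $t$ tests on
$\hat\beta/\widehat{SE}$ with the residual degrees of freedom; nested model
comparisons use
$F = \frac{(D_{\text{reduced}} - D_{\text{full}})/q}{\hat\phi_{\text{full}}}$
on $(q, n-p)$ degrees of freedom, the standard quasibinomial convention.
Dispersion is estimated per fitted model, not pooled across lots or species.

Three design kinds cover every analysis stage: a single lot (intercept +
slope), per-lot intercepts with a common slope (the species-level model:
lots may differ in initial viability but share a decay rate), and per-lot
intercepts with per-lot slopes (the full model whose comparison with the
common-slope model tests whether lots of a species differ in $\sigma$).

Numerical choices: $\mu$ is initialised at $(y + 0.5)/(n + 1)$, the linear
predictor is capped at $|\eta| \le 8$ (viabilities within $\Phi(\pm 8)$ of 0
or 1 carry no usable information and destabilise the weights), iterations
stop when the relative deviance change falls below $10^{-10}$ or after 100
iterations. A fit whose uncapped linear predictor escapes the cap, or whose
response is all-zero/all-full (complete separation), is returned with
`converged = FALSE` and a diagnostic rather than a silent estimate. The test
suite verifies agreement with `stats::glm(quasibinomial(probit))` and with a
direct Nelder–Mead maximisation of the binomial likelihood to $10^{-6}$.

### Confidence intervals for sigma

The interval for $\sigma$ applies $x \mapsto -1/x$ to the endpoints of the
slope's $t$-based Wald interval. The map is monotone on the negative
half-line, so coverage is inherited from the slope interval while respecting
the positivity and asymmetry of $\sigma$; a delta-method interval on
$\sigma$ itself would be symmetric and can cross zero. When the slope
interval reaches 0 the transform is undefined and the interval is flagged
rather than reported. This choice is the package's own; an alternative
(profile or bootstrap intervals) would also be defensible but is not needed
for the analyses here.

## Seed-lot screening

Lots pass through fixed-order rules, each exclusion carrying exactly one
triggering status:

1. **Contamination.** Fungal contamination is recorded per dish in the data;
   a lot with more than half of its dishes flagged is excluded
   (`excluded_contaminated`), otherwise flagged dishes are dropped before
   fitting. The one-half cut-off is the package's operationalisation of
   "particularly affected" — the underlying judgement is not computational.
2. **Initial germination < 50 %** (`excluded_low_viability`). Initial
   germination is the *maximum* of the per-duration mean germination
   percentages over the 0/1/5-day window: some species germinate better
   after one or five days of ageing than fresh because the brief exposure
   breaks physiological dormancy, and the maximum avoids penalising them.
   This rule is applied before any fitting.
3. **No significant decay** (`excluded_no_significant_slope`): a
   non-converged fit, a non-negative slope, or a two-sided slope $p \ge
   0.05$. A significantly *positive* slope is treated as a failed decay fit,
   not a longevity estimate.
4. **$\sigma$ beyond the design** (`excluded_sigma_exceeds_max`): when
   $\hat\sigma$ exceeds the longest ageing duration the time course covers
   too little of the survival curve for a precise estimate. The bound is
   taken from the design's maximum duration (72 days in the standard
   design), not hard-coded, so shorter simulated designs screen
   consistently.

Screening is idempotent and monotone in the initial-germination threshold;
both properties are under test.

## Within- and between-species analyses

For each species with at least two retained lots,
`test_lot_differences()` compares the per-lot-slope and common-slope models
with the nested quasi-$F$ test; a significant lot-by-duration interaction
($\alpha = 0.05$) means lots differ in $\sigma$. The species-level $\sigma$
is always computed from the common-slope model regardless of that outcome,
so per-lot and per-species tables are both emitted.
`detection_probability_model()` then regresses the significance indicator
on the number of lots per species (logistic link), reporting Nagelkerke
pseudo-$R^2$ (with McFadden alongside — which definition underlies published
analyses of this kind is often unstated, so both are reported and neither is
privileged).

`fit_lot_predictor_lmm()` relates lot-level $\ln\sigma$ to the
within-species-scaled 1000-seed mass, mean annual temperature (°C) and
annual precipitation (mm) at the lot origin, with a species random
intercept. Seed mass is centred and standardised *within* species
(`scale_within_group()`, sample SD, groups of one are an error) because
absolute mass varies orders of magnitude between species while the question
is within-species. Choices here:

* **Response.** $\ln\sigma$ in both the mixed and the species-level models.
  $\sigma$ is positive with right-skewed between-lot variation, and a log
  response makes effects multiplicative; `log_response = FALSE` preserves
  the untransformed alternative. The log base only shifts the intercept.
* **REML by 1-D profiling.** For a single random intercept,
  $V(\lambda) = I + \lambda Z Z^\top$ is block diagonal, so the REML
  criterion is a smooth function of the variance ratio
  $\lambda = \sigma_u^2/\sigma_e^2$ alone and is optimised by
  `stats::optimize` on $[0, 10^4]$ with an explicit boundary comparison at
  $\lambda = 0$; a boundary optimum is reported as a singular fit, not an
  error. The test suite checks agreement with `lme4::lmer` on fixed
  effects, variance components and the REML log-likelihood.
* **Type-III Wald $\chi^2$** per fixed term, without small-sample
  correction (no Satterthwaite/Kenward–Roger), each continuous covariate
  contributing one degree of freedom. In the species-level OLS models,
  type-III $F$ tests are computed under sum-to-zero contrasts via
  `car::Anova`; with no interactions this equals dropping each term, so the
  result is contrast-invariant.
* **$R^2$ decomposition.** With $\sigma_f^2$ the variance of the
  fixed-effect linear predictor,
  $R^2_m = \sigma_f^2/(\sigma_f^2 + \sigma_u^2 + \sigma_e^2)$ and
  $R^2_c = (\sigma_f^2 + \sigma_u^2)/(\cdot)$. `species_share()`
  ($R^2_c - R^2_m$) is the species-identity share of total lot-level
  variance, and `within_species_share()`
  ($R^2_m / (1 - (R^2_c - R^2_m))$) is the fixed-effect contribution
  relative to the variance left after accounting for species.
* Lots missing any covariate are dropped listwise with a reported count;
  collinear covariates (condition number above $10^8$) are an error.

The species-level models (`fit_species_lm()`) are ordinary least squares of
$\ln\sigma$ on family plus mean seed mass, or on protein plus oil content.
Families represented by one species are retained — they still inform the
family effect — so the family term's numerator degrees of freedom equal the
number of families minus one.

## The synthetic-data generator

`simulate_dataset()` inverts the analysis model so every stage can be tested
against known truth: species effects $u_s \sim N(0, \tau^2)$ on
$\ln\sigma$; lot-level MAT uniform, mass lognormal around the species mean;
$\ln\sigma_{\text{lot}}$ assembled from the species mean, $u_s$, covariate
effects and a lot residual; $K_i \sim N(\mu_K, \sigma_K^2)$; and dish counts
beta-binomial with intraclass correlation $\rho$ — the standard generative
counterpart of quasibinomial mean–variance inflation, giving dispersion
$1 + \rho(n-1)$ at dish size $n$ (verified empirically in the tests).
Dormancy is modelled as a day-0-only germination deficit, the simplest
mechanism that exercises the max-over-{0,1,5} initial-germination rule.

Defaults are fixed once as the study conditions the package targets: the
standard design (10 durations × 3 dishes × 30 seeds = 900 seeds per lot),
40 species × 5 lots (the scale of a ~190-lot, ~40-species European grassland
study), $\ln\sigma$ centred at $\log 20$ with species SD 0.55 and lot
residual SD 0.355 (species $\sigma$ spanning roughly 5–70 days and species
identity dominating lot-level variance), $\beta_{\text{MAT}} = +0.03$ per
°C and $\beta_{\text{mass}} = -0.1$ per within-species SD (longevity rising
with origin temperature and falling with seed mass), $K_i \sim N(2, 0.5^2)$
(≈ 98 % initial viability), $\rho = 0.05$, and a 10 % day-0 dormancy
deficit. MAT uniform on 5–12 °C and lognormal mass with CV 0.2 are pragmatic
distributional choices; only their moments matter to the analyses.

What the generator does *not* emulate: fungal contamination dynamics,
seed-moisture equilibration physics, spatial or phylogenetic correlation
between lots and species, and duration-dependent dormancy beyond day 0.
Passing tests therefore demonstrate correctness of the estimators under the
assumed statistical structure, not robustness to every feature of real
germination data.

### The variance-share anchor

One acceptance-level check engineers the generator so that lot-level
$\ln\sigma$ variance splits 5 % fixed / 67 % species / 28 % residual and
verifies the fitted $R^2_m/R^2_c$ near 0.05/0.72. Two constructional points
matter. First, the shares describe the *estimated* $\sigma$ values entering
the mixed model, so the residual share includes probit-stage measurement
error; the check measures that error variance from the generator on
retained-like lots at run time (≈ 0.012 on the $\ln\sigma$ scale under the
standard design) and assigns the latent lot residual the remainder. Second,
the total $\ln\sigma$ variance is set to 0.2 so the $\sigma$ distribution
(roughly 8–50 days) stays inside the 72-day ageing window: a wider latent
spread pushes lots past the screenable range and the resulting truncation
censors the species tail — a property of the fixture, not of the pipeline.

## Problem sizes and simulation scales

The test suite runs its Monte-Carlo checks at sizes chosen to keep the full
suite around a minute while leaving binomial Monte-Carlo error well inside
the asserted bands: 2 000 two-lot null simulations for the interaction
test's type-I error (95 % binomial band 3.5–6.5 % at a true 5 % rate),
1 000 table-level simulations for the mixed model's null calibration (band
3–8 %, allowing the mild asymptotic-Wald inflation expected at 40 groups),
500 lots for $\sigma$ recovery, 300 fits for dispersion calibration, and
200-replicate coverage checks for the mixed-model and detection-model
coefficients.

## Known limitations

* $\sigma$ intervals are Wald-based; near-flat slopes give undefined
  intervals rather than profile alternatives.
* The mixed model supports exactly one random intercept (species); crossed
  or nested designs (e.g. population within species) are out of scope.
* The quasi-$F$ interaction test is calibrated for binomial and mildly
  overdispersed data; its type-I error under strong, structured
  overdispersion is not characterised here.
* Under dish-level overdispersion ($\rho = 0.05$, dispersion ≈ 2.45) the
  median relative error of $\hat\sigma$ under the standard design is about
  7 % (≈ 4.4 % without overdispersion) — the information limit of a
  30-dish time course, relevant when planning designs that need tighter
  lot-level estimates.
* Screening truncates the observable $\sigma$ range at the longest ageing
  duration; variance components estimated after screening are attenuated
  when a substantial fraction of lots lies near or beyond that bound.
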