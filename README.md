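# seedlongevity

Seed banks conserve plant diversity *ex situ*, but banked seeds die in
storage, and how fast they die varies not only between species but between
seed lots of the same species. `seedlongevity` implements the statistical
pipeline used to quantify that variation from controlled-ageing experiments:
seeds are aged at 45 °C / 60 % relative humidity, germination is scored on
replicate dishes withdrawn at increasing durations, and viability is assumed
to decay linearly on the probit scale,

```
P(viable at t) = Φ(Ki − t/σ)
```

where `Ki` is the initial viability in probits and `σ` (sigma, days per
probit) is the rate-of-loss longevity trait: `σ = −1/slope` of a
quasibinomial probit regression of germination on ageing duration. Unlike
`p50` (time to 50 % viability, which equals `Ki·σ` on this scale), `σ` does
not depend on how viable the seeds were at the start.

The package provides, for researchers and seed-bank practitioners:

* **Probit engine** — binomial-likelihood probit fits by IRLS with seed
  counts as weights, Pearson-dispersion (quasibinomial) inference, nested
  quasi-F tests, and the `σ` / `Ki` / `p50` transforms with
  endpoint-transformed confidence intervals (`fit_probit()`,
  `sigma_from_fit()`, `p50()`).
* **Seed-lot screening** — the fixed-order inclusion rules: contamination,
  initial germination < 50 % (maximum over the 0/1/5-day window, tolerating
  dormancy broken by brief ageing), non-significant slope, and `σ` beyond
  the longest ageing duration (`screen_dataset()`).
* **Within-species tests** — lot-by-duration interaction tests of `σ`
  heterogeneity, species-level common-slope `σ`, and a logistic model for
  how detection probability grows with the number of lots
  (`test_lot_differences()`, `fit_species_sigma()`,
  `detection_probability_model()`).
* **Predictor models** — a REML random-intercept mixed model of `ln σ` on
  within-species-scaled seed mass, origin temperature and precipitation,
  with type-III Wald tests and marginal/conditional R², plus species-level
  OLS on family, seed mass, and protein/oil content
  (`fit_lot_predictor_lmm()`, `fit_species_lm()`).
* **Synthetic data** — a generator inverting the full hierarchical model
  (probit decay, beta-binomial dish overdispersion, species random effects,
  covariate effects, day-0 dormancy) so every stage is testable with known
  truth (`simulate_dataset()`, `make_screening_fixture()`).
* **Pipeline** — `run_all()` chains the stages with CSV/JSON outputs, a run
  manifest and a log; YAML configuration via `read_pipeline_config()`.

## Worked example

```r
library(seedlongevity)

cfg <- simulation_config(n_species = 6, lots_per_species = 3, rng_seed = 1)
sim <- simulate_dataset(cfg)

scr <- screen_dataset(sim$observations)
scr$counts
#>                      retained         excluded_contaminated
#>                            17                             0
#>        excluded_low_viability excluded_no_significant_slope
#>                             0                             1
#>    excluded_sigma_exceeds_max
#>                             0

head(scr$retained[, c("lot_id", "species_id", "sigma_days",
                      "sigma_ci_low", "sigma_ci_high", "slope_p")], 4)
#>       lot_id species_id sigma_days sigma_ci_low sigma_ci_high   slope_p
#> 1 sp01_lot01       sp01      23.00        18.41         30.63 6.049e-09
#> 2 sp01_lot02       sp01      14.97        12.20         19.36 8.749e-10
#> 3 sp01_lot03       sp01      25.15        20.79         31.81 1.590e-10
#> 4 sp02_lot01       sp02      30.00        21.95         47.39 5.657e-06
```

One lot of 18 was excluded (its decay slope was not distinguishable from
zero); each retained lot gets its longevity `σ` in days with a 95 %
confidence interval. Do the three lots of species `sp01` really differ in
longevity?

```r
test_lot_differences(scr$retained_obs[scr$retained_obs$species_id == "sp01", ])
#> Species sp01: 3 lots, interaction F(2, 84) = 5.661, p = 0.004939 *
#>   common-slope sigma = 21.21 days
```

Yes: the lot-by-duration interaction is significant, i.e. within-species
variation in `σ` (here 15.0–25.2 days against a pooled 21.2). Finally, the
mixed model partitions lot-level variance in `ln σ`:

```r
lmm <- fit_lot_predictor_lmm(scr$retained, sim$lot_meta)
lmm
#> Random-intercept LMM of ln(sigma) on lot predictors: 17 lots, 6 species
#>          term estimate     se
#> 1 (Intercept)   3.3110 0.5022
#> 2 mass_scaled  -0.0939 0.0966
#> 3       mat_c  -0.0029 0.0396
#> 4      map_mm  -0.0003 0.0003
#> variances: species 0.2297, residual 0.1019
#> type-III Wald tests:
#>          term  chi2 df     p
#> 1 mass_scaled 0.945  1 0.331
#> 2       mat_c 0.005  1 0.941
#> 3      map_mm 0.833  1 0.361
#> R2 marginal = 0.034, conditional = 0.703

species_share(lmm$r2_marginal, lmm$r2_conditional)       # 0.67
within_species_share(lmm$r2_marginal, lmm$r2_conditional) # 0.102
```

Species identity explains 67 % of the lot-level variance in this simulated
dataset; the lot-level covariates explain about 10 % of what remains —
at this small example size none of the individual covariate tests is
significant. See `vignettes/seed-longevity-methods.Rmd` for the model,
screening rules, numerical choices and the generator's scope.

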