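test_that("identical configs give bit-identical datasets", {
  cfg <- simulation_config(n_species = 4, lots_per_species = 3, rng_seed = 123)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_dataset(simulation_config(n_species = 4, lots_per_species = 3,
                                           rng_seed = 124))
  expect_false(identical(a$observations$n_germinated,
                         c2$observations$n_germinated))
})

test_that("simulated day-0 proportions match the probit viability curve", {
  set.seed(7)
  big <- aging_design(c(0, 1), replicates_per_duration = 3000,
                      seeds_per_replicate = 30, temperature_c = 45,
                      relative_humidity_pct = 60, dormancy_window = c(0, 1))
  obs <- simulate_lot(ki = 2, sigma = 10, design = big, rho = 0,
                      dormancy_fraction = 0)
  p0 <- with(obs[obs$aging_days == 0, ], sum(n_germinated) / sum(n_seeds))
  expect_equal(p0, pnorm(2), tolerance = 3 * sqrt(pnorm(2) * pnorm(-2) / 90000) / pnorm(2))
  # dormancy suppresses day-0 germination only
  obs_d <- simulate_lot(ki = 2, sigma = 10, design = big, rho = 0,
                        dormancy_fraction = 0.3)
  p0d <- with(obs_d[obs_d$aging_days == 0, ], sum(n_germinated) / sum(n_seeds))
  p1d <- with(obs_d[obs_d$aging_days == 1, ], sum(n_germinated) / sum(n_seeds))
  expect_equal(p0d, pnorm(2) * 0.7, tolerance = 0.02)
  expect_equal(p1d, pnorm(2 - 0.1), tolerance = 0.02)
})

test_that("replicate overdispersion matches the beta-binomial target", {
  set.seed(8)
  big <- aging_design(c(0, 1), replicates_per_duration = 4000,
                      seeds_per_replicate = 30, temperature_c = 45,
                      relative_humidity_pct = 60, dormancy_window = c(0, 1))
  for (rho in c(0, 0.05, 0.15)) {
    obs <- simulate_lot(ki = 0.5, sigma = 1e6, design = big, rho = rho)
    k <- obs$n_germinated[obs$aging_days == 0]
    p <- mean(k) / 30
    inflation <- var(k) / (30 * p * (1 - p))
    expect_equal(inflation, 1 + rho * 29, tolerance = 0.08 * (1 + rho * 29))
  }
})

test_that("an effectively infinite sigma gives a flat germination course", {
  set.seed(9)
  obs <- simulate_lot(ki = 1, sigma = 1e9, rho = 0)
  m <- tapply(obs$n_germinated / obs$n_seeds, obs$aging_days, mean)
  # binomial noise only: all duration means near pnorm(1)
  expect_true(all(abs(m - pnorm(1)) < 4 * sqrt(pnorm(1) * pnorm(-1) / 90)))
})

test_that("the hierarchical truth table is complete, positive and consistent", {
  cfg <- simulation_config(n_species = 6, lots_per_species = c(2, 3, 4, 2, 5, 3),
                           rng_seed = 10)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth), sum(cfg$lots_per_species))
  expect_true(all(is.finite(sim$truth$true_sigma) & sim$truth$true_sigma > 0))
  expect_equal(nrow(sim$lot_meta), nrow(sim$truth))
  expect_equal(sort(unique(sim$observations$lot_id)), sort(sim$truth$lot_id))
  # per-species u is constant within species
  u_by_sp <- tapply(sim$truth$u_species, sim$truth$species_id,
                    function(x) length(unique(x)))
  expect_true(all(u_by_sp == 1))
  # species mean mass equals the mean of its lots' masses
  agg <- tapply(sim$lot_meta$thousand_seed_mass_g, sim$lot_meta$species_id, mean)
  expect_equal(as.numeric(agg[sim$species_meta$species_id]),
               sim$species_meta$mean_thousand_seed_mass_g, tolerance = 1e-12)
})

test_that("a null structure yields near-zero fitted variance components", {
  sim <- simulate_dataset(simulation_config(
    n_species = 25, lots_per_species = 4, species_log_sigma_sd = 0,
    beta_mat = 0, beta_mass_scaled = 0, lot_log_sigma_resid_sd = 0.25,
    overdispersion_rho = 0, dormancy_fraction = 0, rng_seed = 12))
  scr <- screen_dataset(sim$observations)
  fit <- suppressWarnings(fit_lot_predictor_lmm(scr$retained, sim$lot_meta))
  expect_lt(fit$r2_marginal, 0.08)
  expect_lt(fit$r2_conditional - fit$r2_marginal, 0.12)
})

test_that("sigma estimates track the simulated truth without bias", {
  set.seed(13)
  signed <- sapply(rep(c(10, 20, 40), length.out = 150), function(true_sigma) {
    obs <- simulate_lot(ki = 2, sigma = true_sigma, rho = 0)
    s <- sigma_from_fit(fit_probit(obs, "single_lot"))
    (s$sigma_days - true_sigma) / true_sigma
  })
  # binomial sampling noise alone: small median error, centred on zero
  expect_lte(median(abs(signed)), 0.06)
  expect_lte(abs(median(signed)), 0.03)
  # replicate overdispersion widens errors roughly by sqrt(phi)
  set.seed(14)
  over <- sapply(rep(20, 150), function(true_sigma) {
    obs <- simulate_lot(ki = 2, sigma = true_sigma, rho = 0.05)
    s <- sigma_from_fit(fit_probit(obs, "single_lot"))
    abs(s$sigma_days - true_sigma) / true_sigma
  })
  expect_gt(median(over), median(abs(signed)))
  expect_lte(median(over), 0.15)
})
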