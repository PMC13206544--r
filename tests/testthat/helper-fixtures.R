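# Fixtures built in code. Noiseless lots carry fractional "counts" so the
# probit-transformed proportions lie exactly on a line; fit_probit() accepts
# them because only the readers enforce integer counts.

noiseless_lot <- function(ki, slope, t = seq(0, 70, by = 5), n = 30,
                          lot_id = "L1", species_id = "S1") {
  v <- pnorm(ki + slope * t)
  data.frame(
    lot_id = lot_id, species_id = species_id, aging_days = t,
    replicate_id = paste0("r", seq_along(t)),
    n_seeds = n, n_germinated = v * n, contaminated = FALSE,
    stringsAsFactors = FALSE
  )
}

random_lot <- function(ki = runif(1, 0.5, 2.5), sigma = runif(1, 8, 50),
                       design = paper_design(), rho = 0,
                       lot_id = "L1", species_id = "S1") {
  simulate_lot(ki, sigma, design, rho = rho, lot_id = lot_id,
               species_id = species_id)
}

# Independent binomial-probit negative log-likelihood for oracle fits.
probit_negloglik <- function(par, obs) {
  eta <- par[1] + par[2] * obs$aging_days
  mu <- pnorm(eta)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -sum(dbinom(obs$n_germinated, obs$n_seeds, mu, log = TRUE))
}

# Nelder-Mead oracle with a restart, independent of the IRLS path.
oracle_probit_fit <- function(obs, start = c(1, -0.05)) {
  o <- optim(start, probit_negloglik, obs = obs, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 20000))
  o <- optim(o$par, probit_negloglik, obs = obs, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 20000))
  o$par
}

# Lot-level sigma table + metadata for mixed-model tests, simulated directly
# at the ln(sigma) level (no germination counts involved).
simulate_sigma_table <- function(n_species = 20, lots = 4, mu = log(20),
                                 sd_species = 0.5, sd_resid = 0.3,
                                 beta_mass = 0, beta_mat = 0, beta_map = 0) {
  n <- n_species * lots
  species <- rep(sprintf("sp%02d", seq_len(n_species)), each = lots)
  u <- rep(rnorm(n_species, 0, sd_species), each = lots)
  mass <- exp(rnorm(n, 0, 0.3))
  mat <- runif(n, 5, 12)
  map <- runif(n, 500, 1200)
  mass_scaled <- scale_within_group(mass, species)
  y <- mu + u + beta_mass * mass_scaled + beta_mat * (mat - 8.5) +
    beta_map * (map - 850) / 100 + rnorm(n, 0, sd_resid)
  list(
    sigma_table = data.frame(
      lot_id = sprintf("lot%03d", seq_len(n)), species_id = species,
      sigma_days = exp(y), stringsAsFactors = FALSE
    ),
    metadata = data.frame(
      lot_id = sprintf("lot%03d", seq_len(n)), species_id = species,
      family = "FamA", thousand_seed_mass_g = mass, mat_c = mat, map_mm = map,
      latitude = 50, longitude = 10, provenance = "wild",
      stringsAsFactors = FALSE
    )
  )
}
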