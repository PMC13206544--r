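# Synthetic germination data with the statistical structure the analysis
# assumes: probit-linear viability decay per lot, beta-binomial replicate
# overdispersion, a species-level random intercept on ln(sigma), lot-level
# covariate effects (positive MAT, negative scaled seed mass), and a day-0
# dormancy deficit that exercises the initial-germination rule.

#' Simulation configuration
#'
#' Parameterises the generative model used throughout the test suite. The
#' defaults describe a controlled-ageing study of European grassland species
#' at the scale of roughly 200 seed lots across 40 species: the standard
#' design ([paper_design()]), species-level sigma centred at 20 days with
#' most species between 5 and 70 days (ln-scale SD 0.55), lot-level residual
#' SD 0.355 on ln(sigma), a mild positive temperature effect and negative
#' within-species seed-mass effect on ln(sigma), initial viability Ki around
#' 2 probits (about 98%), beta-binomial intraclass correlation 0.05 among
#' replicate dishes, and a 10% day-0 dormancy deficit.
#'
#' @param n_species Number of species.
#' @param lots_per_species Lots per species: a single integer or a
#'   per-species integer vector.
#' @param design An [aging_design()].
#' @param species_log_sigma_mean,species_log_sigma_sd Mean and SD of the
#'   species-level ln(sigma) distribution (ln days).
#' @param family_effects Optional named numeric vector of ln(sigma) offsets
#'   per family; species are assigned families round-robin.
#' @param beta_mat Effect of mean annual temperature on ln(sigma), per
#'   degree C (centred MAT).
#' @param beta_mass_scaled Effect of within-species-scaled 1000-seed mass on
#'   ln(sigma), per SD.
#' @param lot_log_sigma_resid_sd Lot-level residual SD of ln(sigma).
#' @param ki_mean,ki_sd Mean and SD of initial viability Ki (probits).
#' @param overdispersion_rho Beta-binomial intraclass correlation among
#'   replicate dishes, in [0, 1); 0 gives pure binomial counts.
#' @param dormancy_fraction Fraction of otherwise-germinable seeds that stay
#'   dormant at day 0 only, in [0, 1).
#' @param mat_range_c Range (low, high) of lot MAT, degrees C.
#' @param map_range_mm Range of lot annual precipitation, mm (no effect on
#'   sigma; carried as a covariate).
#' @param mass_cv Coefficient of variation of lot 1000-seed mass within a
#'   species.
#' @param rng_seed Integer seed; all randomness flows from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 40L,
                              lots_per_species = 5L,
                              design = paper_design(),
                              species_log_sigma_mean = log(20),
                              species_log_sigma_sd = 0.55,
                              family_effects = NULL,
                              beta_mat = 0.03,
                              beta_mass_scaled = -0.1,
                              lot_log_sigma_resid_sd = 0.355,
                              ki_mean = 2,
                              ki_sd = 0.5,
                              overdispersion_rho = 0.05,
                              dormancy_fraction = 0.1,
                              mat_range_c = c(5, 12),
                              map_range_mm = c(500, 1200),
                              mass_cv = 0.2,
                              rng_seed = 1L) {
  stopifnot(inherits(design, "aging_design"))
  n_species <- as.integer(n_species)
  lots <- as.integer(lots_per_species)
  if (length(lots) == 1L) lots <- rep(lots, n_species)
  if (length(lots) != n_species || any(lots < 1L)) {
    stop("`lots_per_species` must be a positive integer or one per species",
         call. = FALSE)
  }
  if (species_log_sigma_sd < 0 || lot_log_sigma_resid_sd < 0 || ki_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (overdispersion_rho < 0 || overdispersion_rho >= 1) {
    stop("`overdispersion_rho` must lie in [0, 1)", call. = FALSE)
  }
  if (dormancy_fraction < 0 || dormancy_fraction >= 1) {
    stop("`dormancy_fraction` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_species = n_species, lots_per_species = lots, design = design,
      species_log_sigma_mean = species_log_sigma_mean,
      species_log_sigma_sd = species_log_sigma_sd,
      family_effects = family_effects,
      beta_mat = beta_mat, beta_mass_scaled = beta_mass_scaled,
      lot_log_sigma_resid_sd = lot_log_sigma_resid_sd,
      ki_mean = ki_mean, ki_sd = ki_sd,
      overdispersion_rho = overdispersion_rho,
      dormancy_fraction = dormancy_fraction,
      mat_range_c = mat_range_c, map_range_mm = map_range_mm,
      mass_cv = mass_cv, rng_seed = as.integer(rng_seed)
    ),
    class = "simulation_config"
  )
}

.rbetabinom <- function(k, size, mu, rho) {
  # k draws of Binomial(size, p) with p ~ Beta(mean mu, intraclass rho).
  if (rho == 0 || mu <= 0 || mu >= 1) {
    p <- rep(mu, k)
  } else {
    m <- 1 / rho - 1
    p <- stats::rbeta(k, mu * m, (1 - mu) * m)
  }
  stats::rbinom(k, size, p)
}

#' Simulate one seed lot's germination time course
#'
#' True viability follows v(t) = pnorm(ki - t / sigma); at t = 0 the
#' germinable fraction is additionally reduced to v(0) * (1 -
#' dormancy_fraction), the day-0-only dormancy deficit. Replicate dish counts
#' are beta-binomial with intraclass correlation `rho` (binomial when 0).
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param ki Initial viability in probits.
#' @param sigma Days per probit of viability loss (> 0).
#' @param design An [aging_design()].
#' @param rho Beta-binomial intraclass correlation.
#' @param dormancy_fraction Day-0 dormancy deficit.
#' @param lot_id,species_id Identifiers for the emitted rows.
#' @return A germination data frame (one row per replicate dish).
#' @export
simulate_lot <- function(ki, sigma, design = paper_design(), rho = 0,
                         dormancy_fraction = 0, lot_id = "lot1",
                         species_id = "sp1") {
  stopifnot(inherits(design, "aging_design"))
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  reps <- design$replicates_per_duration
  n <- design$seeds_per_replicate
  rows <- lapply(design$durations, function(t) {
    v <- stats::pnorm(ki - t / sigma)
    if (t == 0) v <- v * (1 - dormancy_fraction)
    data.frame(
      lot_id = lot_id, species_id = species_id, aging_days = t,
      replicate_id = paste0("r", seq_len(reps)),
      n_seeds = n, n_germinated = .rbetabinom(reps, n, v, rho),
      contaminated = FALSE, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate a full hierarchical germination dataset
#'
#' Draws species effects u_s ~ N(0, species_log_sigma_sd^2), lot MAT uniform
#' over `mat_range_c`, lot 1000-seed mass lognormal around the species mean
#' with CV `mass_cv`, and sets
#' ln(sigma_lot) = species_log_sigma_mean + u_s + family effect +
#' beta_mat * (MAT - mean MAT) + beta_mass_scaled * scaled mass + residual.
#' Ki ~ N(ki_mean, ki_sd^2). Counts come from [simulate_lot()]. The truth
#' table records every latent value.
#'
#' @param config A [simulation_config()].
#' @return List with `observations`, `lot_meta`, `species_meta`, `truth`
#'   (data frames) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  fams <- if (is.null(config$family_effects)) {
    stats::setNames(0, "FamA")
  } else config$family_effects
  fam_names <- names(fams)

  obs <- list(); lots_meta <- list(); truth <- list(); spp_meta <- list()
  for (s in seq_len(config$n_species)) {
    sp_id <- sprintf("sp%02d", s)
    fam <- fam_names[((s - 1L) %% length(fam_names)) + 1L]
    u_s <- stats::rnorm(1, 0, config$species_log_sigma_sd)
    n_lots <- config$lots_per_species[s]
    sp_mass <- stats::rlnorm(1, meanlog = 0, sdlog = 0.8)  # species mean 1000-seed mass, g
    mat <- stats::runif(n_lots, config$mat_range_c[1], config$mat_range_c[2])
    map <- stats::runif(n_lots, config$map_range_mm[1], config$map_range_mm[2])
    mass <- sp_mass * stats::rlnorm(n_lots,
                                    meanlog = -0.5 * log(1 + config$mass_cv^2),
                                    sdlog = sqrt(log(1 + config$mass_cv^2)))
    mass_scaled <- if (n_lots >= 2L) {
      (mass - mean(mass)) / stats::sd(mass)
    } else rep(0, n_lots)
    mat_centred <- mat - mean(config$mat_range_c)
    resid <- stats::rnorm(n_lots, 0, config$lot_log_sigma_resid_sd)
    log_sigma <- config$species_log_sigma_mean + u_s + fams[[fam]] +
      config$beta_mat * mat_centred + config$beta_mass_scaled * mass_scaled +
      resid
    ki <- stats::rnorm(n_lots, config$ki_mean, config$ki_sd)
    for (l in seq_len(n_lots)) {
      lot_id <- sprintf("%s_lot%02d", sp_id, l)
      obs[[lot_id]] <- simulate_lot(
        ki = ki[l], sigma = exp(log_sigma[l]), design = config$design,
        rho = config$overdispersion_rho,
        dormancy_fraction = config$dormancy_fraction,
        lot_id = lot_id, species_id = sp_id
      )
      lots_meta[[lot_id]] <- data.frame(
        lot_id = lot_id, species_id = sp_id, family = fam,
        thousand_seed_mass_g = mass[l], mat_c = mat[l], map_mm = map[l],
        latitude = 50, longitude = 10, provenance = "wild",
        stringsAsFactors = FALSE
      )
      truth[[lot_id]] <- data.frame(
        lot_id = lot_id, species_id = sp_id, family = fam,
        true_sigma = exp(log_sigma[l]), true_ki = ki[l], u_species = u_s,
        mat_effect = config$beta_mat * mat_centred[l],
        mass_effect = config$beta_mass_scaled * mass_scaled[l],
        lot_residual = resid[l], stringsAsFactors = FALSE
      )
    }
    spp_meta[[sp_id]] <- data.frame(
      species_id = sp_id, family = fam,
      mean_thousand_seed_mass_g = mean(mass),
      oil_content_pct = stats::runif(1, 2, 40),
      protein_content_pct = stats::runif(1, 10, 40),
      life_cycle = "P", stringsAsFactors = FALSE
    )
  }
  list(
    observations = validate_germination(
      do.call(rbind, c(obs, list(make.row.names = FALSE)))),
    lot_meta = validate_lot_metadata(
      do.call(rbind, c(lots_meta, list(make.row.names = FALSE)))),
    species_meta = do.call(rbind, c(spp_meta, list(make.row.names = FALSE))),
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    config = config
  )
}

#' Labelled screening fixture
#'
#' A small dataset in which each screening status has at least one lot with
#' a known ground-truth label, including a dormancy lot whose day-0 mean is
#' below 50% but whose day-5 mean exceeds it (and which must be retained),
#' a lot with most dishes contaminated, a low-viability lot, a flat
#' (no-decay) lot, and a lot whose sigma exceeds the maximum duration while
#' its slope is still significant.
#'
#' @param seed Integer RNG seed.
#' @param design An [aging_design()].
#' @return List with `observations` and `truth` (lot_id, expected_status).
#' @export
make_screening_fixture <- function(seed = 42L, design = paper_design()) {
  set.seed(seed)
  specs <- list(
    list(id = "ret1", sp = "spA", ki = 2.0, sigma = 12, dorm = 0,   status = "retained"),
    list(id = "ret2", sp = "spA", ki = 2.2, sigma = 25, dorm = 0,   status = "retained"),
    list(id = "ret3", sp = "spB", ki = 1.8, sigma = 40, dorm = 0.1, status = "retained"),
    # dormancy lot: day-0 germinable fraction pnorm(1.3)*0.4 = 36% < 50%,
    # day-5 viability pnorm(1.3 - 5/25) = 86% -> retained via the window max
    list(id = "dorm", sp = "spB", ki = 1.3, sigma = 25, dorm = 0.6, status = "retained"),
    # initial viability pnorm(-0.5) = 31% -> excluded before fitting
    list(id = "lowv", sp = "spC", ki = -0.5, sigma = 20, dorm = 0,  status = "excluded_low_viability"),
    # slope -1/90 over a 72-day course: significant but sigma > 72
    list(id = "slow", sp = "spC", ki = 2.0, sigma = 90, dorm = 0,   status = "excluded_sigma_exceeds_max")
  )
  obs <- lapply(specs, function(z) {
    simulate_lot(z$ki, z$sigma, design, rho = 0.01, dormancy_fraction = z$dorm,
                 lot_id = z$id, species_id = z$sp)
  })
  # flat lot: constant 80% germination, no decay signal
  flat <- simulate_lot(ki = 2, sigma = 1, design, lot_id = "flat",
                       species_id = "spD")
  flat$n_germinated <- stats::rbinom(nrow(flat), flat$n_seeds, 0.8)
  # contaminated lot: two-thirds of dishes flagged
  cont <- simulate_lot(ki = 2, sigma = 15, design, rho = 0.01,
                       lot_id = "cont", species_id = "spD")
  cont$contaminated <- rep(c(TRUE, TRUE, FALSE),
                           length.out = nrow(cont))
  observations <- validate_germination(
    rbind(do.call(rbind, obs), flat, cont))
  truth <- data.frame(
    lot_id = c(vapply(specs, `[[`, "", "id"), "flat", "cont"),
    expected_status = c(vapply(specs, `[[`, "", "status"),
                        "excluded_no_significant_slope", "excluded_contaminated"),
    stringsAsFactors = FALSE
  )
  list(observations = observations, truth = truth)
}
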