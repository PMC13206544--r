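test_that("within-group scaling centres and standardises per group", {
  expect_equal(scale_within_group(c(1, 2, 3), rep("a", 3)), c(-1, 0, 1))
  expect_warning(z <- scale_within_group(c(5, 5), c("a", "a")), "zero SD")
  expect_equal(z, c(0, 0))
  expect_error(scale_within_group(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
  set.seed(81)
  v <- rnorm(30); g <- rep(letters[1:3], each = 10)
  s <- scale_within_group(v, g)
  for (gi in unique(g)) {
    expect_equal(mean(s[g == gi]), 0, tolerance = 1e-12)
    expect_equal(sd(s[g == gi]), 1, tolerance = 1e-12)
  }
})

test_that("the REML fit matches lme4 on fixed effects, variances and likelihood", {
  skip_if_not_installed("lme4")
  set.seed(91)
  sim <- simulate_sigma_table(n_species = 25, lots = 4, sd_species = 0.5,
                              sd_resid = 0.3, beta_mass = -0.1, beta_mat = 0.05)
  fit <- fit_lot_predictor_lmm(sim$sigma_table, sim$metadata)
  df <- fit$data
  df$y <- log(df$sigma_days)
  m <- lme4::lmer(y ~ mass_scaled + mat_c + map_mm + (1 | species_id),
                  data = df, REML = TRUE)
  expect_equal(fit$fixed_effects$estimate, unname(lme4::fixef(m)),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(fit$random_intercept_variance, vc[1], tolerance = 1e-4)
  expect_equal(fit$residual_variance, vc[2], tolerance = 1e-4)
  expect_equal(fit$reml_loglik, as.numeric(logLik(m)), tolerance = 1e-5)
  expect_equal(fit$fixed_effects$se,
               unname(coef(summary(m))[, "Std. Error"]), tolerance = 1e-4)
})

test_that("forcing zero random-intercept variance reproduces ordinary least squares", {
  set.seed(92)
  sim <- simulate_sigma_table(n_species = 15, lots = 3)
  fit0 <- suppressWarnings(
    fit_lot_predictor_lmm(sim$sigma_table, sim$metadata, var_ratio = 0))
  df <- fit0$data
  ols <- lm(log(sigma_days) ~ mass_scaled + mat_c + map_mm, data = df)
  expect_equal(fit0$fixed_effects$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit0$random_intercept_variance, 0)
  expect_equal(fit0$r2_conditional, fit0$r2_marginal)
})

test_that("zero true species variance yields a boundary fit with R2c near R2m", {
  set.seed(93)
  sim <- simulate_sigma_table(n_species = 30, lots = 4, sd_species = 0,
                              sd_resid = 0.3)
  fit <- suppressWarnings(fit_lot_predictor_lmm(sim$sigma_table, sim$metadata))
  expect_lt(fit$random_intercept_variance, 0.01)
  expect_lt(fit$r2_conditional - fit$r2_marginal, 0.05)
})

test_that("the REML optimum beats perturbed variance ratios", {
  set.seed(94)
  sim <- simulate_sigma_table(n_species = 20, lots = 4)
  fit <- fit_lot_predictor_lmm(sim$sigma_table, sim$metadata)
  expect_gt(fit$variance_ratio, 0)
  for (f in c(0.9, 1.1)) {
    pert <- fit_lot_predictor_lmm(sim$sigma_table, sim$metadata,
                                  var_ratio = fit$variance_ratio * f)
    expect_gte(fit$reml_loglik, pert$reml_loglik - 1e-8)
  }
})

test_that("R2 identities hold and the share formulas follow their definitions", {
  set.seed(95)
  sim <- simulate_sigma_table(n_species = 20, lots = 4, beta_mass = -0.2)
  fit <- fit_lot_predictor_lmm(sim$sigma_table, sim$metadata)
  expect_gte(fit$r2_marginal, 0)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  expect_lte(fit$r2_conditional, 1)
  expect_equal(unname(r2_nakagawa(fit)),
               c(fit$r2_marginal, fit$r2_conditional))
  # the reported decomposition: marginal 0.05 / conditional 0.72 splits into
  # a 0.67 species share and about 15% of the within-species variance
  expect_equal(species_share(0.05, 0.72), 0.67)
  expect_equal(within_species_share(0.05, 0.72), 0.05 / 0.33, tolerance = 1e-12)
  expect_equal(within_species_share(0, 0.5), 0)
  expect_equal(within_species_share(0.3, 0.3), 0.3)
  expect_equal(species_share(0, 0), 0)
  expect_error(within_species_share(0.2, 0.1))
  # decomposition identity: species share + residual share + marginal = 1
  expect_equal(species_share(0.05, 0.72) + (1 - 0.72) + 0.05, 1)
})

test_that("lots with missing covariates are dropped listwise with a message", {
  set.seed(96)
  sim <- simulate_sigma_table(n_species = 10, lots = 3)
  sim$metadata$mat_c[c(1, 5)] <- NA
  expect_message(fit <- fit_lot_predictor_lmm(sim$sigma_table, sim$metadata),
                 "2 lot")
  expect_equal(fit$dropped_missing, 2)
})

test_that("collinear covariates are rejected", {
  set.seed(97)
  sim <- simulate_sigma_table(n_species = 10, lots = 3)
  sim$metadata$map_mm <- sim$metadata$mat_c * 100
  expect_error(fit_lot_predictor_lmm(sim$sigma_table, sim$metadata),
               "collinear")
})

test_that("the type-III Wald chi-squared matches its closed form", {
  # a z-ratio of 2 gives chi2 = 4 and p = 0.0455
  expect_equal(pchisq(4, 1, lower.tail = FALSE), 0.0455, tolerance = 1e-3)
  set.seed(98)
  sim <- simulate_sigma_table(n_species = 20, lots = 4, beta_mat = 0.05)
  fit <- fit_lot_predictor_lmm(sim$sigma_table, sim$metadata)
  fe <- fit$fixed_effects
  z2 <- (fe$estimate[-1] / fe$se[-1])^2
  expect_equal(fit$type3_tests$chi2, unname(z2))
  expect_equal(fit$type3_tests$p, pchisq(z2, 1, lower.tail = FALSE))
  expect_identical(wald_type3(fit), fit$type3_tests)
})

test_that("fixed effects are recovered with near-nominal Wald coverage", {
  set.seed(99)
  beta_mass <- -0.1; beta_mat <- 0.03
  covered <- replicate(200, {
    sim <- simulate_sigma_table(n_species = 40, lots = 5, sd_species = 0.5,
                                sd_resid = 0.2, beta_mass = beta_mass,
                                beta_mat = beta_mat)
    fit <- fit_lot_predictor_lmm(sim$sigma_table, sim$metadata)
    fe <- fit$fixed_effects
    c(abs(fe$estimate[fe$term == "mass_scaled"] - beta_mass) <
        1.96 * fe$se[fe$term == "mass_scaled"],
      abs(fe$estimate[fe$term == "mat_c"] - beta_mat) <
        1.96 * fe$se[fe$term == "mat_c"])
  })
  expect_gte(mean(covered[1, ]), 0.9)
  expect_gte(mean(covered[2, ]), 0.9)
})

test_that("species-level OLS handles families, aliasing and degenerate factors", {
  set.seed(100)
  n_sp <- 33
  fams <- rep(paste0("Fam", 1:9), length.out = n_sp)
  meta <- data.frame(
    species_id = sprintf("sp%02d", 1:n_sp), family = fams,
    mean_thousand_seed_mass_g = exp(rnorm(n_sp, 0, 0.8)),
    oil_content_pct = runif(n_sp, 2, 40),
    protein_content_pct = runif(n_sp, 10, 40),
    life_cycle = "P", stringsAsFactors = FALSE
  )
  sig <- data.frame(species_id = meta$species_id,
                    sigma_days = exp(log(20) + rnorm(n_sp, 0, 0.5)),
                    stringsAsFactors = FALSE)
  fit <- fit_species_lm(sig, meta, model = "family_mass")
  t3 <- fit$type3_tests
  # family enters with (number of families - 1) numerator df
  expect_equal(t3$df_num[t3$term == "family"], 8)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  fit2 <- fit_species_lm(sig, meta, model = "protein_oil")
  expect_equal(nrow(fit2$type3_tests), 2)
  one_fam <- transform(meta, family = "FamA")
  expect_warning(fit3 <- fit_species_lm(sig, one_fam, model = "family_mass"),
                 "single family")
  expect_false("family" %in% fit3$type3_tests$term)
})

test_that("a joint type-III test of a 2-level factor equals the squared t test", {
  set.seed(101)
  df <- data.frame(y = rnorm(30), f = factor(rep(c("a", "b"), 15)),
                   x = rnorm(30))
  fit <- lm(y ~ f + x, data = df, contrasts = list(f = "contr.sum"))
  t3 <- wald_type3(fit)
  tval <- coef(summary(fit))["f1", "t value"]
  expect_equal(t3$F[t3$term == "f"], tval^2, tolerance = 1e-10)
})

test_that("a true-null mass effect in the species model rejects at about 5%", {
  set.seed(102)
  rej <- replicate(400, {
    n_sp <- 30
    fams <- rep(paste0("Fam", 1:6), each = 5)
    meta <- data.frame(
      species_id = sprintf("sp%02d", 1:n_sp), family = fams,
      mean_thousand_seed_mass_g = exp(rnorm(n_sp, 0, 0.8)),
      oil_content_pct = NA, protein_content_pct = NA, life_cycle = "P",
      stringsAsFactors = FALSE
    )
    fam_eff <- rnorm(6, 0, 0.4)[match(fams, paste0("Fam", 1:6))]
    sig <- data.frame(species_id = meta$species_id,
                      sigma_days = exp(log(20) + fam_eff + rnorm(n_sp, 0, 0.3)))
    t3 <- fit_species_lm(sig, meta, model = "family_mass")$type3_tests
    t3$p[t3$term == "mean_thousand_seed_mass_g"] < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
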