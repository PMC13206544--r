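test_that("probit is the normal equivalent deviate and inverts inv_probit", {
  expect_equal(probit(0.5), 0)
  expect_equal(probit(0.85), 1.036433, tolerance = 1e-5)
  # independent oracle: invert the normal CDF by root finding
  for (p in c(0.1, 0.37, 0.85, 0.999)) {
    root <- uniroot(function(x) pnorm(x) - p, c(-10, 10), tol = 1e-12)$root
    expect_equal(probit(p), root, tolerance = 1e-8)
  }
  x <- seq(-6, 6, by = 0.5)
  expect_equal(probit(inv_probit(x)), x, tolerance = 1e-9)
  expect_error(probit(0), "inside")
  expect_error(probit(1), "inside")
})

test_that("noiseless probit-linear data are recovered exactly", {
  obs <- noiseless_lot(ki = 2, slope = -0.1)
  fit <- fit_probit(obs, "single_lot")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), c(2, -0.1), tolerance = 1e-6)
  # weighted least squares on the probit scale is an independent oracle here:
  # the transformed proportions lie exactly on a line
  wls <- lm(qnorm(n_germinated / n_seeds) ~ aging_days, data = obs)
  expect_equal(unname(fit$coefficients), unname(coef(wls)), tolerance = 1e-6)
})

test_that("a constant germination level yields a zero slope and p near 1", {
  t <- seq(0, 70, by = 10)
  obs <- data.frame(lot_id = "L1", species_id = "S1", aging_days = t,
                    replicate_id = paste0("r", seq_along(t)),
                    n_seeds = 30, n_germinated = 24)
  fit <- fit_probit(obs, "single_lot")
  expect_equal(unname(fit$coefficients["slope"]), 0, tolerance = 1e-8)
  wt <- slope_wald_test(fit, "slope")
  expect_gt(wt$p_value, 0.05)
})

test_that("the IRLS fit agrees with stats::glm quasibinomial probit", {
  set.seed(101)
  for (i in 1:5) {
    obs <- random_lot(rho = 0.05)
    fit <- fit_probit(obs, "single_lot")
    g <- glm(cbind(n_germinated, n_seeds - n_germinated) ~ aging_days,
             family = quasibinomial(probit), data = obs)
    expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-5)
    expect_equal(fit$dispersion_phi, summary(g)$dispersion, tolerance = 1e-4)
    expect_equal(unname(sqrt(diag(fit$covariance))),
                 unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
    expect_equal(fit$deviance, deviance(g), tolerance = 1e-6)
  }
})

test_that("IRLS estimates agree with brute-force likelihood maximisation", {
  set.seed(202)
  for (i in 1:20) {
    obs <- random_lot()
    fit <- fit_probit(obs, "single_lot")
    oracle <- oracle_probit_fit(obs, start = unname(fit$coefficients) * 0 + c(1, -0.05))
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
  }
})

test_that("dispersion is consistent with its definition and degenerate cases", {
  set.seed(303)
  obs <- random_lot(rho = 0.1)
  fit <- fit_probit(obs, "single_lot")
  # recompute phi from the reported residuals
  y <- fit$response; mu <- fit$fitted; w <- fit$weights
  phi <- sum(w * (y - mu)^2 / (mu * (1 - mu))) / fit$residual_df
  expect_equal(dispersion_pearson(fit), phi)
  # perfect fit: phi = 0
  fit0 <- fit_probit(noiseless_lot(2, -0.1), "single_lot")
  expect_equal(dispersion_pearson(fit0), 0, tolerance = 1e-12)
})

test_that("mean dispersion is near 1 for binomial data and inflated for beta-binomial", {
  set.seed(404)
  phi_binom <- replicate(300, {
    dispersion_pearson(fit_probit(random_lot(ki = 2, sigma = 20), "single_lot"))
  })
  expect_equal(mean(phi_binom), 1, tolerance = 0.06)
  # intraclass correlation rho inflates phi towards 1 + rho (n - 1) = 3.9
  phi_bb <- replicate(300, {
    dispersion_pearson(fit_probit(random_lot(ki = 2, sigma = 20, rho = 0.1),
                                  "single_lot"))
  })
  expect_equal(mean(phi_bb), 1 + 0.1 * 29, tolerance = 0.12 * 3.9)
})

test_that("the Wald slope test matches the t distribution and is scale invariant", {
  fake <- structure(list(
    coefficients = c(ki = 2, slope = -0.1),
    covariance = diag(c(0.1^2, 0.02^2)), residual_df = 28L, converged = TRUE
  ), class = "probit_fit")
  wt <- slope_wald_test(fake, "slope")
  expect_equal(wt$statistic, -5)
  expect_equal(wt$p_value, 2 * pt(-5, 28))
  expect_lt(wt$p_value, 0.001)
  # beta = 0 gives p = 1
  fake$coefficients["slope"] <- 0
  expect_equal(slope_wald_test(fake, "slope")$p_value, 1)
  # rescaling time (days -> hours) leaves the p-value unchanged
  set.seed(505)
  obs <- random_lot(rho = 0.05)
  obs_h <- transform(obs, aging_days = aging_days * 24)
  p_d <- slope_wald_test(fit_probit(obs, "single_lot"), "slope")$p_value
  p_h <- slope_wald_test(fit_probit(obs_h, "single_lot"), "slope")$p_value
  expect_equal(p_d, p_h, tolerance = 1e-8)
})

test_that("complete separation and degenerate responses are flagged, not estimated", {
  t <- seq(0, 70, by = 10)
  all_dead <- data.frame(lot_id = "L1", species_id = "S1", aging_days = t,
                         replicate_id = paste0("r", seq_along(t)),
                         n_seeds = 30, n_germinated = 0)
  fit <- fit_probit(all_dead, "single_lot")
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation")
  expect_error(sigma_from_fit(fit), "converge")
})

test_that("rank-deficient designs are rejected up front", {
  obs <- noiseless_lot(2, -0.1, t = c(0, 0, 0))
  obs$replicate_id <- paste0("r", 1:3)
  expect_error(fit_probit(obs, "single_lot"), "rank deficiency")
  two <- rbind(noiseless_lot(2, -0.1, lot_id = "A"),
               noiseless_lot(2, -0.05, t = c(0, 0, 0), lot_id = "B"))
  two$replicate_id <- paste0("r", seq_len(nrow(two)))
  expect_error(fit_probit(two, "lot_intercepts_lot_slopes"), "lot 'B'")
})

test_that("the nested quasi-F test behaves at its boundaries", {
  set.seed(606)
  obs <- rbind(random_lot(ki = 2, sigma = 15, lot_id = "A"),
               random_lot(ki = 2, sigma = 30, lot_id = "B"))
  full <- fit_probit(obs, "lot_intercepts_lot_slopes")
  reduced <- fit_probit(obs, "lot_intercepts_common_slope")
  # same model compared with itself: F = 0, p = 1
  same <- nested_f_test(full, full)
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)
  ft <- nested_f_test(full, reduced)
  expect_equal(ft$df_num, 1L)
  expect_equal(ft$df_den, full$residual_df)
  expect_gte(ft$p_value, 0)
  # non-nested orders rejected
  expect_error(nested_f_test(reduced, full), "more coefficients|not nested")
})

test_that("the lot-by-duration test has power against a 10 vs 40 day contrast", {
  set.seed(707)
  rejections <- replicate(200, {
    obs <- rbind(random_lot(ki = 2, sigma = 10, rho = 0.05, lot_id = "A"),
                 random_lot(ki = 2, sigma = 40, rho = 0.05, lot_id = "B"))
    full <- fit_probit(obs, "lot_intercepts_lot_slopes")
    reduced <- fit_probit(obs, "lot_intercepts_common_slope")
    nested_f_test(full, reduced)$p_value < 0.05
  })
  expect_gt(mean(rejections), 0.9)
})
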