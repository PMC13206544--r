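# Random-intercept linear mixed model for ln(sigma) on seed-lot predictors,
# fitted by REML via one-dimensional profiling of the variance ratio
# lambda = var(species intercept) / var(residual). For a random-intercept
# model V(lambda) = I + lambda * J within each species block, so V^-1,
# log|V| and the GLS quantities have closed forms and the whole REML
# criterion reduces to a smooth 1-D optimisation. lme4 is used only as an
# independent cross-check in the tests.

#' Centre and standardise values within groups
#'
#' Per group: (x - group mean) / group sample SD (denominator n - 1). Groups
#' whose SD is zero get all members set to 0 with a warning. Groups of size
#' one are an error: callers must pre-filter to groups with at least two
#' members (as the lot-level mixed model does for species).
#'
#' @param values Numeric vector.
#' @param groups Group identifiers, same length.
#' @return Scaled numeric vector.
#' @export
scale_within_group <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- rep(NA_real_, length(values))
  for (g in unique(groups)) {
    i <- which(groups == g & !is.na(values))
    if (length(i) < 2L) {
      stop(sprintf("group '%s' has fewer than 2 non-missing values", g),
           call. = FALSE)
    }
    s <- stats::sd(values[i])
    if (s == 0) {
      warning(sprintf("group '%s' has zero SD: scaled values set to 0", g))
      out[i] <- 0
    } else {
      out[i] <- (values[i] - mean(values[i])) / s
    }
  }
  out
}

# REML machinery. Group-blocked computations: for group i with n_i members,
# V_i = I + lambda J, V_i^-1 = I - c_i J with c_i = lambda / (1 + n_i lambda),
# log|V_i| = log(1 + n_i lambda).
.reml_quantities <- function(lambda, y, X, gindex, gsizes) {
  c_g <- lambda / (1 + gsizes * lambda)
  Xs <- rowsum(X, gindex)           # group sums of columns
  ys <- rowsum(y, gindex)
  A <- crossprod(X) - crossprod(Xs * sqrt(c_g))
  b <- crossprod(X, y) - crossprod(Xs, c_g * ys)
  yy <- sum(y^2) - sum(c_g * ys^2)
  beta <- solve(A, b)
  Q <- drop(yy - 2 * crossprod(beta, b) + crossprod(beta, A %*% beta))
  list(A = A, beta = drop(beta), Q = max(Q, 1e-300),
       logdetV = sum(log1p(gsizes * lambda)),
       logdetA = determinant(A, logarithm = TRUE)$modulus)
}

.reml_criterion <- function(lambda, y, X, gindex, gsizes) {
  n <- length(y); p <- ncol(X)
  q <- .reml_quantities(lambda, y, X, gindex, gsizes)
  (n - p) * log(q$Q) + q$logdetV + as.numeric(q$logdetA)
}

.reml_fit <- function(y, X, group, var_ratio = NULL) {
  group <- factor(group)
  gindex <- as.integer(group)
  gsizes <- as.numeric(table(group))
  n <- length(y); p <- ncol(X)
  if (is.null(var_ratio)) {
    f <- function(l) .reml_criterion(l, y, X, gindex, gsizes)
    opt <- stats::optimize(f, interval = c(0, 1e4), tol = 1e-9)
    lambda <- if (f(0) <= opt$objective) 0 else opt$minimum
  } else {
    lambda <- var_ratio
  }
  q <- .reml_quantities(lambda, y, X, gindex, gsizes)
  sigma2_e <- q$Q / (n - p)
  cov_beta <- sigma2_e * solve(q$A)
  # l_R = -1/2 [(n-p)(log(2 pi sigma_e^2) + 1) + log|V| + log|X'V^-1 X|]
  # (the p*log(sigma_e^2) from log|X'V*^-1X| cancels against n vs n-p in log|V*|)
  reml_loglik <- -0.5 * ((n - p) * (log(2 * pi * sigma2_e) + 1) +
                           q$logdetV + as.numeric(q$logdetA))
  list(beta = q$beta, cov_beta = cov_beta, lambda = lambda,
       sigma2_u = lambda * sigma2_e, sigma2_e = sigma2_e,
       reml_loglik = reml_loglik, n = n, p = p,
       n_groups = nlevels(group), singular = lambda < 1e-8,
       fitted_fixed = drop(X %*% q$beta))
}

#' Mixed model of seed-lot longevity on lot-level predictors
#'
#' Fits ln(sigma) (or sigma) of each retained seed lot against the
#' within-species-scaled 1000-seed mass, mean annual temperature and annual
#' precipitation at the lot origin, with a species random intercept. Variance
#' components by REML (one-dimensional profiling of the variance ratio);
#' fixed effects by generalised least squares at the REML optimum; type-III
#' Wald chi-squared per covariate (each continuous, so df = 1); marginal and
#' conditional R-squared per [r2_nakagawa()]. Only species with at least two
#' lots enter, and lots missing any covariate are dropped listwise (a message
#' reports the count). A boundary fit (zero species variance) is reported
#' with `singular = TRUE`, not an error.
#'
#' @param sigma_table Data frame with columns `lot_id`, `species_id`,
#'   `sigma_days` (e.g. the `retained` table of [screen_dataset()]).
#' @param metadata Lot metadata with `thousand_seed_mass_g`, `mat_c`, `map_mm`.
#' @param log_response Model ln(sigma) (default) or plain sigma.
#' @param var_ratio Fix the variance ratio var_species/var_residual instead
#'   of estimating it (0 reproduces ordinary least squares); `NULL` estimates
#'   it by REML.
#' @param condition_cap Error when the fixed-design condition number exceeds
#'   this (collinear covariates).
#' @return An object of class `seed_lmm`: `fixed_effects` (estimate, se),
#'   `random_intercept_variance`, `residual_variance`, `reml_loglik`,
#'   `type3_tests` (chi2, df, p per term), `r2_marginal`, `r2_conditional`,
#'   `n_obs`, `n_groups`, `singular`, `dropped_missing`, `data` (the model
#'   frame used).
#' @export
fit_lot_predictor_lmm <- function(sigma_table, metadata, log_response = TRUE,
                                  var_ratio = NULL, condition_cap = 1e8) {
  metadata <- validate_lot_metadata(metadata)
  df <- merge(sigma_table[, c("lot_id", "species_id", "sigma_days")],
              metadata[, c("lot_id", "thousand_seed_mass_g", "mat_c", "map_mm")],
              by = "lot_id")
  df <- df[!is.na(df$sigma_days), , drop = FALSE]
  complete <- stats::complete.cases(
    df[, c("thousand_seed_mass_g", "mat_c", "map_mm")])
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(sprintf("dropping %d lot(s) with missing covariates", dropped))
  }
  df <- df[complete, , drop = FALSE]
  tab <- table(df$species_id)
  df <- df[df$species_id %in% names(tab)[tab >= 2L], , drop = FALSE]
  if (length(unique(df$species_id)) < 2L) {
    stop("need at least 2 species with at least 2 retained lots each",
         call. = FALSE)
  }
  df$mass_scaled <- scale_within_group(df$thousand_seed_mass_g, df$species_id)
  y <- if (log_response) log(df$sigma_days) else df$sigma_days
  X <- cbind(`(Intercept)` = 1, mass_scaled = df$mass_scaled,
             mat_c = df$mat_c, map_mm = df$map_mm)
  Xs <- X
  for (j in 2:ncol(Xs)) Xs[, j] <- scale(Xs[, j])
  if (kappa(Xs, exact = TRUE) > condition_cap) {
    stop("collinear covariates: condition number exceeds the cap", call. = FALSE)
  }
  fit <- .reml_fit(y, X, df$species_id, var_ratio = var_ratio)
  if (fit$singular) {
    warning("singular fit: species random-intercept variance estimated at 0")
  }
  se <- sqrt(diag(fit$cov_beta))
  fixed <- data.frame(term = colnames(X), estimate = fit$beta, se = se,
                      row.names = NULL, stringsAsFactors = FALSE)
  terms <- colnames(X)[-1L]
  chi2 <- (fit$beta[-1L] / se[-1L])^2
  type3 <- data.frame(
    term = terms, chi2 = unname(chi2), df = 1L,
    p = stats::pchisq(unname(chi2), df = 1L, lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  r2 <- r2_nakagawa(fit$fitted_fixed, fit$sigma2_u, fit$sigma2_e)
  structure(
    list(
      fixed_effects = fixed,
      random_intercept_variance = fit$sigma2_u,
      residual_variance = fit$sigma2_e,
      variance_ratio = fit$lambda,
      reml_loglik = fit$reml_loglik,
      type3_tests = type3,
      r2_marginal = r2[["r2_marginal"]], r2_conditional = r2[["r2_conditional"]],
      n_obs = fit$n, n_groups = fit$n_groups, singular = fit$singular,
      dropped_missing = dropped, log_response = log_response,
      data = df
    ),
    class = "seed_lmm"
  )
}

#' @export
print.seed_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept LMM of %s on lot predictors: %d lots, %d species\n",
              if (x$log_response) "ln(sigma)" else "sigma", x$n_obs, x$n_groups))
  print(transform(x$fixed_effects, estimate = round(estimate, 4),
                  se = round(se, 4)))
  cat(sprintf("variances: species %.4f, residual %.4f%s\n",
              x$random_intercept_variance, x$residual_variance,
              if (x$singular) " [singular]" else ""))
  cat("type-III Wald tests:\n")
  print(transform(x$type3_tests, chi2 = round(chi2, 3), p = signif(p, 3)))
  cat(sprintf("R2 marginal = %.3f, conditional = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Marginal and conditional R-squared for a random-intercept model
#'
#' Variance-component decomposition: with sf2 the variance (over
#' observations) of the fixed-effects linear predictor, marginal R2 =
#' sf2 / (sf2 + var_random + var_residual) and conditional R2 =
#' (sf2 + var_random) / (same denominator).
#'
#' @param fitted_fixed Either a `seed_lmm` object or the numeric vector of
#'   fixed-effect fitted values.
#' @param sigma2_u,sigma2_e Random-intercept and residual variances (ignored
#'   when a `seed_lmm` is given).
#' @return Named vector `r2_marginal`, `r2_conditional`.
#' @export
r2_nakagawa <- function(fitted_fixed, sigma2_u = NULL, sigma2_e = NULL) {
  if (inherits(fitted_fixed, "seed_lmm")) {
    x <- fitted_fixed
    return(c(r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional))
  }
  sf2 <- stats::var(fitted_fixed)
  tot <- sf2 + sigma2_u + sigma2_e
  c(r2_marginal = sf2 / tot, r2_conditional = (sf2 + sigma2_u) / tot)
}

#' Within-species share of explained variance
#'
#' The contribution of the lot-level (within-species) predictors relative to
#' the variance remaining after accounting for species identity:
#' R2_marginal / (1 - (R2_conditional - R2_marginal)).
#'
#' @param r2_marginal,r2_conditional Marginal and conditional R-squared.
#' @return A proportion.
#' @export
within_species_share <- function(r2_marginal, r2_conditional) {
  stopifnot(r2_marginal >= 0, r2_conditional >= r2_marginal, r2_conditional <= 1)
  denom <- 1 - (r2_conditional - r2_marginal)
  if (denom <= 0) stop("denominator <= 0: species share saturates", call. = FALSE)
  r2_marginal / denom
}

#' Species-identity share of total variance
#'
#' R2_conditional - R2_marginal: the fraction of total lot-level variance
#' attributed to the species random intercept.
#'
#' @inheritParams within_species_share
#' @return A proportion.
#' @export
species_share <- function(r2_marginal, r2_conditional) {
  stopifnot(r2_marginal >= 0, r2_conditional >= r2_marginal, r2_conditional <= 1)
  r2_conditional - r2_marginal
}
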