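# Quasibinomial probit regression engine.
#
# The fit is a binomial-likelihood probit regression estimated by iteratively
# reweighted least squares (IRLS) with the seed counts as prior weights;
# overdispersion is handled quasi-likelihood style by scaling the coefficient
# covariance with the Pearson dispersion. This is the package's own engine
# (stats::glm is used only as an independent cross-check in the test suite).

#' Probit transform (normal equivalent deviate)
#'
#' Maps a proportion to the standard-normal quantile scale, linearising
#' sigmoid viability decay. No +5 offset is used, so an intercept is directly
#' the initial viability Ki in probits and p50 = Ki * sigma holds exactly.
#'
#' @param p Probability strictly between 0 and 1.
#' @return The normal equivalent deviate, `qnorm(p)`.
#' @seealso [inv_probit()]
#' @export
probit <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("probit() requires probabilities strictly inside (0, 1)", call. = FALSE)
  }
  stats::qnorm(p)
}

#' Inverse probit transform
#'
#' @param x Value on the probit (normal equivalent deviate) scale.
#' @return `pnorm(x)`.
#' @export
inv_probit <- function(x) stats::pnorm(x)

# Design-matrix kinds. Per-lot parameterisation (one intercept column per lot,
# and for "lot_intercepts_lot_slopes" one slope column per lot) so that Ki and
# slope coefficients can be read off directly.
.design_kinds <- c("single_lot", "lot_intercepts_common_slope",
                   "lot_intercepts_lot_slopes")

.build_design <- function(obs, kind, lot_order = NULL) {
  kind <- match.arg(kind, .design_kinds)
  lots <- if (is.null(lot_order)) unique(obs$lot_id) else as.character(lot_order)
  if (!setequal(lots, unique(obs$lot_id))) {
    stop("`lot_order` must list exactly the lots present in the data", call. = FALSE)
  }
  t <- obs$aging_days
  if (kind == "single_lot") {
    if (length(lots) != 1L) {
      stop("design kind 'single_lot' requires exactly one lot", call. = FALSE)
    }
    if (length(unique(t)) < 2L) {
      stop("rank deficiency: need at least 2 distinct aging durations", call. = FALSE)
    }
    X <- cbind(ki = 1, slope = t)
  } else {
    f <- factor(obs$lot_id, levels = lots)
    Z <- stats::model.matrix(~ 0 + f)
    colnames(Z) <- paste0("ki:", lots)
    if (kind == "lot_intercepts_common_slope") {
      if (length(unique(t)) < 2L) {
        stop("rank deficiency: need at least 2 distinct aging durations", call. = FALSE)
      }
      X <- cbind(Z, slope = t)
    } else {
      for (l in lots) {
        if (length(unique(t[obs$lot_id == l])) < 2L) {
          stop(sprintf(
            "rank deficiency: lot '%s' has fewer than 2 distinct aging durations", l),
            call. = FALSE)
        }
      }
      S <- Z * t
      colnames(S) <- paste0("slope:", lots)
      X <- cbind(Z, S)
    }
  }
  list(X = X, kind = kind, lot_order = lots)
}

.binomial_deviance <- function(y, mu, w) {
  # y, mu proportions; w seed counts. 0*log(0) treated as 0.
  term <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
  2 * sum(w * (term(y, mu) + term(1 - y, 1 - mu)))
}

#' Fit a probit viability-decay regression
#'
#' Fits germinated/sown counts against ageing duration on the probit scale by
#' IRLS with seed counts as weights. Three design kinds are supported:
#' `"single_lot"` (one intercept Ki, one slope), `"lot_intercepts_common_slope"`
#' (per-lot Ki, shared slope; the species-level model), and
#' `"lot_intercepts_lot_slopes"` (per-lot Ki and per-lot slope; the full model
#' whose comparison with the common-slope model tests slope heterogeneity).
#' The coefficient covariance is `(X'WX)^-1` scaled by the Pearson dispersion,
#' the quasibinomial convention.
#'
#' @param obs Data frame with columns `lot_id`, `aging_days`, `n_seeds`,
#'   `n_germinated` (one row per replicate dish).
#' @param kind Design kind, see above.
#' @param lot_order Optional explicit ordering of lot identifiers.
#' @param max_iter,eta_cap,tol IRLS controls: iteration cap, bound on the
#'   absolute linear predictor, and relative deviance-change tolerance.
#' @return An object of class `probit_fit` with elements `coefficients`,
#'   `covariance` (dispersion-scaled), `cov_unscaled`, `dispersion_phi`,
#'   `deviance`, `pearson_chi2`, `residual_df`, `n_obs`, `fitted`, `converged`,
#'   `diagnostic`, `kind`, `lot_order`.
#' @export
fit_probit <- function(obs, kind = c("single_lot", "lot_intercepts_common_slope",
                                     "lot_intercepts_lot_slopes"),
                       lot_order = NULL, max_iter = 100L, eta_cap = 8,
                       tol = 1e-10) {
  kind <- match.arg(kind)
  .require_cols(obs, c("lot_id", "aging_days", "n_seeds", "n_germinated"),
                "probit fit input")
  d <- .build_design(obs, kind, lot_order)
  X <- d$X
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 1L) {
    stop(sprintf("need at least %d observations to fit %d coefficients", p + 1L, p),
         call. = FALSE)
  }
  w <- as.numeric(obs$n_seeds)
  y <- as.numeric(obs$n_germinated) / w

  mu <- (obs$n_germinated + 0.5) / (obs$n_seeds + 1)
  eta <- stats::qnorm(mu)
  eta <- pmin(pmax(eta, -eta_cap), eta_cap)
  dev <- .binomial_deviance(y, stats::pnorm(eta), w)
  beta <- NULL
  converged <- FALSE
  diagnostic <- NA_character_
  escaped <- FALSE

  for (iter in seq_len(max_iter)) {
    mu <- stats::pnorm(eta)
    dmu <- stats::dnorm(eta)
    vmu <- mu * (1 - mu)
    Wt <- w * dmu^2 / vmu
    z <- eta + (y - mu) / dmu
    fit <- stats::lm.wfit(x = X, y = z, w = Wt)
    if (any(is.na(fit$coefficients))) {
      stop("rank deficiency: design matrix is singular for these data", call. = FALSE)
    }
    beta <- fit$coefficients
    eta_raw <- drop(X %*% beta)
    escaped <- any(abs(eta_raw) > eta_cap)
    eta <- pmin(pmax(eta_raw, -eta_cap), eta_cap)
    dev_new <- .binomial_deviance(y, stats::pnorm(eta), w)
    if (abs(dev_new - dev) < tol * (abs(dev) + 0.1)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged) diagnostic <- "iteration cap reached"
  if (converged && escaped) {
    converged <- FALSE
    diagnostic <- "linear predictor at stability cap (separation or degenerate response)"
  }
  if (all(y == 0) || all(y == 1)) {
    converged <- FALSE
    diagnostic <- "complete separation: all-zero or all-full germination"
  }

  mu <- stats::pnorm(eta)
  dmu <- stats::dnorm(eta)
  vmu <- mu * (1 - mu)
  Wt <- w * dmu^2 / vmu
  XtWX <- crossprod(X * sqrt(Wt))
  cov_unscaled <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
    solve(XtWX)
  })
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  pearson <- sum(w * (y - mu)^2 / vmu)
  residual_df <- n - p
  phi <- if (residual_df >= 1L) pearson / residual_df else NA_real_

  structure(
    list(
      coefficients = beta,
      covariance = if (is.na(phi)) cov_unscaled * NA_real_ else phi * cov_unscaled,
      cov_unscaled = cov_unscaled,
      dispersion_phi = phi,
      deviance = dev,
      pearson_chi2 = pearson,
      residual_df = residual_df,
      n_obs = n,
      fitted = mu,
      linear_predictor = eta,
      weights = w,
      response = y,
      converged = converged,
      diagnostic = diagnostic,
      kind = kind,
      lot_order = d$lot_order
    ),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit viability fit (%s), %d obs, %d coefficients\n",
              x$kind, x$n_obs, length(x$coefficients)))
  print(round(x$coefficients, 6))
  cat(sprintf("dispersion phi = %.4f, deviance = %.4f, converged: %s\n",
              x$dispersion_phi, x$deviance, x$converged))
  invisible(x)
}

#' Pearson dispersion of a probit fit
#'
#' The quasi-likelihood variance-inflation factor: Pearson chi-squared over
#' residual degrees of freedom. Values near 1 indicate binomial sampling
#' noise; beta-binomial replicate heterogeneity with intraclass correlation
#' rho and dish size n inflates it towards 1 + rho (n - 1).
#'
#' @param fit A [fit_probit()] result.
#' @return The dispersion estimate; `NA` (with a warning) when residual
#'   degrees of freedom are zero.
#' @export
dispersion_pearson <- function(fit) {
  stopifnot(inherits(fit, "probit_fit"))
  if (fit$residual_df < 1L) {
    warning("dispersion undefined: zero residual degrees of freedom")
    return(NA_real_)
  }
  fit$pearson_chi2 / fit$residual_df
}

#' Wald t test for one coefficient
#'
#' t = estimate / (dispersion-scaled standard error), two-sided p from the
#' t distribution with the fit's residual degrees of freedom.
#'
#' @param fit A converged [fit_probit()] result.
#' @param coefficient Coefficient name or index.
#' @return List with `statistic`, `se`, `df`, `p_value`.
#' @export
slope_wald_test <- function(fit, coefficient) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!fit$converged) stop("fit did not converge; Wald test unavailable", call. = FALSE)
  b <- fit$coefficients[coefficient]
  if (length(b) != 1L || is.na(b)) {
    stop("unknown coefficient: ", coefficient, call. = FALSE)
  }
  idx <- if (is.character(coefficient)) match(coefficient, names(fit$coefficients)) else coefficient
  se <- sqrt(fit$covariance[idx, idx])
  if (!is.finite(se) || se <= 0) {
    warning("standard error is zero or undefined; p-value flagged NA")
    return(list(statistic = NA_real_, se = se, df = fit$residual_df,
                p_value = NA_real_))
  }
  t <- unname(b / se)
  list(statistic = t, se = unname(se), df = fit$residual_df,
       p_value = 2 * stats::pt(-abs(t), df = fit$residual_df))
}

#' Nested quasi-F test between two probit fits
#'
#' Compares a full and a reduced (column-subspace) design on the same
#' observations: F = ((dev_reduced - dev_full) / df_num) / phi_full, with
#' phi_full the full model's Pearson dispersion; the p-value comes from the
#' F distribution with (df_num, full residual df). This is the standard
#' quasibinomial nested-model comparison; applied to per-lot-slope versus
#' common-slope designs it tests slope (sigma) heterogeneity among lots.
#'
#' @param full,reduced [fit_probit()] results on the same observations, with
#'   the reduced design nested in the full one.
#' @return List with `F`, `df_num`, `df_den`, `p_value`, `phi`.
#' @export
nested_f_test <- function(full, reduced) {
  stopifnot(inherits(full, "probit_fit"), inherits(reduced, "probit_fit"))
  nested_pairs <- list(
    c("lot_intercepts_common_slope", "single_lot"),
    c("lot_intercepts_lot_slopes", "lot_intercepts_common_slope"),
    c("lot_intercepts_lot_slopes", "single_lot")
  )
  same_kind <- identical(full$kind, reduced$kind)
  ok <- same_kind || any(vapply(nested_pairs, function(pr) {
    identical(pr[1L], full$kind) && identical(pr[2L], reduced$kind)
  }, logical(1)))
  if (!ok || !setequal(full$lot_order, reduced$lot_order)) {
    stop("`reduced` is not nested in `full`", call. = FALSE)
  }
  if (full$n_obs != reduced$n_obs) {
    stop("full and reduced fits must use the same observations", call. = FALSE)
  }
  df_num <- length(full$coefficients) - length(reduced$coefficients)
  if (df_num < 0L) stop("`reduced` has more coefficients than `full`", call. = FALSE)
  ddev <- reduced$deviance - full$deviance
  if (ddev < -1e-6 * (abs(full$deviance) + 1)) {
    stop("reduced-model deviance below full-model deviance: convergence failure",
         call. = FALSE)
  }
  ddev <- max(ddev, 0)
  if (df_num == 0L) {
    return(list(F = 0, df_num = 0L, df_den = full$residual_df, p_value = 1,
                phi = full$dispersion_phi))
  }
  phi <- full$dispersion_phi
  if (!is.finite(phi) || phi < 0) {
    stop("full-model dispersion is undefined; F test unavailable", call. = FALSE)
  }
  # a perfect full-model fit (phi = 0) gives an infinite F when the reduced
  # model fits worse, and F = 0 when it fits equally well
  Fstat <- if (phi == 0) {
    if (ddev > 0) Inf else 0
  } else {
    (ddev / df_num) / phi
  }
  list(F = Fstat, df_num = df_num, df_den = full$residual_df,
       p_value = stats::pf(Fstat, df_num, full$residual_df, lower.tail = FALSE),
       phi = phi)
}
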