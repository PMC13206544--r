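# Longevity transforms: sigma = -1/slope, Ki, p50 and their intervals.

.slope_name <- function(fit, lot_id = NULL) {
  switch(fit$kind,
         single_lot = "slope",
         lot_intercepts_common_slope = "slope",
         lot_intercepts_lot_slopes = {
           if (is.null(lot_id)) {
             stop("`lot_id` is required for a per-lot-slope fit", call. = FALSE)
           }
           paste0("slope:", lot_id)
         })
}

.ki_name <- function(fit, lot_id = NULL) {
  if (fit$kind == "single_lot") return("ki")
  if (is.null(lot_id)) return(NULL)
  paste0("ki:", lot_id)
}

#' Seed longevity (sigma) from a probit fit
#'
#' Back-transforms the probit slope into sigma = -1/slope, the number of
#' ageing days needed for viability to fall by one probit. The confidence
#' interval applies x -> -1/x to the endpoints of the slope's t-based Wald
#' interval (the map is monotone on the negative half-line, so endpoint order
#' is preserved); it is flagged undefined when the slope interval reaches 0.
#' A non-negative slope yields an undefined sigma, never a negative longevity.
#'
#' @param fit A converged [fit_probit()] result.
#' @param lot_id Lot whose slope/intercept to use; required for per-lot-slope
#'   fits, optional otherwise. For multi-lot common-slope fits with no
#'   `lot_id`, `ki_probits` is the mean of the per-lot intercepts.
#' @param confidence_level Coverage of the slope interval (default 0.95).
#' @return An object of class `sigma_estimate`: `sigma_days`, `ci_low_days`,
#'   `ci_high_days`, `slope`, `slope_se`, `slope_p`, `ki_probits`, `ki_pct`,
#'   `defined`, `flag`.
#' @export
sigma_from_fit <- function(fit, lot_id = NULL, confidence_level = 0.95) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!fit$converged) {
    stop("fit did not converge; sigma unavailable", call. = FALSE)
  }
  sl_name <- .slope_name(fit, lot_id)
  if (!sl_name %in% names(fit$coefficients)) {
    stop("slope coefficient not found: ", sl_name, call. = FALSE)
  }
  wt <- slope_wald_test(fit, sl_name)
  slope <- unname(fit$coefficients[sl_name])

  ki_name <- .ki_name(fit, lot_id)
  ki <- if (is.null(ki_name)) {
    mean(fit$coefficients[startsWith(names(fit$coefficients), "ki:")])
  } else {
    unname(fit$coefficients[ki_name])
  }

  out <- list(
    sigma_days = NA_real_, ci_low_days = NA_real_, ci_high_days = NA_real_,
    slope = slope, slope_se = wt$se, slope_p = wt$p_value,
    ki_probits = ki, ki_pct = 100 * stats::pnorm(ki),
    confidence_level = confidence_level,
    defined = FALSE, flag = NA_character_, lot_id = lot_id
  )
  if (!is.finite(slope) || slope >= 0) {
    out$flag <- "non-negative slope: no viability decay, sigma undefined"
    class(out) <- "sigma_estimate"
    return(out)
  }
  out$sigma_days <- -1 / slope
  out$defined <- TRUE
  tq <- stats::qt(1 - (1 - confidence_level) / 2, df = fit$residual_df)
  lo <- slope - tq * wt$se
  hi <- slope + tq * wt$se
  if (is.finite(hi) && hi < 0) {
    out$ci_low_days <- -1 / lo
    out$ci_high_days <- -1 / hi
  } else {
    out$flag <- "slope interval reaches 0: sigma CI undefined"
  }
  class(out) <- "sigma_estimate"
  out
}

#' @export
print.sigma_estimate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("sigma = %.2f days", x$sigma_days))
    if (is.finite(x$ci_low_days)) {
      cat(sprintf(" (%.0f%% CI %.2f-%.2f)", 100 * x$confidence_level,
                  x$ci_low_days, x$ci_high_days))
    }
    cat(sprintf("; Ki = %.2f probits (%.1f%%); slope p = %.3g\n",
                x$ki_probits, x$ki_pct, x$slope_p))
  } else {
    cat("sigma undefined:", x$flag, "\n")
  }
  invisible(x)
}

#' Time to 50% viability
#'
#' On the normal-equivalent-deviate probit scale the viability probit is
#' Ki + slope * t, so it crosses 0 (i.e. 50% viability) at
#' p50 = Ki * sigma. p50 is non-positive when Ki <= 0 (initial viability at
#' or below 50%); a warning flags that case.
#'
#' @param ki_probits Initial viability on the probit scale.
#' @param sigma_days Rate of viability loss, days per probit (> 0).
#' @return p50 in days.
#' @export
p50 <- function(ki_probits, sigma_days) {
  if (any(!is.finite(sigma_days) | sigma_days <= 0)) {
    stop("`sigma_days` must be positive", call. = FALSE)
  }
  out <- ki_probits * sigma_days
  if (any(ki_probits <= 0)) {
    warning("Ki <= 0 (initial viability <= 50%): p50 is non-positive")
  }
  out
}
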