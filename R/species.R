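# Within-species analyses: slope-heterogeneity tests between seed lots,
# the per-species common-slope sigma, and the detection-probability model.

#' Test sigma differences between seed lots of one species
#'
#' Fits the full model (per-lot intercepts and per-lot slopes) and the
#' reduced model (per-lot intercepts, one shared slope) on the species'
#' retained lots and compares them with the nested quasi-F test. A
#' significant lot-by-duration interaction means the lots lose viability at
#' different rates, i.e. have different sigma.
#'
#' @param obs Germination observations of one species, restricted to retained
#'   lots (at least two lots, each with at least two distinct durations).
#' @param alpha Significance threshold for the interaction (default 0.05).
#' @param confidence_level Coverage for the sigma intervals.
#' @return An object of class `species_comparison`: `species_id`, `n_lots`,
#'   `interaction_F`, `df_num`, `df_den`, `p_value`, `significant`,
#'   `lot_sigmas` (named list of per-lot sigma estimates from the full
#'   model), `species_sigma` (from the reduced model).
#' @export
test_lot_differences <- function(obs, alpha = 0.05, confidence_level = 0.95) {
  species_id <- unique(obs$species_id)
  if (length(species_id) != 1L) {
    stop("`obs` must contain a single species", call. = FALSE)
  }
  lots <- unique(obs$lot_id)
  if (length(lots) < 2L) {
    stop("need at least two retained lots to compare", call. = FALSE)
  }
  for (l in lots) {
    if (length(unique(obs$aging_days[obs$lot_id == l])) < 2L) {
      stop(sprintf("lot '%s' has fewer than 2 distinct aging durations", l),
           call. = FALSE)
    }
  }
  full <- fit_probit(obs, kind = "lot_intercepts_lot_slopes", lot_order = lots)
  reduced <- fit_probit(obs, kind = "lot_intercepts_common_slope",
                        lot_order = lots)
  ft <- nested_f_test(full, reduced)
  lot_sigmas <- stats::setNames(
    lapply(lots, function(l) sigma_from_fit(full, lot_id = l,
                                            confidence_level = confidence_level)),
    lots
  )
  structure(
    list(
      species_id = species_id, n_lots = length(lots),
      interaction_F = ft$F, df_num = ft$df_num, df_den = ft$df_den,
      p_value = ft$p_value, significant = ft$p_value < alpha,
      lot_sigmas = lot_sigmas,
      species_sigma = sigma_from_fit(reduced, lot_id = NULL,
                                     confidence_level = confidence_level),
      full_fit = full, reduced_fit = reduced
    ),
    class = "species_comparison"
  )
}

#' @export
print.species_comparison <- function(x, ...) {
  cat(sprintf("Species %s: %d lots, interaction F(%d, %d) = %.3f, p = %.4g%s\n",
              x$species_id, x$n_lots, x$df_num, x$df_den, x$interaction_F,
              x$p_value, if (x$significant) " *" else ""))
  if (x$species_sigma$defined) {
    cat(sprintf("  common-slope sigma = %.2f days\n", x$species_sigma$sigma_days))
  }
  invisible(x)
}

#' Species-level sigma estimate
#'
#' One sigma per species from all its retained lots: a plain single-lot fit
#' when only one lot is available, otherwise a common-slope fit with per-lot
#' intercepts (so lots may differ in initial viability Ki but share the decay
#' rate).
#'
#' @param obs Germination observations of one species, retained lots only.
#' @param confidence_level Coverage for the sigma interval.
#' @return A `sigma_estimate`.
#' @export
fit_species_sigma <- function(obs, confidence_level = 0.95) {
  if (length(unique(obs$species_id)) != 1L) {
    stop("`obs` must contain a single species", call. = FALSE)
  }
  kind <- if (length(unique(obs$lot_id)) == 1L) "single_lot" else
    "lot_intercepts_common_slope"
  fit <- fit_probit(obs, kind = kind)
  sigma_from_fit(fit, lot_id = NULL, confidence_level = confidence_level)
}

#' Detection probability of within-species sigma differences
#'
#' Logistic-link binomial regression of whether a species showed a
#' significant lot-by-duration interaction (yes/no) on its number of seed
#' lots. Reports the Wald p of the slope plus McFadden and Nagelkerke
#' pseudo-R-squared.
#'
#' @param comparisons List of [test_lot_differences()] results, or a data
#'   frame with columns `species_id`, `n_lots`, `significant`.
#' @return An object of class `detection_model`: `intercept`, `slope`,
#'   `slope_p`, `pseudo_r2_mcfadden`, `pseudo_r2_nagelkerke`, `n_species`,
#'   `separation` flag, and the underlying `glm` fit.
#' @export
detection_probability_model <- function(comparisons) {
  df <- if (is.data.frame(comparisons)) comparisons else {
    do.call(rbind, lapply(comparisons, function(x) {
      data.frame(species_id = x$species_id, n_lots = x$n_lots,
                 significant = x$significant, stringsAsFactors = FALSE)
    }))
  }
  if (nrow(df) < 3L) stop("need at least 3 species", call. = FALSE)
  if (length(unique(df$n_lots)) < 2L) {
    stop("`n_lots` must vary across species", call. = FALSE)
  }
  y <- as.logical(df$significant)
  if (all(y) || all(!y)) {
    stop("all species have the same outcome: detection model undefined",
         call. = FALSE)
  }
  m <- stats::glm(y ~ n_lots, data = df, family = stats::binomial())
  sm <- summary(m)
  mu <- stats::fitted(m)
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(stats::coef(m)) > 20)
  if (separation) {
    warning("quasi-complete separation detected: coefficients unreliable")
  }
  n <- nrow(df)
  dev <- m$deviance
  dev0 <- m$null.deviance
  # Bernoulli saturated log-likelihood is 0, so deviance = -2 log-likelihood.
  r2_mcfadden <- 1 - dev / dev0
  r2_cs <- 1 - exp(-(dev0 - dev) / n)
  r2_nagelkerke <- r2_cs / (1 - exp(-dev0 / n))
  structure(
    list(
      intercept = unname(stats::coef(m)[1L]),
      slope = unname(stats::coef(m)[2L]),
      slope_se = sm$coefficients["n_lots", "Std. Error"],
      slope_p = sm$coefficients["n_lots", "Pr(>|z|)"],
      pseudo_r2_mcfadden = r2_mcfadden,
      pseudo_r2_nagelkerke = r2_nagelkerke,
      n_species = n, separation = separation, glm_fit = m
    ),
    class = "detection_model"
  )
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf(
    "Detection model (%d species): logit P(significant) = %.3f + %.3f * n_lots\n",
    x$n_species, x$intercept, x$slope))
  cat(sprintf("  slope p = %.4g; pseudo-R2: Nagelkerke %.3f, McFadden %.3f%s\n",
              x$slope_p, x$pseudo_r2_nagelkerke, x$pseudo_r2_mcfadden,
              if (x$separation) " [separation: unreliable]" else ""))
  invisible(x)
}

#' Species-comparison table
#'
#' Flattens a list of [test_lot_differences()] results into the
#' machine-readable table written by the pipeline.
#'
#' @param comparisons List of `species_comparison` objects.
#' @return Data frame with one row per species.
#' @export
species_comparison_table <- function(comparisons) {
  do.call(rbind, c(lapply(comparisons, function(x) {
    s <- x$species_sigma
    data.frame(
      species_id = x$species_id, n_lots = x$n_lots, F = x$interaction_F,
      df_num = x$df_num, df_den = x$df_den, p = x$p_value,
      significant = x$significant,
      species_sigma = if (s$defined) s$sigma_days else NA_real_,
      sigma_ci_low = s$ci_low_days, sigma_ci_high = s$ci_high_days,
      stringsAsFactors = FALSE
    )
  }), list(make.row.names = FALSE)))
}
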