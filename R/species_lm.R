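# Species-level linear models for ln(sigma) and type-III Wald tests.

#' Type-III tests for a fitted model
#'
#' For the package's random-intercept model the per-term Wald chi-squared
#' table (df = 1 for each continuous covariate) is returned. For an `lm`,
#' type-III F tests are computed under sum-to-zero contrasts via
#' `car::Anova`; with no interactions present this equals dropping each term
#' from the full model, so the result is contrast-invariant.
#'
#' @param fit A `seed_lmm` or `lm` object.
#' @return Data frame with one row per term: test statistic, df and p.
#' @export
wald_type3 <- function(fit) UseMethod("wald_type3")

#' @export
wald_type3.seed_lmm <- function(fit) fit$type3_tests

#' @export
wald_type3.lm <- function(fit) {
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("aliased coefficient(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  a <- car::Anova(fit, type = "III")
  keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
  data.frame(
    term = rownames(a)[keep],
    F = a[keep, "F value"],
    df_num = a[keep, "Df"],
    df_den = stats::df.residual(fit),
    p = a[keep, "Pr(>F)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Species-level regression of longevity on traits
#'
#' Ordinary least squares of ln(sigma) per species on either plant family
#' plus mean 1000-seed mass (`"family_mass"`) or protein plus oil content
#' (`"protein_oil"`), with type-III F tests under sum-to-zero contrasts.
#' Families represented by a single species are retained (they still inform
#' the family effect); a single-family input drops the family term with a
#' warning and fits mass alone.
#'
#' @param species_sigma Data frame with `species_id` and `sigma_days` (one
#'   row per species).
#' @param species_meta Species metadata ([validate_species_metadata()]
#'   columns).
#' @param model `"family_mass"` or `"protein_oil"`.
#' @param log_response Model ln(sigma) (default) or plain sigma.
#' @return An object of class `species_lm`: `coefficients`, `type3_tests`,
#'   `r_squared`, `n_obs`, `model`, `lm_fit`.
#' @export
fit_species_lm <- function(species_sigma, species_meta,
                           model = c("family_mass", "protein_oil"),
                           log_response = TRUE) {
  model <- match.arg(model)
  species_meta <- validate_species_metadata(species_meta)
  df <- merge(species_sigma[, c("species_id", "sigma_days")], species_meta,
              by = "species_id")
  df <- df[!is.na(df$sigma_days), , drop = FALSE]
  df$y <- if (log_response) log(df$sigma_days) else df$sigma_days
  if (model == "family_mass") {
    df <- df[!is.na(df$family) & !is.na(df$mean_thousand_seed_mass_g), ,
             drop = FALSE]
    df$family <- factor(df$family)
    if (nlevels(df$family) < 2L) {
      warning("single family present: family term dropped, mass-only fit")
      fit <- stats::lm(y ~ mean_thousand_seed_mass_g, data = df)
    } else {
      fit <- stats::lm(y ~ family + mean_thousand_seed_mass_g, data = df,
                       contrasts = list(family = "contr.sum"))
    }
  } else {
    df <- df[!is.na(df$protein_content_pct) & !is.na(df$oil_content_pct), ,
             drop = FALSE]
    if (nrow(df) < 4L) stop("too few species with protein and oil contents",
                            call. = FALSE)
    fit <- stats::lm(y ~ protein_content_pct + oil_content_pct, data = df)
  }
  if (stats::df.residual(fit) < 1L) {
    stop("no residual degrees of freedom in the species model", call. = FALSE)
  }
  structure(
    list(
      coefficients = stats::coef(fit),
      type3_tests = wald_type3(fit),
      r_squared = summary(fit)$r.squared,
      n_obs = nrow(df),
      model = model, log_response = log_response, lm_fit = fit
    ),
    class = "species_lm"
  )
}

#' @export
print.species_lm <- function(x, ...) {
  cat(sprintf("Species-level model (%s) on %s, %d species, R2 = %.3f\n",
              x$model, if (x$log_response) "ln(sigma)" else "sigma",
              x$n_obs, x$r_squared))
  print(transform(x$type3_tests, F = round(F, 3), p = signif(p, 3)))
  invisible(x)
}
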