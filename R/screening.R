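# Seed-lot screening: initial-germination filter, slope-significance filter,
# and the maximum-sigma bound, applied in a fixed order so each excluded lot
# carries exactly one triggering rule.

.screen_statuses <- c("retained", "excluded_contaminated",
                      "excluded_low_viability",
                      "excluded_no_significant_slope",
                      "excluded_sigma_exceeds_max")

#' Initial germination of a seed lot
#'
#' The maximum, across the design's dormancy-window durations present in the
#' data, of the mean replicate germination percentage at that duration. Taking
#' the maximum over the shortest durations (0, 1, 5 days in the standard
#' design) tolerates physiological dormancy that a brief ageing exposure
#' breaks: such lots germinate better after 1 or 5 days than fresh.
#'
#' @param obs Germination observations for a single lot.
#' @param design An [aging_design()].
#' @return Initial germination in percent.
#' @export
initial_germination <- function(obs, design) {
  stopifnot(inherits(design, "aging_design"))
  if (length(unique(obs$lot_id)) > 1L) {
    stop("`obs` must contain a single lot", call. = FALSE)
  }
  win <- obs[obs$aging_days %in% design$dormancy_window, , drop = FALSE]
  if (nrow(win) == 0L) {
    stop("no observations at any dormancy-window duration", call. = FALSE)
  }
  pct <- 100 * win$n_germinated / win$n_seeds
  max(tapply(pct, win$aging_days, mean))
}

.outcome <- function(lot_id, species_id, initial_pct, status, sig = NULL,
                     detail = "") {
  data.frame(
    lot_id = lot_id, species_id = species_id,
    initial_germination_pct = initial_pct, status = status,
    sigma_days = if (!is.null(sig) && sig$defined) sig$sigma_days else NA_real_,
    sigma_ci_low = if (!is.null(sig)) sig$ci_low_days else NA_real_,
    sigma_ci_high = if (!is.null(sig)) sig$ci_high_days else NA_real_,
    slope = if (!is.null(sig)) sig$slope else NA_real_,
    slope_p = if (!is.null(sig)) sig$slope_p else NA_real_,
    ki_probits = if (!is.null(sig)) sig$ki_probits else NA_real_,
    ki_pct = if (!is.null(sig)) sig$ki_pct else NA_real_,
    rule_detail = detail,
    stringsAsFactors = FALSE
  )
}

#' Screen one seed lot
#'
#' Applies the inclusion rules in a fixed order: (1) contaminated replicates
#' are expected to have been removed upstream (any remaining are noted);
#' (2) initial germination below `min_initial_pct` excludes the lot;
#' (3) a non-converged fit, a non-negative slope, or slope p >= `alpha`
#' excludes it (no significant decay); (4) sigma above the design's maximum
#' duration excludes it (the time course covers too little of the survival
#' curve for a precise estimate). Otherwise the lot is retained with its
#' sigma estimate attached.
#'
#' @param obs Observations for the lot (contaminated dishes removed).
#' @param fit The lot's `single_lot` [fit_probit()] result, or `NULL` to fit
#'   here.
#' @param design An [aging_design()].
#' @param thresholds List with `min_initial_pct` (default 50) and `alpha`
#'   (default 0.05).
#' @return One-row data frame (class `screening_outcome`): lot_id, species_id,
#'   initial_germination_pct, status, sigma and slope columns, rule_detail.
#' @export
screen_lot <- function(obs, fit = NULL, design = paper_design(),
                       thresholds = list(min_initial_pct = 50, alpha = 0.05)) {
  min_pct <- thresholds$min_initial_pct %||% 50
  alpha <- thresholds$alpha %||% 0.05
  lot_id <- unique(obs$lot_id)
  stopifnot(length(lot_id) == 1L)
  species_id <- obs$species_id[1L]
  note <- ""
  if (isTRUE(any(obs$contaminated))) {
    note <- sprintf("%d contaminated replicate(s) still present; ",
                    sum(obs$contaminated))
  }
  init <- initial_germination(obs, design)
  if (init < min_pct) {
    out <- .outcome(lot_id, species_id, init, "excluded_low_viability",
                    detail = sprintf("%sinitial germination %.1f%% < %g%%",
                                     note, init, min_pct))
    class(out) <- c("screening_outcome", class(out))
    return(out)
  }
  if (is.null(fit)) fit <- fit_probit(obs, kind = "single_lot")
  if (fit$kind != "single_lot") {
    stop("`fit` must be a single_lot fit of this lot", call. = FALSE)
  }
  sig <- if (fit$converged) sigma_from_fit(fit, lot_id = NULL) else NULL
  no_decay <- !fit$converged || is.null(sig) || !sig$defined ||
    !is.finite(sig$slope_p) || sig$slope_p >= alpha
  if (no_decay) {
    detail <- if (!fit$converged) {
      sprintf("%sfit not converged: %s", note, fit$diagnostic)
    } else if (!sig$defined) {
      paste0(note, sig$flag)
    } else {
      sprintf("%sslope p = %.3g >= %g", note, sig$slope_p, alpha)
    }
    out <- .outcome(lot_id, species_id, init, "excluded_no_significant_slope",
                    sig, detail)
  } else if (sig$sigma_days > max(design$durations)) {
    out <- .outcome(lot_id, species_id, init, "excluded_sigma_exceeds_max", sig,
                    sprintf("%ssigma %.1f d > max duration %g d", note,
                            sig$sigma_days, max(design$durations)))
  } else {
    out <- .outcome(lot_id, species_id, init, "retained", sig,
                    paste0(note, "all rules passed"))
  }
  class(out) <- c("screening_outcome", class(out))
  out
}

#' Screen a whole germination dataset
#'
#' Per-lot screening for every lot in the dataset. A lot with more than
#' `max_contaminated_frac` of its dishes flagged as contaminated is excluded
#' as contaminated; in other lots, flagged dishes are dropped before
#' fitting. Deterministic given the inputs and thresholds.
#'
#' @param obs Validated germination observations for all lots.
#' @param design An [aging_design()].
#' @param thresholds List with `min_initial_pct` (default 50), `alpha`
#'   (default 0.05) and `max_contaminated_frac` (default 0.5).
#' @return List with `outcomes` (one row per lot), `retained` (the outcome
#'   rows with status "retained"), `retained_obs` (observations of retained
#'   lots, contaminated dishes removed), and `counts` (table of statuses).
#' @export
screen_dataset <- function(obs, design = paper_design(),
                           thresholds = list(min_initial_pct = 50, alpha = 0.05,
                                             max_contaminated_frac = 0.5)) {
  obs <- validate_germination(obs)
  frac_cap <- thresholds$max_contaminated_frac %||% 0.5
  rows <- list()
  keep_obs <- list()
  for (lot in unique(obs$lot_id)) {
    lobs <- obs[obs$lot_id == lot, , drop = FALSE]
    cfrac <- mean(lobs$contaminated)
    if (cfrac > frac_cap) {
      clean <- lobs[!lobs$contaminated, , drop = FALSE]
      init <- if (any(clean$aging_days %in% design$dormancy_window)) {
        initial_germination(clean, design)
      } else NA_real_
      rows[[lot]] <- .outcome(lot, lobs$species_id[1L], init,
                              "excluded_contaminated",
                              detail = sprintf("%.0f%% of dishes contaminated",
                                               100 * cfrac))
      next
    }
    clean <- lobs[!lobs$contaminated, , drop = FALSE]
    rows[[lot]] <- screen_lot(clean, fit = NULL, design, thresholds)
    if (rows[[lot]]$status == "retained") keep_obs[[lot]] <- clean
  }
  outcomes <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  retained <- outcomes[outcomes$status == "retained", , drop = FALSE]
  retained_obs <- if (length(keep_obs)) {
    do.call(rbind, c(keep_obs, list(make.row.names = FALSE)))
  } else {
    obs[0, , drop = FALSE]
  }
  counts <- table(factor(outcomes$status, levels = .screen_statuses))
  list(outcomes = outcomes, retained = retained, retained_obs = retained_obs,
       counts = counts)
}

#' Write a screening table to CSV
#'
#' @param screening Result of [screen_dataset()].
#' @param path Output CSV path.
#' @export
write_screening_table <- function(screening, path) {
  utils::write.csv(screening$outcomes, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
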