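# Pipeline orchestration: staged analysis with CSV/JSON outputs, a JSON run
# manifest and a plain-text log. Each stage is exported on its own so a run
# can be composed piecewise; run_all() chains them.

#' Pipeline configuration
#'
#' @param germination Path to a germination CSV, or an in-memory data frame.
#' @param lot_meta Optional path/data frame of lot metadata (needed for the
#'   mixed-model stage).
#' @param species_meta Optional path/data frame of species metadata (needed
#'   for the species-model stage).
#' @param design `"paper"` or an [aging_design()].
#' @param min_initial_pct,alpha Screening thresholds.
#' @param log_response,confidence_level Model options.
#' @param out_dir Output directory (created if absent).
#' @param rng_seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters in simulation mode).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(germination, lot_meta = NULL, species_meta = NULL,
                            design = "paper", min_initial_pct = 50,
                            alpha = 0.05, log_response = TRUE,
                            confidence_level = 0.95, out_dir = tempfile("run"),
                            rng_seed = 1L) {
  if (identical(design, "paper")) design <- paper_design()
  stopifnot(inherits(design, "aging_design"))
  for (x in list(germination, lot_meta, species_meta)) {
    if (!is.null(x) && is.character(x) && !file.exists(x)) {
      stop("input path does not exist: ", x, call. = FALSE)
    }
  }
  structure(
    list(germination = germination, lot_meta = lot_meta,
         species_meta = species_meta, design = design,
         thresholds = list(min_initial_pct = min_initial_pct, alpha = alpha),
         log_response = log_response, confidence_level = confidence_level,
         out_dir = out_dir, rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat schema: `germination`, `lot_meta`, `species_meta` (paths),
#' `min_initial_pct`, `alpha`, `log_response`, `confidence_level`,
#' `out_dir`, `rng_seed`; `design` is `"paper"` or a mapping with
#' `durations`, `replicates_per_duration`, `seeds_per_replicate`,
#' `temperature_c`, `relative_humidity_pct`, `dormancy_window`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- if (is.null(y$design) || identical(y$design, "paper")) {
    "paper"
  } else {
    do.call(aging_design, y$design)
  }
  pipeline_config(
    germination = y$germination, lot_meta = y$lot_meta,
    species_meta = y$species_meta, design = design,
    min_initial_pct = y$min_initial_pct %||% 50,
    alpha = y$alpha %||% 0.05,
    log_response = y$log_response %||% TRUE,
    confidence_level = y$confidence_level %||% 0.95,
    out_dir = y$out_dir %||% tempfile("run"),
    rng_seed = y$rng_seed %||% 1L
  )
}

.as_obs <- function(x, col_map = NULL) {
  if (is.data.frame(x)) validate_germination(x) else read_germination_table(x, col_map)
}

#' Per-lot sigma stage
#'
#' Screens every lot (which includes the per-lot probit fits) and returns the
#' screening/sigma table; the pipeline's first two stages.
#'
#' @param obs Germination observations (data frame or CSV path).
#' @param design An [aging_design()].
#' @param thresholds Screening thresholds, see [screen_dataset()].
#' @return The [screen_dataset()] result.
#' @export
stage_screen <- function(obs, design = paper_design(),
                         thresholds = list(min_initial_pct = 50, alpha = 0.05)) {
  obs <- .as_obs(obs)
  if (nrow(obs) == 0L) stop("empty germination table", call. = FALSE)
  screen_dataset(obs, design, thresholds)
}

#' Within-species comparison stage
#'
#' Interaction tests for every species with at least two retained lots,
#' species-level sigma for every retained species, and the detection model
#' when it is estimable.
#'
#' @param retained_obs Observations of retained lots ([stage_screen()]'s
#'   `retained_obs`).
#' @param alpha Interaction significance threshold.
#' @param confidence_level Coverage for sigma intervals.
#' @return List with `comparisons`, `comparison_table`, `species_sigma`
#'   (data frame, all retained species), `detection` (or `NULL` with a
#'   warning when not estimable).
#' @export
stage_compare_species <- function(retained_obs, alpha = 0.05,
                                  confidence_level = 0.95) {
  species <- unique(retained_obs$species_id)
  comparisons <- list()
  sig_rows <- list()
  for (sp in species) {
    sobs <- retained_obs[retained_obs$species_id == sp, , drop = FALSE]
    n_lots <- length(unique(sobs$lot_id))
    if (n_lots >= 2L) {
      comparisons[[sp]] <- test_lot_differences(sobs, alpha, confidence_level)
      s <- comparisons[[sp]]$species_sigma
    } else {
      s <- fit_species_sigma(sobs, confidence_level)
    }
    sig_rows[[sp]] <- data.frame(
      species_id = sp, n_lots = n_lots,
      sigma_days = if (s$defined) s$sigma_days else NA_real_,
      sigma_ci_low = s$ci_low_days, sigma_ci_high = s$ci_high_days,
      stringsAsFactors = FALSE
    )
  }
  detection <- NULL
  if (length(comparisons) >= 3L) {
    detection <- tryCatch(detection_probability_model(comparisons),
                          error = function(e) {
                            warning("detection model skipped: ",
                                    conditionMessage(e))
                            NULL
                          })
  }
  list(
    comparisons = comparisons,
    comparison_table = if (length(comparisons)) {
      species_comparison_table(comparisons)
    } else NULL,
    species_sigma = do.call(rbind, c(sig_rows, list(make.row.names = FALSE))),
    detection = detection
  )
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stage order: per-lot probit fits and screening, within-species comparison
#' and detection model, the lot-predictor mixed model (skipped with a warning
#' when lot covariates are unavailable), and the species-level trait models
#' (skipped without species metadata). All stage outputs are written under
#' `config$out_dir` as CSV/JSON together with a JSON manifest and a
#' timestamped plain-text log; any hard stage failure aborts with the stage
#' named.
#'
#' @param config A [pipeline_config()].
#' @return The output directory path, invisibly; the stage results are
#'   returned as the attribute `"results"`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  logline <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  stage <- "read-inputs"
  res <- tryCatch({
    obs <- .as_obs(config$germination)
    if (nrow(obs) == 0L) stop("empty germination table", call. = FALSE)
    logline("read %d observations, %d lots", nrow(obs),
            length(unique(obs$lot_id)))

    stage <- "fit-lots/screen"
    screening <- stage_screen(obs, config$design, config$thresholds)
    write_screening_table(screening, file.path(out, "screening.csv"))
    utils::write.csv(screening$retained, file.path(out, "lot_sigma.csv"),
                     row.names = FALSE, na = "")
    for (st in names(screening$counts)) {
      logline("screening: %s = %d", st, screening$counts[[st]])
    }
    excl <- screening$outcomes[screening$outcomes$status != "retained", ,
                               drop = FALSE]
    for (i in seq_len(nrow(excl))) {
      logline("excluded %s: %s (%s)", excl$lot_id[i], excl$status[i],
              excl$rule_detail[i])
    }

    stage <- "compare-species"
    comparison <- stage_compare_species(screening$retained_obs,
                                        config$thresholds$alpha,
                                        config$confidence_level)
    if (!is.null(comparison$comparison_table)) {
      utils::write.csv(comparison$comparison_table,
                       file.path(out, "species_comparison.csv"),
                       row.names = FALSE, na = "")
    }
    utils::write.csv(comparison$species_sigma,
                     file.path(out, "species_sigma.csv"),
                     row.names = FALSE, na = "")
    if (!is.null(comparison$detection)) {
      d <- comparison$detection
      .write_json(d[c("intercept", "slope", "slope_se", "slope_p",
                      "pseudo_r2_mcfadden", "pseudo_r2_nagelkerke",
                      "n_species", "separation")],
                  file.path(out, "detection_model.json"))
    }
    logline("compared %d species (%d with >= 2 lots)",
            nrow(comparison$species_sigma), length(comparison$comparisons))

    stage <- "lmm"
    lmm <- NULL
    if (!is.null(config$lot_meta)) {
      meta <- if (is.data.frame(config$lot_meta)) {
        validate_lot_metadata(config$lot_meta)
      } else read_lot_metadata(config$lot_meta)
      lmm <- tryCatch(
        fit_lot_predictor_lmm(screening$retained, meta,
                              log_response = config$log_response),
        error = function(e) {
          warning("LMM stage skipped: ", conditionMessage(e))
          logline("LMM stage skipped: %s", conditionMessage(e))
          NULL
        })
      if (!is.null(lmm)) {
        utils::write.csv(lmm$type3_tests, file.path(out, "lmm_type3.csv"),
                         row.names = FALSE)
        .write_json(list(
          fixed_effects = lmm$fixed_effects,
          random_intercept_variance = lmm$random_intercept_variance,
          residual_variance = lmm$residual_variance,
          reml_loglik = lmm$reml_loglik,
          r2_marginal = lmm$r2_marginal, r2_conditional = lmm$r2_conditional,
          within_species_share = within_species_share(lmm$r2_marginal,
                                                      lmm$r2_conditional),
          species_share = species_share(lmm$r2_marginal, lmm$r2_conditional),
          n_obs = lmm$n_obs, n_groups = lmm$n_groups, singular = lmm$singular
        ), file.path(out, "lmm_summary.json"))
        logline("LMM: %d lots, %d species, R2m %.3f R2c %.3f", lmm$n_obs,
                lmm$n_groups, lmm$r2_marginal, lmm$r2_conditional)
      }
    } else {
      logline("LMM stage skipped: no lot metadata supplied")
    }

    stage <- "species-models"
    species_models <- NULL
    if (!is.null(config$species_meta)) {
      smeta <- if (is.data.frame(config$species_meta)) {
        validate_species_metadata(config$species_meta)
      } else read_species_metadata(config$species_meta)
      species_models <- list()
      for (mod in c("family_mass", "protein_oil")) {
        species_models[[mod]] <- tryCatch(
          fit_species_lm(comparison$species_sigma, smeta, model = mod,
                         log_response = config$log_response),
          error = function(e) {
            warning(sprintf("species model '%s' skipped: %s", mod,
                            conditionMessage(e)))
            logline("species model '%s' skipped: %s", mod, conditionMessage(e))
            NULL
          })
      }
      keep <- !vapply(species_models, is.null, logical(1))
      if (any(keep)) {
        .write_json(lapply(species_models[keep], function(m) {
          list(coefficients = as.list(m$coefficients),
               type3 = m$type3_tests, r_squared = m$r_squared, n = m$n_obs)
        }), file.path(out, "species_models.json"))
      }
    } else {
      logline("species-model stage skipped: no species metadata supplied")
    }

    list(screening = screening, comparison = comparison, lmm = lmm,
         species_models = species_models)
  }, error = function(e) {
    logline("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  stage <- "manifest"
  .write_json(list(
    package_version = as.character(utils::packageVersion("seedlongevity")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(
      germination = if (is.character(config$germination)) config$germination else "<in-memory>",
      lot_meta = if (is.character(config$lot_meta)) config$lot_meta else
        if (is.null(config$lot_meta)) NULL else "<in-memory>",
      species_meta = if (is.character(config$species_meta)) config$species_meta else
        if (is.null(config$species_meta)) NULL else "<in-memory>"
    ),
    design = unclass(config$design),
    thresholds = config$thresholds,
    log_response = config$log_response,
    confidence_level = config$confidence_level,
    rng_seed = config$rng_seed
  ), file.path(out, "manifest.json"))
  logline("run complete")
  structure(invisible(out), results = res)
}

#' Write a simulated dataset to disk
#'
#' Simulation mode of the pipeline: generates a dataset from a
#' [simulation_config()] and writes the germination, lot-metadata,
#' species-metadata and truth tables plus the config echoed as a JSON
#' manifest.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly; the dataset as attribute `"dataset"`.
#' @export
stage_simulate <- function(config = simulation_config(), out_dir = tempfile("sim")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config)
  write_germination_table(sim$observations, file.path(out_dir, "germination.csv"))
  write_lot_metadata(sim$lot_meta, file.path(out_dir, "lot_meta.csv"))
  write_species_metadata(sim$species_meta, file.path(out_dir, "species_meta.csv"))
  utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, na = "")
  cfg <- sim$config
  cfg$design <- unclass(cfg$design)
  .write_json(unclass(cfg), file.path(out_dir, "sim_config.json"))
  structure(invisible(out_dir), dataset = sim)
}
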