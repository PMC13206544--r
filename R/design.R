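#' Artificial-ageing experimental design
#'
#' An `aging_design` describes one controlled-ageing experiment: the schedule
#' of ageing durations (days at elevated temperature and humidity), the
#' replication per duration, and the short-duration window used to define
#' "initial germination" of a seed lot (the maximum mean germination across
#' those durations, which tolerates dormancy broken by brief ageing).
#'
#' @param durations Numeric vector of ageing durations in days. Must be
#'   strictly increasing, unique, and start at 0 (fresh seeds).
#' @param replicates_per_duration Positive integer, dishes per duration.
#' @param seeds_per_replicate Positive integer, seeds per dish.
#' @param temperature_c Ageing temperature in degrees Celsius.
#' @param relative_humidity_pct Ageing relative humidity in percent.
#' @param dormancy_window Subset of `durations` (must contain 0) over which
#'   initial germination is taken as the maximum of per-duration means.
#'
#' @return An object of class `aging_design`.
#' @seealso [paper_design()], [design_total_seeds()], [initial_germination()]
#' @export
aging_design <- function(durations,
                         replicates_per_duration,
                         seeds_per_replicate,
                         temperature_c,
                         relative_humidity_pct,
                         dormancy_window = durations[durations <= 5]) {
  durations <- as.numeric(durations)
  if (length(durations) < 2L || anyNA(durations)) {
    stop("`durations` must be a numeric vector with at least two values", call. = FALSE)
  }
  if (any(diff(durations) <= 0)) {
    stop("`durations` must be strictly increasing and unique", call. = FALSE)
  }
  if (durations[1L] != 0) {
    stop("`durations` must start at 0 (fresh-seed control)", call. = FALSE)
  }
  replicates_per_duration <- as.integer(replicates_per_duration)
  seeds_per_replicate <- as.integer(seeds_per_replicate)
  if (is.na(replicates_per_duration) || replicates_per_duration < 1L) {
    stop("`replicates_per_duration` must be a positive integer", call. = FALSE)
  }
  if (is.na(seeds_per_replicate) || seeds_per_replicate < 1L) {
    stop("`seeds_per_replicate` must be a positive integer", call. = FALSE)
  }
  dormancy_window <- as.numeric(dormancy_window)
  if (!all(dormancy_window %in% durations)) {
    stop("`dormancy_window` must be a subset of `durations`", call. = FALSE)
  }
  if (!0 %in% dormancy_window) {
    stop("`dormancy_window` must contain 0", call. = FALSE)
  }
  structure(
    list(
      durations = durations,
      replicates_per_duration = replicates_per_duration,
      seeds_per_replicate = seeds_per_replicate,
      temperature_c = as.numeric(temperature_c),
      relative_humidity_pct = as.numeric(relative_humidity_pct),
      dormancy_window = sort(dormancy_window)
    ),
    class = "aging_design"
  )
}

#' Standard controlled-ageing design
#'
#' The reference design used throughout this package: ageing at 45 degrees C
#' and 60% relative humidity for 0, 1, 5, 9, 15, 20, 30, 40, 57, or 72 days,
#' with three replicate dishes of 30 seeds per duration (900 seeds per lot),
#' and initial germination defined over the 0/1/5-day window.
#'
#' @return An `aging_design`.
#' @examples
#' d <- paper_design()
#' design_total_seeds(d, 188)
#' @export
paper_design <- function() {
  aging_design(
    durations = c(0, 1, 5, 9, 15, 20, 30, 40, 57, 72),
    replicates_per_duration = 3L,
    seeds_per_replicate = 30L,
    temperature_c = 45,
    relative_humidity_pct = 60,
    dormancy_window = c(0, 1, 5)
  )
}

#' Total seeds required by a design
#'
#' @param design An [aging_design()].
#' @param n_lots Positive integer, number of seed lots.
#' @return Integer: durations x replicates x seeds-per-dish x lots.
#' @export
design_total_seeds <- function(design, n_lots) {
  stopifnot(inherits(design, "aging_design"))
  n_lots <- as.integer(n_lots)
  if (is.na(n_lots) || n_lots < 1L) stop("`n_lots` must be >= 1", call. = FALSE)
  length(design$durations) * design$replicates_per_duration *
    design$seeds_per_replicate * n_lots
}

#' @export
print.aging_design <- function(x, ...) {
  cat("Controlled-ageing design\n")
  cat(sprintf("  conditions : %g degC, %g%% RH\n",
              x$temperature_c, x$relative_humidity_pct))
  cat(sprintf("  durations  : %s days\n", paste(x$durations, collapse = ", ")))
  cat(sprintf("  replication: %d x %d seeds per duration\n",
              x$replicates_per_duration, x$seeds_per_replicate))
  cat(sprintf("  dormancy window: %s days\n",
              paste(x$dormancy_window, collapse = ", ")))
  invisible(x)
}
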