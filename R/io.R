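# Readers, writers and validation for the germination and metadata tables.
# CSV dialect: UTF-8, comma separator, "." decimal, header required; missing
# numeric values are empty cells on disk and NA in memory (no zero-filling).

.germ_cols <- c("lot_id", "species_id", "aging_days", "replicate_id",
                "n_seeds", "n_germinated", "contaminated")
.lot_cols <- c("lot_id", "species_id", "family", "thousand_seed_mass_g",
               "mat_c", "map_mm", "latitude", "longitude", "provenance")
.species_cols <- c("species_id", "family", "mean_thousand_seed_mass_g",
                   "oil_content_pct", "protein_content_pct", "life_cycle")

.apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  if (is.null(names(col_map)) || any(names(col_map) == "")) {
    stop("`col_map` must be a named character vector: canonical_name = file_column",
         call. = FALSE)
  }
  for (canon in names(col_map)) {
    src <- col_map[[canon]]
    if (!src %in% names(df)) {
      stop(sprintf("column '%s' (mapped to '%s') not found in file", src, canon),
           call. = FALSE)
    }
    names(df)[names(df) == src] <- canon
  }
  df
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Validate a germination table
#'
#' Checks the per-dish invariants: counts are non-negative integers with
#' `n_germinated <= n_seeds`, ageing durations are non-negative, and
#' (lot, duration, replicate) triples are unique.
#'
#' @param obs A data frame of germination observations.
#' @return The validated data frame (invisibly usable), with `contaminated`
#'   coerced to logical.
#' @export
validate_germination <- function(obs) {
  .require_cols(obs, setdiff(.germ_cols, "contaminated"), "germination table")
  if (!"contaminated" %in% names(obs)) obs$contaminated <- rep(FALSE, nrow(obs))
  obs$lot_id <- as.character(obs$lot_id)
  obs$species_id <- as.character(obs$species_id)
  obs$replicate_id <- as.character(obs$replicate_id)
  obs$aging_days <- as.numeric(obs$aging_days)
  obs$n_seeds <- as.integer(obs$n_seeds)
  obs$n_germinated <- as.integer(obs$n_germinated)
  obs$contaminated <- as.logical(obs$contaminated)

  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("germination table row %d: %s", i[1L], msg), call. = FALSE)
    }
  }
  bad(is.na(obs$aging_days) | obs$aging_days < 0,
      "aging_days must be a non-negative number")
  bad(is.na(obs$n_seeds) | obs$n_seeds < 1L, "n_seeds must be a positive integer")
  bad(is.na(obs$n_germinated) | obs$n_germinated < 0L,
      "n_germinated must be a non-negative integer")
  bad(obs$n_germinated > obs$n_seeds, "n_germinated exceeds n_seeds")
  bad(is.na(obs$contaminated), "contaminated must be TRUE/FALSE")

  key <- paste(obs$lot_id, obs$aging_days, obs$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf(
      "germination table row %d: duplicate (lot_id, aging_days, replicate_id) = (%s, %g, %s)",
      i, obs$lot_id[i], obs$aging_days[i], obs$replicate_id[i]), call. = FALSE)
  }
  lot_sp <- unique(obs[, c("lot_id", "species_id")])
  if (anyDuplicated(lot_sp$lot_id)) {
    dup <- lot_sp$lot_id[duplicated(lot_sp$lot_id)][1L]
    stop(sprintf("lot '%s' is mapped to more than one species", dup), call. = FALSE)
  }
  obs
}

#' Read a germination trial table
#'
#' One row per replicate dish: seed lot, species, ageing duration (days),
#' seeds sown and germinated, and an optional contamination flag. A missing
#' `contaminated` column defaults to `FALSE`.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(lot_id = "accession", n_germinated = "germ")`.
#' @return A validated data frame of germination observations.
#' @export
read_germination_table <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df <- .apply_col_map(df, col_map)
  validate_germination(df)
}

#' Write a germination trial table
#'
#' @param obs A germination data frame (validated on the way out).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_germination_table <- function(obs, path) {
  obs <- validate_germination(obs)
  utils::write.csv(obs[, .germ_cols], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a seed-lot metadata table
#'
#' @param meta A data frame of per-lot metadata.
#' @return The validated data frame. Empty numeric cells become `NA`.
#' @export
validate_lot_metadata <- function(meta) {
  .require_cols(meta, c("lot_id", "species_id"), "lot metadata")
  for (col in setdiff(.lot_cols, names(meta))) meta[[col]] <- NA
  meta$lot_id <- as.character(meta$lot_id)
  meta$species_id <- as.character(meta$species_id)
  meta$family <- as.character(meta$family)
  for (col in c("thousand_seed_mass_g", "mat_c", "map_mm", "latitude", "longitude")) {
    meta[[col]] <- suppressWarnings(as.numeric(meta[[col]]))
  }
  meta$provenance <- as.character(meta$provenance)

  if (anyDuplicated(meta$lot_id)) {
    dup <- meta$lot_id[duplicated(meta$lot_id)][1L]
    stop(sprintf("lot metadata: duplicate lot_id '%s'", dup), call. = FALSE)
  }
  chk <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) stop(sprintf("lot metadata row %d: %s", i[1L], msg), call. = FALSE)
  }
  chk(!is.na(meta$thousand_seed_mass_g) & meta$thousand_seed_mass_g <= 0,
      "thousand_seed_mass_g must be positive when present")
  chk(!is.na(meta$map_mm) & meta$map_mm < 0, "map_mm must be non-negative")
  chk(!is.na(meta$latitude) & abs(meta$latitude) > 90,
      "latitude must lie in [-90, 90]")
  chk(!is.na(meta$longitude) & abs(meta$longitude) > 180,
      "longitude must lie in [-180, 180]")
  chk(!is.na(meta$provenance) & !meta$provenance %in% c("wild", "farm"),
      "provenance must be 'wild' or 'farm'")
  meta
}

#' Read seed-lot metadata
#'
#' Per-lot covariates: family, 1000-seed mass (g), mean annual temperature
#' (degrees C) and annual precipitation (mm) at the origin, coordinates, and
#' provenance (wild or farm). Empty numeric cells are read as missing.
#'
#' @inheritParams read_germination_table
#' @return A validated data frame of lot metadata.
#' @export
read_lot_metadata <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        na.strings = c("", "NA"))
  df <- .apply_col_map(df, col_map)
  validate_lot_metadata(df)
}

#' Write seed-lot metadata
#'
#' @inheritParams write_germination_table
#' @param meta A lot metadata data frame.
#' @export
write_lot_metadata <- function(meta, path) {
  meta <- validate_lot_metadata(meta)
  utils::write.csv(meta[, .lot_cols], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate species-level metadata
#'
#' @param meta A data frame of per-species traits.
#' @param lot_meta Optional lot metadata; when given, each species' mean
#'   1000-seed mass is checked against the mean of its lots' masses.
#' @param tol Relative tolerance for the mass-consistency check.
#' @return The validated data frame.
#' @export
validate_species_metadata <- function(meta, lot_meta = NULL, tol = 1e-6) {
  .require_cols(meta, c("species_id"), "species metadata")
  for (col in setdiff(.species_cols, names(meta))) meta[[col]] <- NA
  meta$species_id <- as.character(meta$species_id)
  meta$family <- as.character(meta$family)
  for (col in c("mean_thousand_seed_mass_g", "oil_content_pct", "protein_content_pct")) {
    meta[[col]] <- suppressWarnings(as.numeric(meta[[col]]))
  }
  meta$life_cycle <- as.character(meta$life_cycle)
  if (anyDuplicated(meta$species_id)) {
    stop("species metadata: duplicate species_id", call. = FALSE)
  }
  if (any(!is.na(meta$mean_thousand_seed_mass_g) &
          meta$mean_thousand_seed_mass_g <= 0)) {
    stop("mean_thousand_seed_mass_g must be positive when present", call. = FALSE)
  }
  ok <- !is.na(meta$life_cycle) & !meta$life_cycle %in% c("A", "B", "P", "mixed")
  if (any(ok)) stop("life_cycle must be one of A, B, P, mixed", call. = FALSE)
  if (!is.null(lot_meta)) {
    lot_meta <- validate_lot_metadata(lot_meta)
    for (i in seq_len(nrow(meta))) {
      m <- lot_meta$thousand_seed_mass_g[lot_meta$species_id == meta$species_id[i]]
      m <- m[!is.na(m)]
      if (length(m) && !is.na(meta$mean_thousand_seed_mass_g[i])) {
        if (abs(mean(m) - meta$mean_thousand_seed_mass_g[i]) >
            tol * max(1, abs(mean(m)))) {
          stop(sprintf(
            "species '%s': mean_thousand_seed_mass_g (%g) does not match the mean of its lots (%g)",
            meta$species_id[i], meta$mean_thousand_seed_mass_g[i], mean(m)),
            call. = FALSE)
        }
      }
    }
  }
  meta
}

#' Read species-level metadata
#'
#' @inheritParams read_germination_table
#' @return A validated data frame of species traits.
#' @export
read_species_metadata <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        na.strings = c("", "NA"))
  df <- .apply_col_map(df, col_map)
  validate_species_metadata(df)
}

#' Write species-level metadata
#'
#' @inheritParams write_germination_table
#' @param meta A species metadata data frame.
#' @export
write_species_metadata <- function(meta, path) {
  meta <- validate_species_metadata(meta)
  utils::write.csv(meta[, .species_cols], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
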