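#' Write the panel tables as delimited text
#'
#' Writes the trait, water-content, time-course and (if present) soil
#' moisture tables of a simulated or assembled panel to tab-separated UTF-8
#' files with fixed headers, the on-disk interface between the generator
#' and the evaluation pipeline.
#'
#' @param panel A named list of tibbles as from [simulate_panel()]
#'   (`traits`, `water_content`, `timecourses`, optionally `smc`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(traits = file.path(dir, "traits.tsv"),
             water_content = file.path(dir, "water_content.tsv"),
             timecourses = file.path(dir, "timecourses.tsv"),
             smc = file.path(dir, "smc.tsv"))
  for (nm in names(paths)) {
    if (!is.null(panel[[nm]])) readr::write_tsv(panel[[nm]], paths[[nm]])
  }
  invisible(paths[names(paths) %in% names(panel)])
}

# Shared reader: parse a TSV with the given column spec, collect per-row
# diagnostics from `checks`, drop offending rows, attach diagnostics as an
# attribute. `checks` is a named list of functions(data) -> character issue
# per row (NA when fine). Line numbers count the header as line 1.
read_validated <- function(path, col_names, numeric_cols, checks = list()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  miss <- setdiff(col_names, names(raw))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw <- raw[col_names]
  diagnostics <- tibble::tibble(line = integer(), column = character(),
                                problem = character())
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad)) {
      diagnostics <- dplyr::bind_rows(diagnostics, tibble::tibble(
        line = bad + 1L, column = col,
        problem = paste0("unparseable numeric '", raw[[col]][bad], "'")))
    }
    raw[[col]] <- parsed
  }
  for (nm in names(checks)) {
    issue <- checks[[nm]](raw)
    bad <- which(!is.na(issue))
    if (length(bad)) {
      diagnostics <- dplyr::bind_rows(diagnostics, tibble::tibble(
        line = bad + 1L, column = nm, problem = issue[bad]))
    }
  }
  if (nrow(diagnostics)) {
    drop <- unique(diagnostics$line) - 1L
    warning(length(drop), " row(s) of ", basename(path),
            " rejected (lines ", paste(diagnostics$line, collapse = ", "),
            ")", call. = FALSE)
    raw <- raw[-drop, ]
  }
  out <- tibble::as_tibble(raw)
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Read and validate panel tables
#'
#' Readers for the four delimited-text schemas. Rows violating a hard
#' invariant — unparseable numbers, unknown stage or condition labels,
#' negative measurements, a turgid weight at or below the dry weight,
#' percentages outside 0–100 — are rejected with a warning giving their
#' line numbers, and the full diagnostics are attached to the result as
#' `attr(x, "diagnostics")`. Soft violations (a fresh weight outside the
#' dry–turgid interval, possible from weighing variance) are kept and only
#' warned about downstream.
#'
#' @param path Path to the tab-separated file.
#' @return A validated tibble with a `diagnostics` attribute.
#' @name read_panel_tables
NULL

#' @rdname read_panel_tables
#' @export
read_trait_table <- function(path) {
  cols <- c("cultivar", "stage", "condition", "plant_id",
            "taproot_length", "shoot_length", "root_dm", "shoot_dm")
  num <- cols[4:8]
  checks <- list(
    stage = function(d) ifelse(
      d$stage %in% c("seedling", "V3", "day27"), NA_character_,
      paste0("unknown stage '", d$stage, "'")),
    condition = function(d) ifelse(
      d$condition %in% c("well_watered", "drought"), NA_character_,
      paste0("unknown condition '", d$condition, "'")),
    measurements = function(d) {
      # NA values stem from parse failures already reported; skip them here
      bad <- rowSums(sapply(num[-1], function(col)
        !is.na(d[[col]]) & (!is.finite(d[[col]]) | d[[col]] < 0))) > 0
      ifelse(bad, "negative or non-finite measurement", NA_character_)
    }
  )
  out <- read_validated(path, cols, num, checks)
  out$plant_id <- as.integer(out$plant_id)
  out
}

#' @rdname read_panel_tables
#' @export
read_water_content_table <- function(path) {
  cols <- c("cultivar", "condition", "plant_id",
            "fresh_weight", "turgid_weight", "dry_weight")
  checks <- list(
    weights = function(d) {
      bad_one <- function(v) !is.na(v) & (!is.finite(v) | v < 0)
      ifelse(bad_one(d$fresh_weight) | bad_one(d$turgid_weight) |
               bad_one(d$dry_weight),
             "negative or non-finite weight", NA_character_)
    },
    turgid_weight = function(d) ifelse(
      !is.na(d$turgid_weight) & !is.na(d$dry_weight) &
        d$turgid_weight <= d$dry_weight,
      "turgid weight <= dry weight", NA_character_)
  )
  out <- read_validated(path, cols, cols[3:6], checks)
  out$plant_id <- as.integer(out$plant_id)
  out
}

#' @rdname read_panel_tables
#' @export
read_timecourse_table <- function(path) {
  cols <- c("cultivar", "day", "d_pct", "r_pct")
  checks <- list(
    percentages = function(d) {
      bad_one <- function(v) !is.na(v) & (!is.finite(v) | v < 0 | v > 100)
      ifelse(bad_one(d$d_pct) | bad_one(d$r_pct),
             "percentage outside [0, 100]", NA_character_)
    }
  )
  read_validated(path, cols, cols[2:4], checks)
}

#' @rdname read_panel_tables
#' @export
read_smc_table <- function(path) {
  cols <- c("cultivar", "condition", "day", "smc")
  checks <- list(
    smc = function(d) ifelse(
      !is.na(d$smc) & (!is.finite(d$smc) | d$smc < 0 | d$smc > 100),
      "soil moisture outside [0, 100]", NA_character_)
  )
  read_validated(path, cols, cols[3:4], checks)
}

#' @rdname read_panel_tables
#' @param dir Directory holding `traits.tsv`, `water_content.tsv`,
#'   `timecourses.tsv` and optionally `smc.tsv`, as written by
#'   [write_panel()].
#' @export
read_panel <- function(dir) {
  panel <- list(
    traits = read_trait_table(file.path(dir, "traits.tsv")),
    water_content = read_water_content_table(file.path(dir,
                                                       "water_content.tsv")),
    timecourses = read_timecourse_table(file.path(dir, "timecourses.tsv"))
  )
  smc_path <- file.path(dir, "smc.tsv")
  if (file.exists(smc_path)) panel$smc <- read_smc_table(smc_path)
  panel
}
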