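#' Percent reduction of a trait under drought
#'
#' `100 * (control - drought) / control`: how much of the well-watered
#' mean is lost under water deficit. Positive when drought reduces the
#' trait; a negative value means the trait grew under stress.
#'
#' @param control,drought Cell means under the two conditions; `control`
#'   must be positive.
#' @return Percent reduction (vectorized).
#' @export
#' @examples
#' percent_reduction(44.6, 30.3)
percent_reduction <- function(control, drought) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop("control means must be finite and positive", call. = FALSE)
  }
  100 * (control - drought) / control
}

#' Evaluate a cultivar panel for drought tolerance
#'
#' Runs the full analysis over the measurement tables: per-condition RWC
#' means with Duncan letters, the radar-chart drought-tolerant index and
#' the resulting ranking, Duncan letters for every trait x stage x
#' condition cell, threshold classification of the well-watered trait
#' means, and the drought/control percent reduction per trait. The
#' headline call — most tolerant and most sensitive cultivar — is decided
#' by DTI rank alone; RWC and trait rankings are reported as corroborating
#' columns, not votes. The analysis is deterministic: identical inputs and
#' alpha give identical output, whatever the row order of the inputs.
#'
#' Cultivars present in the trait or water-content tables but absent from
#' the time-course table are flagged in `$missing_timecourse` and excluded
#' from the DTI ranking only; their other summaries are still reported.
#'
#' @param traits Plant-level trait table (see [read_trait_table()]).
#' @param water_content Weight-triple table (see
#'   [read_water_content_table()]).
#' @param timecourses Wilting/recovery table in long form (see
#'   [read_timecourse_table()]).
#' @param smc Optional soil-moisture table, carried through for reporting.
#' @param thresholds Classification thresholds (default
#'   [builtin_thresholds()]).
#' @param alpha Significance level for ANOVA/Duncan (default 0.05).
#' @param layout Radar layout (default [radar_layout()]).
#' @return A `panel_report`: list with tibbles `rwc_summary`,
#'   `dti_ranking`, `letters`, `classification`, `reductions`, character
#'   vector `missing_timecourse`, and `headline` with `most_tolerant` /
#'   `most_sensitive`.
#' @export
#' @examples
#' panel <- simulate_panel(example_panel(n = 4, seed = 8))
#' report <- run_evaluation(panel$traits, panel$water_content,
#'                          panel$timecourses)
#' report$headline
run_evaluation <- function(traits, water_content, timecourses, smc = NULL,
                           thresholds = builtin_thresholds(), alpha = 0.05,
                           layout = radar_layout()) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 0.5) {
    stop("`alpha` must lie in (0, 0.5]", call. = FALSE)
  }
  panel_cultivars <- sort(unique(c(traits$cultivar, water_content$cultivar)))
  if (length(unique(timecourses$cultivar)) < 2) {
    stop("need time courses for at least 2 cultivars", call. = FALSE)
  }
  missing_tc <- setdiff(panel_cultivars, unique(timecourses$cultivar))

  rwc_tbl <- compute_rwc(water_content)
  rwc_summary <- rwc_tbl |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      fit <- duncan_letters(df, rwc, cultivar, alpha = alpha)
      dplyr::rename(fit$groups, cultivar = "group", mean_rwc = "mean")
    }) |>
    dplyr::ungroup() |>
    dplyr::select("condition", "cultivar", "n", "mean_rwc", "se", "letters") |>
    dplyr::arrange(.data$condition, dplyr::desc(.data$mean_rwc),
                   .data$cultivar)

  dti_ranking <- timecourses |>
    dplyr::arrange(.data$cultivar, .data$day) |>
    compute_dti(layout = layout) |>
    dplyr::select("cultivar", "dti", "dti_norm") |>
    rank_cultivars()

  letters_tbl <- compare_cultivars(traits, alpha = alpha)

  class_stages <- intersect(unique(traits$stage), unique(thresholds$stage))
  classification <- traits |>
    dplyr::filter(.data$stage %in% class_stages) |>
    trait_means() |>
    classify_panel(thresholds = thresholds) |>
    dplyr::arrange(.data$cultivar, .data$trait, .data$stage)

  reductions <- traits |>
    tidyr::pivot_longer(c("taproot_length", "shoot_length",
                          "root_dm", "shoot_dm"),
                        names_to = "trait", values_to = "value") |>
    dplyr::group_by(.data$cultivar, .data$stage, .data$trait,
                    .data$condition) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean") |>
    dplyr::filter(!is.na(.data$well_watered) & !is.na(.data$drought)) |>
    dplyr::mutate(reduction_pct = percent_reduction(.data$well_watered,
                                                    .data$drought)) |>
    dplyr::arrange(.data$cultivar, .data$stage, .data$trait)

  headline <- list(
    most_tolerant = dti_ranking$cultivar[1],
    most_sensitive = dti_ranking$cultivar[nrow(dti_ranking)]
  )
  structure(
    list(rwc_summary = rwc_summary, dti_ranking = dti_ranking,
         letters = letters_tbl, classification = classification,
         reductions = reductions, smc = smc,
         missing_timecourse = missing_tc, alpha = alpha,
         headline = headline),
    class = "panel_report"
  )
}

#' @export
print.panel_report <- function(x, ...) {
  cat("Drought-tolerance panel report\n")
  cat("  most tolerant:  ", x$headline$most_tolerant, "\n")
  cat("  most sensitive: ", x$headline$most_sensitive, "\n")
  cat("\nDTI ranking:\n")
  print.data.frame(as.data.frame(x$dti_ranking), digits = 4,
                   row.names = FALSE)
  if (length(x$missing_timecourse)) {
    cat("\nNo time course (excluded from ranking): ",
        paste(x$missing_timecourse, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a panel report to disk
#'
#' Emits the report tables as tab-separated text plus a short
#' human-readable `summary.txt`. Output is byte-identical for identical
#' reports.
#'
#' @param report A `panel_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "panel_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("rwc_summary", "dti_ranking", "letters", "classification",
              "reductions")
  paths <- character(0)
  for (nm in tables) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(report[[nm]], p)
    paths <- c(paths, p)
  }
  summary_path <- file.path(dir, "summary.txt")
  rk <- report$dti_ranking
  lines <- c(
    "Drought-tolerance panel report",
    sprintf("alpha = %g", report$alpha),
    sprintf("most tolerant:  %s (DTI %.2f)", report$headline$most_tolerant,
            rk$dti[1]),
    sprintf("most sensitive: %s (DTI %.2f)", report$headline$most_sensitive,
            rk$dti[nrow(rk)]),
    "",
    "DTI ranking (descending):",
    sprintf("  %2d. %-12s DTI %10.2f  (normalized %.3f)",
            rk$rank, rk$cultivar, rk$dti, rk$dti_norm)
  )
  if (length(report$missing_timecourse)) {
    lines <- c(lines, "",
               paste("no time course (excluded from ranking):",
                     paste(report$missing_timecourse, collapse = ", ")))
  }
  writeLines(lines, summary_path)
  invisible(c(paths, summary_path))
}

#' Simulate and evaluate a panel in one call
#'
#' The end-to-end path: generate every table from a [panel_config()], run
#' [run_evaluation()], and (optionally) write both the raw tables and the
#' report to a directory. Given the same configuration the written files
#' are byte-identical across runs.
#'
#' @param config A [panel_config()].
#' @param dir Optional output directory; when given, the panel tables go
#'   to `dir/tables/` and the report to `dir/report/`.
#' @param ... Passed to [run_evaluation()] (`alpha`, `thresholds`, ...).
#' @return A list with `panel` (the generated tables) and `report`.
#' @export
#' @examples
#' res <- run_full(example_panel(n = 4, seed = 21))
#' res$report$headline
run_full <- function(config, dir = NULL, ...) {
  panel <- simulate_panel(config)
  report <- run_evaluation(panel$traits, panel$water_content,
                           panel$timecourses, smc = panel$smc, ...)
  if (!is.null(dir)) {
    write_panel(panel, file.path(dir, "tables"))
    write_report(report, file.path(dir, "report"))
  }
  list(panel = panel, report = report)
}
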