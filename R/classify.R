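#' Published trait thresholds for cultivar classification
#'
#' The eight cut-off pairs used to sort cultivar trait means into three
#' bins — short/medium/long for lengths, low/medium/high for dry matter —
#' at the seedling (12-day) and V3 (21-day) stages. Lengths are in cm, dry
#' matter in g. Values exactly on a cut fall in the medium bin: the outer
#' bins are defined by strict inequalities, so the medium interval is
#' closed.
#'
#' @return A tibble: `trait`, `stage`, `low_cut`, `high_cut`, `low`,
#'   `medium`, `high` (the category labels).
#' @export
#' @examples
#' builtin_thresholds()
builtin_thresholds <- function() {
  tibble::tribble(
    ~trait,           ~stage,     ~low_cut, ~high_cut, ~low,    ~medium,  ~high,
    "taproot_length", "seedling", 19,       22,        "short", "medium", "long",
    "shoot_length",   "seedling", 22,       23.5,      "short", "medium", "long",
    "root_dm",        "seedling", 0.035,    0.045,     "low",   "medium", "high",
    "shoot_dm",       "seedling", 0.18,     0.20,      "low",   "medium", "high",
    "taproot_length", "V3",       40,       50,        "short", "medium", "long",
    "shoot_length",   "V3",       30,       35,        "short", "medium", "long",
    "root_dm",        "V3",       0.09,     0.15,      "low",   "medium", "high",
    "shoot_dm",       "V3",       0.40,     0.50,      "low",   "medium", "high"
  )
}

#' Classify trait values against a low/high cut pair
#'
#' `low` if the value is strictly below `low_cut`, `high` if strictly above
#' `high_cut`, `medium` on the closed interval between them.
#'
#' @param value Numeric vector of trait means (finite, non-negative).
#' @param low_cut,high_cut Cut-offs with `low_cut < high_cut`.
#' @param labels Length-3 character vector of category names, low to high.
#' @return Character vector of categories.
#' @export
#' @examples
#' classify_value(c(18, 19, 20.5, 22, 30.5), 19, 22,
#'                c("short", "medium", "long"))
classify_value <- function(value, low_cut, high_cut,
                           labels = c("low", "medium", "high")) {
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("trait values must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(low_cut) || !is.finite(high_cut) || low_cut >= high_cut) {
    stop("need finite cuts with low_cut < high_cut", call. = FALSE)
  }
  if (length(labels) != 3) stop("`labels` must have length 3", call. = FALSE)
  dplyr::case_when(
    value < low_cut ~ labels[1],
    value > high_cut ~ labels[3],
    TRUE ~ labels[2]
  )
}

#' Summarise a plant-level trait table to cultivar means
#'
#' Classification operates on cell means, not individual plants; this
#' helper reduces a trait table to one mean per cultivar x trait x stage
#' under the chosen watering condition.
#'
#' @param traits Plant-level trait table (see [simulate_traits()]).
#' @param condition Watering condition to keep (default `"well_watered"`,
#'   matching screening under normal growth).
#' @param trait_cols Trait columns to summarise.
#' @return A tibble: `cultivar`, `trait`, `stage`, `mean_value`.
#' @export
trait_means <- function(traits, condition = "well_watered",
                        trait_cols = c("taproot_length", "shoot_length",
                                       "root_dm", "shoot_dm")) {
  traits |>
    dplyr::filter(.data$condition == !!condition) |>
    tidyr::pivot_longer(dplyr::all_of(trait_cols),
                        names_to = "trait", values_to = "value") |>
    dplyr::group_by(.data$cultivar, .data$trait, .data$stage) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")
}

#' Classify cultivar trait means into threshold bins
#'
#' Joins each (trait, stage) mean to its threshold row and applies
#' [classify_value()]. Pairs with no matching threshold are an error naming
#' the pair — classifying against an unintended default would be silent
#' nonsense.
#'
#' @param means A tibble with columns `cultivar`, `trait`, `stage`,
#'   `mean_value`, e.g. from [trait_means()].
#' @param thresholds Threshold table; defaults to [builtin_thresholds()].
#'   A user table needs the same columns.
#' @return `means` with a `category` column appended.
#' @export
#' @examples
#' m <- tibble::tibble(cultivar = c("A", "B"), trait = "taproot_length",
#'                     stage = "seedling", mean_value = c(30.5, 18))
#' classify_panel(m)
classify_panel <- function(means, thresholds = builtin_thresholds()) {
  need <- c("cultivar", "trait", "stage", "mean_value")
  miss <- setdiff(need, names(means))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(means) == 0) {
    return(dplyr::mutate(tibble::as_tibble(means), category = character(0)))
  }
  joined <- dplyr::left_join(tibble::as_tibble(means), thresholds,
                             by = c("trait", "stage"))
  if (any(is.na(joined$low_cut))) {
    bad <- unique(joined[is.na(joined$low_cut), c("trait", "stage")])
    stop("no thresholds for: ",
         paste(bad$trait, bad$stage, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  joined |>
    dplyr::rowwise() |>
    dplyr::mutate(category = classify_value(
      .data$mean_value, .data$low_cut, .data$high_cut,
      c(.data$low, .data$medium, .data$high))) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(need), "category")
}

#' Read a user threshold table
#'
#' Delimited text with columns `trait`, `stage`, `low_cut`, `high_cut`,
#' `low`, `medium`, `high`, as produced by writing [builtin_thresholds()].
#'
#' @param path File path (tab-separated).
#' @return A threshold tibble.
#' @export
read_thresholds <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trait = "c", stage = "c", low_cut = "d",
                           high_cut = "d", low = "c", medium = "c",
                           high = "c"))
  if (any(out$low_cut >= out$high_cut)) {
    stop("threshold file has rows with low_cut >= high_cut", call. = FALSE)
  }
  out
}
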