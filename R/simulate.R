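#' Trait baselines used by the synthetic generator
#'
#' Noise-free well-watered cell means are `baseline * (1 + span * tolerance)`,
#' so the baseline is the mean of a fully sensitive cultivar and
#' `baseline * (1 + span)` that of a fully tolerant one. The values are set
#' so that panels span the published classification bins for each trait and
#' stage (e.g. seedling taproots from 18 to just over 30 cm).
#'
#' @return A tibble with columns `trait`, `stage`, `baseline`, `span`.
#' @export
trait_baselines <- function() {
  tibble::tribble(
    ~trait,           ~stage,     ~baseline, ~span,
    "taproot_length", "seedling",  18,        0.70,
    "shoot_length",   "seedling",  20,        0.30,
    "root_dm",        "seedling",   0.030,    0.60,
    "shoot_dm",       "seedling",   0.160,    0.40,
    "taproot_length", "V3",        36,        0.64,
    "shoot_length",   "V3",        27,        0.65,
    "root_dm",        "V3",         0.075,    1.20,
    "shoot_dm",       "V3",         0.340,    0.60,
    "taproot_length", "day27",     52,        0.35,
    "shoot_length",   "day27",     30,        0.50,
    "root_dm",        "day27",      0.100,    0.80,
    "shoot_dm",       "day27",      0.400,    0.50
  )
}

#' Simulate the plant-level growth-trait experiment
#'
#' Generates `n_plants_trait` plants per cultivar x stage x condition cell
#' with taproot length, shoot length, root dry matter and shoot dry matter.
#' The noise-free cell mean is `baseline * (1 + span * tolerance)` under
#' well-watered conditions and is further multiplied by
#' `1 - drought_effect * (1 - tolerance)` under drought, so sensitive
#' cultivars lose the most growth when water is withheld. Plant-level noise
#' is multiplicative log-normal with coefficient of variation
#' `noise_sd_frac`; draws are truncated at zero (a no-op for log-normal
#' noise, kept as a guard).
#'
#' @param config A [panel_config()].
#' @param stages Stages to simulate; defaults to all of `"seedling"`,
#'   `"V3"`, `"day27"`. The first two mirror well-watered screening at 12
#'   and 21 days after sowing; `"day27"` mirrors the 27-day harvest after a
#'   15-day drought treatment.
#' @param baselines Baseline table as from [trait_baselines()].
#' @return A tibble with one row per plant: `cultivar`, `stage`,
#'   `condition`, `plant_id`, `taproot_length`, `shoot_length`, `root_dm`,
#'   `shoot_dm` (lengths in cm, dry matter in g).
#' @export
#' @examples
#' traits <- simulate_traits(example_panel(n = 4, seed = 3))
#' dplyr::count(traits, stage, condition)
simulate_traits <- function(config,
                            stages = c("seedling", "V3", "day27"),
                            baselines = trait_baselines()) {
  stopifnot(inherits(config, "panel_config"))
  stages <- match.arg(stages, c("seedling", "V3", "day27"), several.ok = TRUE)
  base <- dplyr::filter(baselines, .data$stage %in% stages)
  n <- config$n_plants_trait
  purrr::pmap_dfr(config$cultivars, function(cultivar, tolerance) {
    with_seed(cultivar_seed(config, cultivar, 1L), {
      cells <- tidyr::expand_grid(
        stage = stages,
        condition = c("well_watered", "drought")
      )
      purrr::pmap_dfr(cells, function(stage, condition) {
        rows <- base[base$stage == stage, ]
        mult <- if (condition == "drought") {
          1 - config$drought_effect * (1 - tolerance)
        } else 1
        vals <- lapply(seq_len(nrow(rows)), function(i) {
          mu <- rows$baseline[i] * (1 + rows$span[i] * tolerance) * mult
          pmax(mu * lognormal_factor(n, config$noise_sd_frac), 0)
        })
        names(vals) <- rows$trait
        tibble::tibble(cultivar = cultivar, stage = stage,
                       condition = condition, plant_id = seq_len(n),
                       !!!vals)
      })
    })
  })
}

#' Simulate the fresh/turgid/dry weight experiment
#'
#' For each plant a turgid weight is drawn first, the dry weight is a fixed
#' fraction of it, and the fresh weight is then placed between them so that
#' the implied relative water content hits a tolerance-dependent target:
#' `base + gain * tolerance` under well-watered conditions, lowered by
#' `penalty * (1 - tolerance)` under drought. The construction guarantees
#' `DW < FW <= TW` on every draw.
#'
#' @param config A [panel_config()].
#' @param base,gain,penalty Target RWC model, in percentage points
#'   (defaults 74, 10, 8: a fully tolerant cultivar targets 84% when
#'   watered; a fully sensitive one 66% under drought).
#' @param turgid_mean Mean turgid weight in g (default 2.5).
#' @param dry_frac Dry weight as a fraction of turgid weight (default 0.22).
#' @return A tibble with columns `cultivar`, `condition`, `plant_id`,
#'   `fresh_weight`, `turgid_weight`, `dry_weight` (g).
#' @export
#' @examples
#' wc <- simulate_water_content(example_panel(n = 3, seed = 5))
#' all(wc$dry_weight < wc$fresh_weight & wc$fresh_weight <= wc$turgid_weight)
simulate_water_content <- function(config, base = 74, gain = 10, penalty = 8,
                                   turgid_mean = 2.5, dry_frac = 0.22) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_plants_rwc
  cv <- config$noise_sd_frac
  purrr::pmap_dfr(config$cultivars, function(cultivar, tolerance) {
    with_seed(cultivar_seed(config, cultivar, 2L), {
      purrr::map_dfr(c("well_watered", "drought"), function(condition) {
        tw <- turgid_mean * lognormal_factor(n, cv)
        dw <- pmin(dry_frac * tw * lognormal_factor(n, cv * 0.3), 0.9 * tw)
        target <- base + gain * tolerance -
          penalty * (1 - tolerance) * (condition == "drought")
        rwc_pct <- target + stats::rnorm(n, 0, cv * target)
        rwc_pct <- pmin(pmax(rwc_pct, 0.5), 100)
        fw <- dw + rwc_pct / 100 * (tw - dw)
        tibble::tibble(cultivar = cultivar, condition = condition,
                       plant_id = seq_len(n),
                       fresh_weight = fw, turgid_weight = tw,
                       dry_weight = dw)
      })
    })
  })
}

#' Simulate the wilting and recovery time-course experiment
#'
#' Wilting and recovery are modelled per plant as latent event days, then
#' aggregated to percentages on the fixed odd-day grid 1, 3, ..., 15 — so
#' the non-withered curve is always non-increasing, the recovered curve
#' non-decreasing, and with the default 25 plants every percentage is a
#' multiple of 4. A cultivar's median wilting day is
#' `wilt_base + wilt_gain * tolerance` days after withholding; plants still
#' turgid at day 15 survive the treatment outright. Among wilted plants the
#' probability of recovering under re-irrigation is
#' `rec_prob_base + rec_prob_gain * tolerance` (clamped to \[0, 1\]) and the
#' median recovery day is `rec_base - rec_gain * tolerance`; surviving
#' plants count as recovered from day 1.
#'
#' @param config A [panel_config()].
#' @param wilt_base,wilt_gain Median wilting day model (defaults 4 + 10 t:
#'   a fully sensitive cultivar wilts around day 4, a fully tolerant one
#'   around day 14).
#' @param rec_base,rec_gain Median recovery day model (defaults 12 - 9 t).
#' @param rec_prob_base,rec_prob_gain Recovery probability model
#'   (defaults 0.15 + 0.8 t).
#' @param event_sd Plant-to-plant standard deviation of the event days, in
#'   days. Defaults to `15 * noise_sd_frac` so the default noise level
#'   spreads events by 1.5 days.
#' @param days Observation grid (default the odd days 1 to 15).
#' @return A tibble in long form: `cultivar`, `day`, `d_pct` (% of plants
#'   not yet withered at that drought day), `r_pct` (% recovered by that
#'   re-irrigation day).
#' @export
#' @examples
#' tc <- simulate_timecourses(example_panel(n = 2, seed = 9))
#' tidyr::pivot_wider(tc, names_from = day, values_from = c(d_pct, r_pct))
simulate_timecourses <- function(config,
                                 wilt_base = 4, wilt_gain = 10,
                                 rec_base = 12, rec_gain = 9,
                                 rec_prob_base = 0.15, rec_prob_gain = 0.8,
                                 event_sd = 15 * config$noise_sd_frac,
                                 days = seq(1, 15, by = 2)) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_plants_dti
  last_day <- max(days)
  purrr::pmap_dfr(config$cultivars, function(cultivar, tolerance) {
    with_seed(cultivar_seed(config, cultivar, 3L), {
      wilt_day <- wilt_base + wilt_gain * tolerance +
        stats::rnorm(n, 0, event_sd)
      p_rec <- min(max(rec_prob_base + rec_prob_gain * tolerance, 0), 1)
      recovers <- stats::runif(n) < p_rec
      rec_day <- pmax(rec_base - rec_gain * tolerance +
                        stats::rnorm(n, 0, event_sd), 1)
      # plants that never wilted are trivially recovered from day 1;
      # wilted plants that fail to recover never enter the recovered count
      rec_day[wilt_day > last_day] <- 1
      rec_day[wilt_day <= last_day & !recovers] <- Inf
      tibble::tibble(
        cultivar = cultivar,
        day = days,
        d_pct = vapply(days, function(d) 100 * sum(wilt_day > d) / n, 0),
        r_pct = vapply(days, function(d) 100 * sum(rec_day <= d) / n, 0)
      )
    })
  })
}

#' Simulate soil moisture content monitoring
#'
#' Well-watered series fluctuate around a constant level; drought series
#' hold that level until watering stops at `onset_day`, then decay
#' exponentially toward a residual moisture. Sampling follows the 5-day
#' monitoring interval of the tube experiments.
#'
#' @param config A [panel_config()].
#' @param condition `"well_watered"` or `"drought"`.
#' @param level Watered soil moisture content, % (default 35).
#' @param residual Air-dry residual moisture, % (default 6).
#' @param decay_rate Exponential dry-down rate per day after onset
#'   (default 0.15).
#' @param onset_day Day water withholding begins (default 12).
#' @param days Sampling grid (default 0 to 30 by 5).
#' @return A tibble with columns `cultivar`, `condition`, `day`, `smc`.
#' @export
simulate_smc <- function(config, condition = c("well_watered", "drought"),
                         level = 35, residual = 6, decay_rate = 0.15,
                         onset_day = 12, days = seq(0, 30, by = 5)) {
  stopifnot(inherits(config, "panel_config"))
  condition <- match.arg(condition)
  mean_curve <- if (condition == "well_watered") {
    rep(level, length(days))
  } else {
    residual + (level - residual) * exp(-decay_rate * pmax(days - onset_day, 0))
  }
  purrr::pmap_dfr(config$cultivars, function(cultivar, tolerance) {
    with_seed(cultivar_seed(config, cultivar, 4L), {
      noise <- stats::rnorm(length(days), 0, config$noise_sd_frac * level * 0.2)
      tibble::tibble(cultivar = cultivar, condition = condition,
                     day = days,
                     smc = pmin(pmax(mean_curve + noise, 0), 100))
    })
  })
}

#' Simulate every table of a screening panel
#'
#' Convenience wrapper returning the four tables the evaluation pipeline
#' consumes.
#'
#' @param config A [panel_config()].
#' @return A named list of tibbles: `traits`, `water_content`,
#'   `timecourses`, `smc` (both conditions bound together).
#' @export
#' @examples
#' panel <- simulate_panel(example_panel(n = 3, seed = 11))
#' names(panel)
simulate_panel <- function(config) {
  list(
    traits = simulate_traits(config),
    water_content = simulate_water_content(config),
    timecourses = simulate_timecourses(config),
    smc = dplyr::bind_rows(simulate_smc(config, "well_watered"),
                           simulate_smc(config, "drought"))
  )
}
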