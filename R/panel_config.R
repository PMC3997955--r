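#' Describe a synthetic cultivar panel
#'
#' A panel configuration bundles everything the synthetic generators need:
#' the cultivar names with their latent tolerance scores, the per-cell
#' sample sizes of the three experiments, the plant-level noise model and
#' the seed. The latent `tolerance` (in \[0, 1\]) is the ground truth the
#' downstream analysis tries to recover: it jointly drives root and shoot
#' growth, water retention, wilting delay and recovery probability.
#'
#' @param cultivars A data frame with columns `cultivar` (character) and
#'   `tolerance` (numeric in \[0, 1\]), or a named numeric vector of
#'   tolerances.
#' @param n_plants_trait Plants per cultivar x stage x condition cell in the
#'   growth-trait experiment (default 30).
#' @param n_plants_rwc Plants per cultivar x condition cell in the
#'   water-content experiment (default 15).
#' @param n_plants_dti Plants per cultivar in the wilting/recovery
#'   experiment (default 25, so survival percentages are multiples of 4).
#' @param noise_sd_frac Plant-level coefficient of variation of the
#'   multiplicative log-normal measurement noise (default 0.1). Zero gives
#'   noise-free panels, useful for exact checks.
#' @param drought_effect Maximal multiplicative trait reduction under
#'   drought, reached at tolerance 0 (default 0.4; must be in (0, 1)).
#' @param seed Integer seed. Each cultivar gets its own reproducible
#'   substream derived from this seed and a stable hash of its name, so
#'   adding a cultivar never perturbs the draws of the others.
#'
#' @return An object of class `panel_config`.
#' @seealso [example_panel()], [simulate_traits()], [simulate_water_content()],
#'   [simulate_timecourses()], [simulate_smc()]
#' @export
#' @examples
#' cfg <- panel_config(c(A = 0.9, B = 0.1), seed = 42)
#' cfg
panel_config <- function(cultivars,
                         n_plants_trait = 30,
                         n_plants_rwc = 15,
                         n_plants_dti = 25,
                         noise_sd_frac = 0.1,
                         drought_effect = 0.4,
                         seed = 1L) {
  if (is.numeric(cultivars) && !is.null(names(cultivars))) {
    cultivars <- tibble::tibble(cultivar = names(cultivars),
                                tolerance = unname(cultivars))
  }
  if (!is.data.frame(cultivars) ||
      !all(c("cultivar", "tolerance") %in% names(cultivars))) {
    stop("`cultivars` must be a data frame with columns `cultivar` and ",
         "`tolerance`, or a named numeric vector", call. = FALSE)
  }
  cultivars <- tibble::as_tibble(cultivars[c("cultivar", "tolerance")])
  cultivars$cultivar <- as.character(cultivars$cultivar)
  if (anyDuplicated(cultivars$cultivar)) {
    stop("duplicate cultivar names in panel", call. = FALSE)
  }
  if (!all(is.finite(cultivars$tolerance)) ||
      any(cultivars$tolerance < 0 | cultivars$tolerance > 1)) {
    stop("tolerance values must be finite and in [0, 1]", call. = FALSE)
  }
  counts <- c(n_plants_trait = n_plants_trait,
              n_plants_rwc = n_plants_rwc,
              n_plants_dti = n_plants_dti)
  if (!all(is.finite(counts)) || any(counts < 2) ||
      any(counts != round(counts))) {
    stop("plant counts must be whole numbers >= 2", call. = FALSE)
  }
  if (!is.finite(noise_sd_frac) || noise_sd_frac < 0) {
    stop("`noise_sd_frac` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(drought_effect) || drought_effect <= 0 || drought_effect >= 1) {
    stop("`drought_effect` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(seed) || seed != round(seed)) {
    stop("`seed` must be an integer", call. = FALSE)
  }
  structure(
    list(cultivars = cultivars,
         n_plants_trait = as.integer(n_plants_trait),
         n_plants_rwc = as.integer(n_plants_rwc),
         n_plants_dti = as.integer(n_plants_dti),
         noise_sd_frac = noise_sd_frac,
         drought_effect = drought_effect,
         seed = as.integer(seed)),
    class = "panel_config"
  )
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config> ", nrow(x$cultivars), " cultivars, seed ", x$seed, "\n",
      "  n per cell: trait ", x$n_plants_trait, ", RWC ", x$n_plants_rwc,
      ", DTI ", x$n_plants_dti, "\n",
      "  noise CV ", x$noise_sd_frac, ", drought effect ", x$drought_effect,
      "\n", sep = "")
  invisible(x)
}

#' A ready-made 14-cultivar synthetic panel
#'
#' Fourteen synthetic cultivars (`SYN-01` ... `SYN-14`) with latent
#' tolerances evenly spread over \[0.1, 0.9\], mirroring the size of a
#' typical screening panel (13 local cultivars plus one reference line).
#'
#' @inheritParams panel_config
#' @param n Number of cultivars (default 14).
#' @return A `panel_config`.
#' @export
#' @examples
#' example_panel(seed = 7)
example_panel <- function(n = 14, seed = 1L, ...) {
  tol <- seq(0.1, 0.9, length.out = n)
  names(tol) <- sprintf("SYN-%02d", seq_len(n))
  panel_config(tol, seed = seed, ...)
}

# Stable 31-bit polynomial hash of a string; used to split the global seed
# into per-cultivar substreams independent of panel composition.
hash_label <- function(label) {
  bytes <- utf8ToInt(enc2utf8(label))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  h
}

cultivar_seed <- function(config, label, stream) {
  # distinct prime multipliers keep the trait/rwc/timecourse/smc streams apart
  (config$seed + 7919 * stream + hash_label(label)) %% 2147483629
}

# Run `expr` under a private RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Multiplicative log-normal noise factors with mean 1 and coefficient of
# variation `cv` (exactly 1 when cv = 0).
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Read or write a panel configuration as a flat YAML file
#'
#' The file holds the scalar fields of [panel_config()] at top level and a
#' `cultivars` mapping of name to tolerance.
#'
#' @param path File path.
#' @param config A `panel_config`.
#' @return `read_panel_config()` returns a `panel_config`;
#'   `write_panel_config()` returns `path` invisibly.
#' @export
read_panel_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tol <- unlist(raw$cultivars)
  panel_config(tol,
               n_plants_trait = raw$n_plants_trait %||% 30,
               n_plants_rwc = raw$n_plants_rwc %||% 15,
               n_plants_dti = raw$n_plants_dti %||% 25,
               noise_sd_frac = raw$noise_sd_frac %||% 0.1,
               drought_effect = raw$drought_effect %||% 0.4,
               seed = raw$seed %||% 1L)
}

#' @rdname read_panel_config
#' @export
write_panel_config <- function(config, path) {
  stopifnot(inherits(config, "panel_config"))
  out <- list(
    cultivars = as.list(stats::setNames(config$cultivars$tolerance,
                                        config$cultivars$cultivar)),
    n_plants_trait = config$n_plants_trait,
    n_plants_rwc = config$n_plants_rwc,
    n_plants_dti = config$n_plants_dti,
    noise_sd_frac = config$noise_sd_frac,
    drought_effect = config$drought_effect,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
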