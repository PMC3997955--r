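test_that("panel_config validates its fields", {
  expect_s3_class(panel_config(c(A = 0, B = 1)), "panel_config")
  expect_error(panel_config(c(A = -0.1, B = 0.5)), "tolerance")
  expect_error(panel_config(c(A = 0.2, B = 1.5)), "tolerance")
  expect_error(panel_config(c(A = 0.2, A = 0.5)), "duplicate")
  expect_error(panel_config(c(A = 0.2, B = 0.5), n_plants_dti = 1), "counts")
  expect_error(panel_config(c(A = 0.2, B = 0.5), noise_sd_frac = NaN),
               "noise_sd_frac")
  expect_error(panel_config(c(A = 0.2, B = 0.5), drought_effect = 1),
               "drought_effect")
  expect_error(panel_config(c(A = 0.2, B = 0.5), seed = 1.5), "seed")
})

test_that("identical configs generate identical panels", {
  cfg <- tiny_config(n = 3, seed = 7)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
})

test_that("adding a cultivar does not perturb the draws of the others", {
  small <- panel_config(c(Alpha = 0.3, Beta = 0.7), seed = 5)
  big <- panel_config(c(Alpha = 0.3, Beta = 0.7, Gamma = 0.5), seed = 5)
  t_small <- simulate_traits(small)
  t_big <- dplyr::filter(simulate_traits(big), cultivar != "Gamma")
  expect_equal(as.data.frame(t_small), as.data.frame(t_big))
})

test_that("noise-free cell means follow the tolerance/drought model exactly", {
  cfg <- panel_config(c(lo = 0, hi = 1), noise_sd_frac = 0,
                      drought_effect = 0.4, n_plants_trait = 2, seed = 1)
  tr <- simulate_traits(cfg, stages = "seedling")
  cell <- tr |>
    dplyr::group_by(cultivar, condition) |>
    dplyr::summarise(m = mean(taproot_length), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = m)
  ratio <- cell$drought / cell$well_watered
  expect_equal(ratio[cell$cultivar == "hi"], 1.0)
  expect_equal(ratio[cell$cultivar == "lo"], 0.6)
  base <- trait_baselines()
  b <- base[base$trait == "taproot_length" & base$stage == "seedling", ]
  expect_equal(cell$well_watered[cell$cultivar == "hi"],
               b$baseline * (1 + b$span))
  expect_equal(cell$well_watered[cell$cultivar == "lo"], b$baseline)
})

test_that("plant-level noise realises the configured coefficient of variation", {
  cfg <- panel_config(c(A = 0.5), noise_sd_frac = 0.1, n_plants_trait = 200,
                      seed = 11)
  tr <- simulate_traits(cfg, stages = "seedling")
  cv <- tr |>
    dplyr::group_by(condition) |>
    dplyr::summarise(cv = stats::sd(taproot_length) / mean(taproot_length))
  expect_true(all(cv$cv > 0.07 & cv$cv < 0.13))
})

test_that("water-content records always satisfy DW < FW <= TW", {
  for (seed in 1:5) {
    wc <- simulate_water_content(tiny_config(n = 3, seed = seed,
                                             noise_sd_frac = 0.2))
    expect_true(all(wc$dry_weight < wc$fresh_weight))
    expect_true(all(wc$fresh_weight <= wc$turgid_weight))
  }
})

test_that("noise-free water content hits the RWC target exactly", {
  cfg <- panel_config(c(top = 1), noise_sd_frac = 0, n_plants_rwc = 2,
                      seed = 2)
  wc <- simulate_water_content(cfg, base = 74, gain = 10, penalty = 8)
  got <- compute_rwc(wc) |>
    dplyr::group_by(condition) |>
    dplyr::summarise(rwc = mean(rwc))
  expect_equal(got$rwc[got$condition == "well_watered"], 84)
  expect_equal(got$rwc[got$condition == "drought"], 84)  # no penalty at tol 1
  lo <- simulate_water_content(panel_config(c(bot = 0), noise_sd_frac = 0,
                                            n_plants_rwc = 2, seed = 2))
  got_lo <- compute_rwc(lo) |>
    dplyr::group_by(condition) |>
    dplyr::summarise(rwc = mean(rwc))
  expect_equal(got_lo$rwc[got_lo$condition == "drought"], 74 - 8)
})

test_that("mean computed RWC tracks the target under noise", {
  cfg <- panel_config(c(A = 0.6), noise_sd_frac = 0.1, n_plants_rwc = 500,
                      seed = 4)
  got <- compute_rwc(simulate_water_content(cfg)) |>
    dplyr::group_by(condition) |>
    dplyr::summarise(rwc = mean(rwc))
  target_ww <- 74 + 10 * 0.6
  target_dr <- target_ww - 8 * 0.4
  expect_lt(abs(got$rwc[got$condition == "well_watered"] - target_ww), 1)
  expect_lt(abs(got$rwc[got$condition == "drought"] - target_dr), 1)
})

test_that("time courses are percentages in multiples of 4 with 25 plants", {
  tc <- simulate_timecourses(tiny_config(n = 4, seed = 9))
  expect_true(all(tc$d_pct %in% seq(0, 100, by = 4)))
  expect_true(all(tc$r_pct %in% seq(0, 100, by = 4)))
})

test_that("survival curves are monotone and recovery is cumulative", {
  for (seed in 1:5) {
    tc <- simulate_timecourses(tiny_config(n = 3, seed = seed))
    by_cv <- split(tc, tc$cultivar)
    for (df in by_cv) {
      df <- df[order(df$day), ]
      expect_true(all(diff(df$d_pct) <= 0))
      expect_true(all(diff(df$r_pct) >= 0))
    }
  }
})

test_that("a cultivar too tolerant to wilt keeps a flat 100% survival curve", {
  cfg <- panel_config(c(iron = 1), noise_sd_frac = 0, seed = 3)
  tc <- simulate_timecourses(cfg, wilt_base = 10, wilt_gain = 10)
  expect_true(all(tc$d_pct == 100))
  expect_true(all(tc$r_pct == 100))  # unwilted plants count as recovered
})

test_that("noise-free generator summaries are monotone in tolerance", {
  tol <- c(A = 0.1, B = 0.5, C = 0.9)
  cfg <- panel_config(tol, noise_sd_frac = 0, n_plants_trait = 2,
                      n_plants_rwc = 2, seed = 6)
  m <- simulate_traits(cfg, stages = "seedling") |>
    dplyr::filter(condition == "well_watered") |>
    dplyr::group_by(cultivar) |>
    dplyr::summarise(m = mean(taproot_length))
  expect_true(all(diff(m$m[order(m$cultivar)]) > 0))
  r <- compute_rwc(simulate_water_content(cfg)) |>
    dplyr::filter(condition == "drought") |>
    dplyr::group_by(cultivar) |>
    dplyr::summarise(m = mean(rwc))
  expect_true(all(diff(r$m[order(r$cultivar)]) > 0))
  tc <- simulate_timecourses(cfg)
  dti <- compute_dti(tc)
  expect_true(all(diff(dti$dti[order(dti$cultivar)]) > 0))
})

test_that("soil moisture series behave by condition", {
  cfg0 <- tiny_config(n = 2, seed = 8, noise_sd_frac = 0)
  ww <- simulate_smc(cfg0, "well_watered", level = 35)
  expect_true(all(ww$smc == 35))
  flat <- simulate_smc(cfg0, "drought", decay_rate = 0, level = 35)
  expect_true(all(flat$smc == 35))
  dry <- simulate_smc(cfg0, "drought", decay_rate = 0.2, onset_day = 12)
  for (df in split(dry, dry$cultivar)) {
    after <- df[df$day >= 12, ]
    expect_true(all(diff(after$smc[order(after$day)]) <= 0))
  }
  expect_error(simulate_smc(cfg0, "flooded"))
})

test_that("panel configs round-trip through YAML", {
  cfg <- tiny_config(n = 3, seed = 42, noise_sd_frac = 0.15)
  path <- withr::local_tempfile(fileext = ".yml")
  write_panel_config(cfg, path)
  expect_equal(read_panel_config(path), cfg)
})
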