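test_that("one-way ANOVA matches the classical fit on simulated data", {
  set.seed(21)
  for (rep in 1:10) {
    df <- draw_panel_values(means = runif(3, 8, 14), n = 5)
    ours <- anova_oneway(df, value, group)
    ref <- stats::anova(stats::aov(value ~ group, data = df))
    expect_equal(ours$f_stat, ref$`F value`[1])
    expect_equal(ours$p_value, ref$`Pr(>F)`[1])
    expect_equal(ours$mse, ref$`Mean Sq`[2])
    expect_equal(ours$df_error, ref$Df[2])
  }
})

test_that("ANOVA handles degenerate variance structures", {
  same <- data.frame(g = rep(c("a", "b"), each = 3), y = 5)
  fit0 <- anova_oneway(same, y, g)
  expect_equal(fit0$f_stat, 0)
  expect_equal(fit0$p_value, 1)
  sep <- data.frame(g = rep(c("a", "b"), each = 2), y = c(0, 0, 1, 1))
  fit1 <- anova_oneway(sep, y, g)
  expect_equal(fit1$mse, 0)
  expect_equal(fit1$f_stat, Inf)
  expect_equal(fit1$p_value, 0)
  expect_error(anova_oneway(data.frame(g = c("a", "a", "b"), y = 1:3), y, g),
               "fewer than 2")
  expect_error(anova_oneway(data.frame(g = "a", y = 1:4), y, g), "2 groups")
})

test_that("Duncan critical values reproduce published table entries", {
  # significant studentized ranges, alpha = 0.05, df = 20, spans 2..5
  fit <- anova_oneway(draw_panel_values(rep(10, 5), n = 5), value, group)
  stopifnot(fit$df_error == 20)
  d <- duncan_mrt(fit, alpha = 0.05)
  published <- c(2.950, 3.097, 3.190, 3.255)
  expect_equal(d$lsr$critical, published, tolerance = 5e-4)
  expect_true(all(diff(d$lsr$lsr) >= 0))  # LSR non-decreasing in span
})

test_that("all-equal means are lettered 'a' across the board", {
  df <- data.frame(g = rep(letters[1:4], each = 3), y = 7)
  d <- duncan_mrt(anova_oneway(df, y, g))
  expect_true(all(d$groups$letters == "a"))
})

test_that("zero error variance separates every pair of distinct means", {
  df <- data.frame(g = rep(letters[1:3], each = 2), y = rep(c(1, 2, 2), each = 2))
  d <- duncan_mrt(anova_oneway(df, y, g))
  lt <- setNames(d$groups$letters, d$groups$group)
  expect_equal(unname(lt["b"]), unname(lt["c"]))  # tied means share a letter
  expect_false(lt["a"] %in% c(lt["b"], lt["c"]))
})

test_that("with two groups Duncan reduces to Fisher's LSD", {
  set.seed(33)
  for (rep in 1:200) {
    df <- draw_panel_values(means = c(10, 10 + runif(1, 0, 2)), n = 6)
    fit <- anova_oneway(df, value, group)
    d <- duncan_mrt(fit, alpha = 0.05)
    diff_means <- abs(diff(fit$groups$mean))
    lsd <- stats::qt(0.975, fit$df_error) * sqrt(2 * fit$mse / 6)
    expect_equal(any(d$separated), diff_means > lsd)
  }
})

test_that("letters match the exhaustive range-scan oracle", {
  set.seed(44)
  for (rep in 1:100) {
    k <- sample(4:8, 1)
    df <- draw_panel_values(means = runif(k, 0, 3), n = sample(4:8, 1))
    d <- duncan_mrt(anova_oneway(df, value, group))
    lsr_by_span <- c(Inf, d$lsr$lsr)  # span 1 never separates
    oracle <- oracle_duncan_separation(d$groups$mean, lsr_by_span)
    expect_identical(unname(d$separated), oracle)
    # lettering soundness: share a letter <=> not separated
    expect_identical(shares_letter(d$groups$letters), !oracle)
  }
})

test_that("letter assignment reproduces the textbook overlap pattern", {
  sep <- matrix(FALSE, 3, 3)
  sep[1, 3] <- sep[3, 1] <- TRUE
  expect_equal(unname(assign_letters(sep, c("A", "B", "C"))),
               c("a", "ab", "b"))
  none <- matrix(FALSE, 3, 3)
  expect_equal(unname(assign_letters(none, c("A", "B", "C"))),
               rep("a", 3))
})

test_that("letter assignment rejects inconsistent relations", {
  bad <- matrix(FALSE, 2, 2)
  bad[1, 2] <- TRUE
  expect_error(assign_letters(bad, c("A", "B")), "symmetric")
  refl <- diag(TRUE, 2)
  expect_error(assign_letters(refl, c("A", "B")), "irreflexive")
})

test_that("letter sharing round-trips random interval-structured relations", {
  set.seed(55)
  for (rep in 1:50) {
    k <- 6
    # build an interval-structured non-separation relation from random
    # reach points (non-decreasing right end per row)
    reach <- pmin(seq_len(k) + sort(sample(0:3, k, replace = TRUE)), k)
    reach <- cummax(reach)
    sep <- matrix(TRUE, k, k)
    for (i in seq_len(k)) for (j in i:min(reach[i], k)) {
      sep[i, j] <- sep[j, i] <- FALSE
    }
    diag(sep) <- FALSE
    lt <- assign_letters(sep, sprintf("g%d", seq_len(k)))
    expect_identical(shares_letter(lt), !sep)
  }
})

test_that("cell-wise cultivar comparison letters every trait cell", {
  traits <- simulate_traits(tiny_config(n = 4, seed = 12),
                            stages = c("seedling", "V3"))
  out <- compare_cultivars(traits)
  expect_equal(nrow(out), 4 * 2 * 2 * 4)  # trait x stage x condition x cultivar
  expect_true(all(nchar(out$letters) >= 1))
  expect_named(out, c("trait", "stage", "condition", "cultivar",
                      "n", "mean", "se", "letters"))
})
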