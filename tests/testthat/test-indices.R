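test_that("rwc reproduces hand-computed values and boundary identities", {
  expect_equal(rwc(2, 3, 1), 50)
  expect_equal(rwc(3, 3, 1), 100)
  expect_equal(rwc(1, 3, 1), 0)
  expect_equal(rwc(1.8, 2.0, 0.4), 87.5)
})

test_that("rwc is invariant under joint rescaling of the weights", {
  set.seed(31)
  for (i in 1:50) {
    dw <- runif(1, 0.1, 1)
    tw <- dw + runif(1, 0.1, 2)
    fw <- runif(1, dw, tw)
    c_scale <- runif(1, 0.01, 50)
    expect_equal(rwc(c_scale * fw, c_scale * tw, c_scale * dw),
                 rwc(fw, tw, dw))
  }
})

test_that("rwc rejects impossible triples and warns on noisy ones", {
  expect_error(rwc(2, 1, 1), "turgid")
  expect_warning(v <- rwc(3.1, 3, 1), "unclipped")
  expect_gt(v, 100)
  wc <- tibble::tibble(cultivar = "A", plant_id = 1:2,
                       fresh_weight = c(2, 2), turgid_weight = c(3, 1),
                       dry_weight = c(1, 1.5))
  expect_error(compute_rwc(wc), "A/plant 2")
})

test_that("DTI matches its closed forms", {
  layout <- radar_layout()
  expect_equal(dti_area(rep(0, 16)), 0)
  expect_equal(dti_area(rep(100, 16)), 8 * sin(22.5 * pi / 180) * 1e4)
  # single adjacent pair: one triangle of area 1/2 sin(alpha)
  axes <- c(1, 1, rep(0, 14))
  expect_equal(radar_polygon_area(axes, layout), 0.5 * sin(22.5 * pi / 180))
  expect_equal(dti_area(axes), 0.5 * sin(22.5 * pi / 180))
  # zero whenever no two adjacent axes are both positive
  alternating <- rep(c(50, 0), 8)
  expect_equal(dti_area(alternating), 0)
})

test_that("DTI equals the shoelace polygon oracle on random axis vectors", {
  layout <- radar_layout()
  set.seed(7)
  for (i in 1:100) {
    axes <- runif(16, 0, 100)
    a1 <- dti_area(axes)
    a2 <- radar_polygon_area(axes, layout)
    expect_lt(abs(a1 - a2), 1e-9 * max(1, a2))
  }
})

test_that("DTI obeys the scale law and the percentage bound", {
  set.seed(8)
  for (i in 1:25) {
    axes <- runif(16, 0, 100)
    c_scale <- runif(1, 0.1, 3)
    expect_equal(dti_area(c_scale * axes), c_scale^2 * dti_area(axes))
    expect_lte(dti_area(axes), 8 * sin(22.5 * pi / 180) * 1e4)
  }
})

test_that("raising one axis with positive neighbours strictly raises DTI", {
  set.seed(9)
  axes <- runif(16, 10, 90)
  for (k in c(1, 5, 16)) {
    bumped <- axes
    bumped[k] <- bumped[k] + 1
    expect_gt(dti_area(bumped), dti_area(axes))
  }
})

test_that("compute_dti validates its inputs", {
  tc <- simulate_timecourses(tiny_config(n = 2, seed = 1))
  expect_error(compute_dti(dplyr::select(tc, -r_pct)), "missing column")
  short <- dplyr::filter(tc, day < 15)
  expect_error(compute_dti(short), "layout grid")
  neg <- tc
  neg$d_pct[1] <- -5
  expect_error(compute_dti(neg), "non-negative")
})

test_that("cultivar ranking is descending with min-rank ties by label", {
  one <- rank_cultivars(tibble::tibble(cultivar = "solo", dti = 4))
  expect_equal(one$rank, 1L)
  tied <- rank_cultivars(tibble::tibble(cultivar = c("B", "A", "C"),
                                        dti = c(5, 3, 5)))
  expect_equal(tied$cultivar, c("B", "C", "A"))
  expect_equal(tied$rank, c(1L, 1L, 3L))
  expect_error(rank_cultivars(tibble::tibble(cultivar = c("A", "A"),
                                             dti = c(1, 2))), "duplicate")
})

test_that("ranking agrees with sorting by the shoelace oracle", {
  layout <- radar_layout()
  for (rep in 1:20) {
    tc <- simulate_timecourses(tiny_config(n = 5, seed = rep))
    ranked <- rank_cultivars(compute_dti(tc, layout))
    oracle <- vapply(split(tc, tc$cultivar), function(df) {
      df <- df[order(df$day), ]
      radar_polygon_area(as.vector(rbind(df$d_pct, df$r_pct)), layout)
    }, 0)
    expected <- names(oracle)[order(-oracle, names(oracle))]
    expect_equal(ranked$cultivar, expected)
  }
})
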