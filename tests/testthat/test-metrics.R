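test_that("session load is duration times RPE with validated inputs", {
  expect_equal(session_load(60, 4), 240)
  expect_equal(session_load(0, 7), 0)
  expect_equal(session_load(90, 7), 630)
  expect_error(session_load(-10, 5), class = "acwrbayes_error_invalid_input")
  expect_error(session_load(60, 11), class = "acwrbayes_error_invalid_input")
  expect_error(session_load(60, -1), class = "acwrbayes_error_invalid_input")
})

test_that("session load is bilinear in duration and RPE", {
  set.seed(11)
  d <- runif(50, 0, 120)
  r <- runif(50, 0, 5)
  expect_equal(session_load(2 * d, r), 2 * session_load(d, r))
  expect_equal(session_load(d, 2 * r), 2 * session_load(d, r))
})

test_that("acute load sums one player-week and rejects mixed weeks", {
  s <- tibble::tibble(
    player_id = "A", week = 1L, day = 1:3,
    duration_min = c(60, 60, 115), rpe = c(4, 5, 4)
  )
  expect_equal(acute_load(s), 240 + 300 + 460)
  expect_equal(acute_load(s[0, ]), 0)
  s7 <- tibble::tibble(
    player_id = "A", week = 2L, day = 1:7, duration_min = 60, rpe = 5
  )
  expect_equal(acute_load(s7), 2100)
  mixed <- dplyr::bind_rows(s, s7)
  expect_error(acute_load(mixed), class = "acwrbayes_error_invalid_input")
})

test_that("cumulative and chronic loads use trailing windows", {
  expect_equal(cumulative_load(c(1000, 1200), 2), 2200)
  expect_equal(cumulative_load(500, 1), 500)
  expect_equal(cumulative_load(rep(400, 4), 4), 1600)
  expect_error(cumulative_load(c(1, 2), 3), class = "acwrbayes_error_undefined_value")
  expect_equal(chronic_load(rep(1000, 4)), 1000)
  expect_equal(chronic_load(c(800, 1200, 1600, 2000)), 1400)
  expect_error(chronic_load(1:3), class = "acwrbayes_error_undefined_value")
})

test_that("chronic load times four equals the 4-week cumulative load", {
  set.seed(2)
  for (i in 1:20) {
    w <- runif(sample(4:10, 1), 500, 3000)
    expect_equal(4 * chronic_load(w), cumulative_load(w, 4))
    expect_equal(cumulative_load(w, 1), tail(w, 1))
  }
})

test_that("ACWR is acute over chronic and equals 1 for constant load", {
  expect_equal(acwr(2000, 1600), 1.25)
  w <- rep(1234, 8)
  expect_equal(acwr(tail(w, 1), chronic_load(w)), 1)
  expect_error(acwr(1000, 0), class = "acwrbayes_error_undefined_value")
  # scale consistency: squad medians acute 1800 / chronic 1900 sit near 1
  expect_equal(acwr(1800, 1900), 1800 / 1900)
})

test_that("ACWRr divides by a reproducible truncated-normal denominator", {
  expect_equal(acwrr(0, seed = 1), 0)
  a <- c(1500, 1900, 2300)
  expect_identical(acwrr(a, seed = 9), acwrr(a, seed = 9))
  expect_error(acwrr(100, denominator_sd = 0, seed = 1),
    class = "acwrbayes_error_invalid_input"
  )
  expect_error(acwrr(-5, seed = 1), class = "acwrbayes_error_invalid_input")
  expect_error(acwrr(100), class = "acwrbayes_error_invalid_input")
  # sd -> 0 limit: denominator collapses to its mean
  expect_equal(acwrr(1900, denominator_sd = 1e-9, seed = 3), 1, tolerance = 1e-8)
  # median over many draws sits near acute/mean, and the spread is wide
  r <- acwrr(rep(1900, 20000), seed = 5)
  expect_equal(median(r), 1, tolerance = 0.03)
  expect_gt(quantile(r, 0.75) - quantile(r, 0.25), 0.3)
})

test_that("ACWRr denominator respects the positivity floor", {
  # sd much larger than mean would produce many negative draws without rejection
  r <- acwrr(rep(100, 5000), denominator_mean = 100, denominator_sd = 500,
    floor = 50, seed = 8
  )
  expect_true(all(r > 0))
  expect_true(all(r < 100 / 50))
})

test_that("monotony is mean over sample SD of daily loads", {
  expect_equal(monotony(c(100, 300)), 200 / sd(c(100, 300)))
  expect_equal(monotony(c(100, 300)), 1.41421356, tolerance = 1e-6)
  expect_error(monotony(rep(250, 7)), class = "acwrbayes_error_undefined_value")
  expect_error(monotony(rep(0, 7)), class = "acwrbayes_error_undefined_value")
  expect_error(monotony(100), class = "acwrbayes_error_invalid_input")
})

test_that("quartile binning uses interpolated percentiles, upper-inclusive", {
  b <- fit_quantile_binning(1:8)
  expect_equal(b$cut_points, c(2.75, 4.5, 6.25))
  expect_equal(unname(table(bin_values(b, 1:8))), rep(2L, 4), ignore_attr = TRUE)
  # a value equal to a cut point falls in the lower bin
  expect_equal(bin_values(b, c(2.75, 4.5, 6.25)), c(1L, 2L, 3L))
  expect_error(fit_quantile_binning(c(1, 1, 2, 2)), class = "acwrbayes_error_invalid_input")
})

test_that("binning its own training sample gives four near-equal groups", {
  set.seed(4)
  for (n in c(40, 815, 1000)) {
    v <- runif(n)
    b <- fit_quantile_binning(v)
    sizes <- tabulate(bin_values(b, v), 4)
    expect_lte(max(sizes) - min(sizes), 2)
    expect_equal(sum(sizes), n)
  }
})

test_that("weekly loads roll windows over the calendar grid", {
  w <- weekly_loads(toy_sessions())
  expect_equal(nrow(w), 5)
  expect_equal(w$acute_load, rep(840, 5))
  expect_equal(w$chronic_load, c(NA, NA, NA, 840, 840))
  expect_equal(w$acwr, c(NA, NA, NA, 1, 1))
  expect_equal(w$cumulative_load_2w, c(NA, rep(1680, 4)))
  # a gap week breaks the windows
  gap <- toy_sessions() %>% dplyr::filter(week != 3)
  wg <- weekly_loads(gap)
  expect_false(wg$trained[wg$week == 3])
  expect_true(all(is.na(wg$chronic_load[wg$week %in% 3:5])))
})

test_that("uncoupled chronic load excludes the current week", {
  s <- tibble::tibble(
    player_id = "A", week = rep(1:5, each = 1), day = 1L,
    duration_min = c(100, 100, 100, 100, 200), rpe = 5
  )
  w <- weekly_loads(s, coupled = FALSE)
  # week 5: previous four weeks all 500 AU
  expect_equal(w$chronic_load[5], 500)
  expect_equal(w$acwr[5], 1000 / 500)
  wc <- weekly_loads(s, coupled = TRUE)
  expect_equal(wc$chronic_load[5], mean(c(500, 500, 500, 1000)))
})

test_that("observation table keeps complete-history weeks and labels injury-preceding weeks", {
  obs <- suppressWarnings(build_observation_table(toy_sessions(),
    injuries = tibble::tibble(player_id = "A", onset_week = 5L, days_lost = 7),
    seed = 1
  ))
  # 5 recorded weeks -> chronic defined in weeks 4 and 5 only
  expect_equal(nrow(obs), 2)
  expect_equal(obs$week, c(4L, 5L))
  expect_equal(obs$injured, c(TRUE, FALSE))

  no_inj <- suppressWarnings(build_observation_table(toy_sessions(), seed = 1))
  expect_false(any(no_inj$injured))

  expect_error(
    build_observation_table(toy_sessions(),
      injuries = tibble::tibble(player_id = "ZZ", onset_week = 3L), seed = 1
    ),
    class = "acwrbayes_error_invalid_input"
  )
  expect_error(build_observation_table(toy_sessions()),
    class = "acwrbayes_error_invalid_input"
  )
})

test_that("an injury without a preceding observation row warns and is dropped", {
  expect_warning(
    obs <- suppressWarnings(
      build_observation_table(toy_sessions(),
        injuries = tibble::tibble(player_id = "A", onset_week = 2L), seed = 1
      ),
      classes = "acwrbayes_warning_binning"
    ),
    class = "acwrbayes_warning_unattached_injury"
  )
  expect_false(any(obs$injured))
})
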