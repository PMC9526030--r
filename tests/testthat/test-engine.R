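test_that("a silent arena yields zero completion; a loud one saturates", {
  g <- hex_grid(10, 11, 1000)
  w <- make_weather(days = 1)
  # source below threshold: audible radius 0, no contact possible
  cfg0 <- scenario_config(freq = 8000, source_level = 20)
  set.seed(21)
  day0 <- run_day(g, init_birds(g), morning_window(w, 1), cfg0)
  expect_equal(day0$end_pct, 0)
  expect_true(all(day0$completion$pct == 0))
  # radius capped at max_radius >= arena diagonal: everyone finishes
  cfg1 <- scenario_config(freq = 200)
  set.seed(22)
  day1 <- run_day(g, init_birds(g), morning_window(w, 1), cfg1)
  expect_equal(day1$end_pct, 100)
  # completion curves never decrease within a day
  expect_true(all(diff(day0$completion$pct) >= 0))
  expect_true(all(diff(day1$completion$pct) >= 0))
})

test_that("contact sets stay symmetric and nondecreasing through a day", {
  g <- hex_grid(5, 6, 800)
  w <- make_weather(days = 1, profile = "drought")
  cfg <- scenario_config(freq = 8000, rows = 5, cols = 6, diameter = 800)
  set.seed(23)
  birds <- init_birds(g)
  mid <- run_day(g, birds, morning_window(w, 1),
                 scenario_config(freq = 8000, rows = 5, cols = 6,
                                 diameter = 800, steps_per_day = 100))
  for (i in seq_len(nrow(g$territories))) {
    for (j in mid$birds$contacts[[i]]) {
      expect_true(i %in% mid$birds$contacts[[j]])
    }
    expect_true(all(mid$birds$contacts[[i]] %in% g$adjacency[[i]]))
  }
  # continuing the same day from the midpoint state only adds contacts
  set.seed(24)
  more <- run_day(g, mid$birds, morning_window(w, 1), cfg)
  for (i in seq_len(nrow(g$territories))) {
    expect_true(all(mid$birds$contacts[[i]] %in% more$birds$contacts[[i]]))
  }
})

test_that("with EWL disabled the water budget never engages", {
  g <- hex_grid(3, 3, 500)
  w <- make_weather(days = 1, profile = "drought")
  set.seed(25)
  day <- run_day(g, init_birds(g), morning_window(w, 1),
                 scenario_config(freq = 8000, rows = 3, cols = 3,
                                 diameter = 500))
  expect_true(all(day$birds$tewl == 0))
  expect_false(any(day$birds$incapacitated))
})

test_that("scenario runs are deterministic under a fixed seed", {
  w <- synthetic_weather(days = 2, seed = 30)
  cfg <- scenario_config(freq = 8000, iterations = 2, seed = 77,
                         ewl = ewl_model(enabled = TRUE))
  a <- run_scenario(w, cfg)
  b <- run_scenario(w, cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$daily, b$daily)
  expect_identical(a$curve, b$curve)
  expect_error(run_scenario(w, scenario_config(days = 5)),
               class = "songscape_data_error")
})

test_that("completion summaries expose tidy, glance and plot methods", {
  w <- synthetic_weather(days = 2, seed = 31)
  cs <- run_scenario(w, scenario_config(freq = 12000, iterations = 3,
                                        seed = 5))
  expect_s3_class(cs, "completion_summary")
  expect_true(all(cs$curve$mean_pct >= 0 & cs$curve$mean_pct <= 100))
  expect_true(all(diff(cs$curve$mean_pct) >= -1e-9))
  td <- tidy(cs)
  expect_named(td, c("iteration", "day", "pct"))
  expect_equal(nrow(td), 6)
  gl <- glance(cs)
  expect_equal(gl$n, 3)
  expect_equal(gl$mean_pct, cs$summary$mean_pct)
  expect_gte(gl$se, 0)
  expect_s3_class(autoplot(cs), "ggplot")
})

test_that("iteration summaries match the textbook mean/SE formulas", {
  expect_equal(summarize_iterations(rep(50, 5)),
               list(mean = 50, se = 0, n = 5L))
  expect_equal(summarize_iterations(c(0, 100)),
               list(mean = 50, se = 50, n = 2L))
  expect_equal(summarize_iterations(7)$se, 0)
  set.seed(40)
  v <- runif(17, 0, 100)
  s <- summarize_iterations(v)
  expect_equal(s$mean, sum(v) / 17)
  expect_equal(s$se, sqrt(sum((v - mean(v))^2) / 16) / sqrt(17))
  expect_error(summarize_iterations(numeric(0)),
               class = "songscape_invalid_input")
})

test_that("two-bird sweeps cover the requested grid and sane limits", {
  w <- make_weather(days = 1)
  sw <- run_pairwise_sweep(w, freqs = c(1000, 6000, 12000),
                           radii = c(25, 300, 900), iterations = 2,
                           seed = 50)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw$grid), 9)
  expect_true(all(sw$grid$contact_pct >= 0 & sw$grid$contact_pct <= 100))
  # tiny adjacent territories at a low frequency: every song connects
  expect_equal(
    dplyr::filter(sw$grid, freq == 1000, radius == 25)$contact_pct, 100)
  # contact falls (weakly) with separation at each frequency
  by_freq <- sw$grid |>
    dplyr::group_by(freq) |>
    dplyr::summarise(drop = dplyr::first(contact_pct) -
                       dplyr::last(contact_pct))
  expect_true(all(by_freq$drop >= 0))
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("sweep differences are antisymmetric and validated", {
  w <- make_weather(days = 1)
  sw_a <- run_pairwise_sweep(w, freqs = c(4000, 9000), radii = c(200, 600),
                             iterations = 2, seed = 51, label = "mild")
  sw_b <- run_pairwise_sweep(apply_climate_delta(w), freqs = c(4000, 9000),
                             radii = c(200, 600), iterations = 2, seed = 51,
                             label = "harsh")
  self <- diff_grid(sw_a, sw_a)
  expect_true(all(self$grid$diff_pct == 0))
  ab <- diff_grid(sw_a, sw_b)
  ba <- diff_grid(sw_b, sw_a)
  expect_equal(ab$grid$diff_pct, -ba$grid$diff_pct)
  sw_small <- run_pairwise_sweep(w, freqs = 4000, radii = c(200, 600),
                                 iterations = 2, seed = 51)
  expect_error(diff_grid(sw_a, sw_small), class = "songscape_invalid_input")
  expect_s3_class(autoplot(ab), "ggplot")
})

test_that("event logs record induced songs and failed-song penalties", {
  g <- hex_grid(3, 3, 400)
  w <- make_weather(days = 1)
  cfg <- scenario_config(freq = 200, rows = 3, cols = 3, diameter = 400,
                         steps_per_day = 30)
  set.seed(60)
  day <- run_day(g, init_birds(g), morning_window(w, 1), cfg,
                 log_events = TRUE)
  ev <- day$events
  expect_named(ev, c("step", "id", "behavior", "sang", "penalized"))
  expect_equal(nrow(ev), 30 * 9)
  # radius covers the arena: a failed song is impossible, so no penalties
  expect_false(any(ev$penalized))
  # induced cascades: some birds sang without choosing to, and several
  # birds end up singing in the same step
  expect_true(any(ev$sang & ev$behavior != "sing"))
  sings <- ev |>
    dplyr::filter(sang) |>
    dplyr::count(step)
  expect_gt(max(sings$n), 1)
})
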