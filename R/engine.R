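#' Scenario configuration
#'
#' Bundles everything a population run needs besides the weather series:
#' the song, the arena, the water-budget model, the schedule and the
#' random seed. Defaults follow the standard study design: a 10 x 11
#' hexagonal arena (110 territories, 72 interior), 1-km territories,
#' 360 one-minute steps per morning, 5 iterations.
#'
#' @param freq Song carrier frequency, Hz.
#' @param diameter Territory flat-to-flat diameter, m.
#' @param rows,cols Arena dimensions.
#' @param days Number of days to simulate; `NULL` uses every day present in
#'   the weather series.
#' @param steps_per_day One-minute time steps per day.
#' @param iterations Independent replicate runs.
#' @param seed Master seed; per-iteration streams are derived from it.
#' @param source_level,ref_distance Song source level (dB) and its
#'   reference distance (m); see [song_spec()].
#' @param threshold,mode,max_radius Propagation settings; see
#'   [propagation_settings()].
#' @param ewl An [ewl_model()]; disabled by default.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config(freq = 8000, days = 10)
#' @export
scenario_config <- function(freq = 8000, diameter = 1000,
                            rows = 10, cols = 11,
                            days = NULL, steps_per_day = 360,
                            iterations = 5, seed = 1,
                            source_level = 90, ref_distance = 1,
                            threshold = 30,
                            mode = c("absorption_only",
                                     "spreading_plus_absorption"),
                            max_radius = 5e4,
                            ewl = ewl_model(enabled = FALSE)) {
  mode <- match.arg(mode)
  if (!is.null(days) && days < 1) {
    abort("`days` must be >= 1.", class = "songscape_invalid_input")
  }
  if (iterations < 1) {
    abort("`iterations` must be >= 1.", class = "songscape_invalid_input")
  }
  structure(
    list(freq = freq, diameter = diameter, rows = rows, cols = cols,
         days = days, steps_per_day = steps_per_day,
         iterations = iterations, seed = seed,
         song = song_spec(freq, source_level, ref_distance),
         settings = propagation_settings(threshold, mode, max_radius),
         ewl = ewl),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %.0f Hz, %g m territories, %d x %d grid, %s days x %d steps, %d iterations, EWL %s\n",
    x$freq, x$diameter, x$rows, x$cols,
    if (is.null(x$days)) "all" else as.character(x$days),
    x$steps_per_day, x$iterations, if (x$ewl$enabled) "on" else "off"))
  invisible(x)
}

#' Simulate one morning for a bird population
#'
#' Runs one day of the model: at each one-minute step the audible radius is
#' recomputed from that minute's weather, every active bird chooses a
#' behavior, movers relocate, singers trigger same-step induced-singing
#' cascades, and (if enabled) the water budget advances. Contacts,
#' penalties, positions and TEWL start fresh from the supplied birds
#' tibble.
#'
#' @param grid A [hex_grid()].
#' @param birds A birds tibble from [init_birds()] (its positions and state
#'   are the day's starting state).
#' @param window A per-minute weather window from [morning_window()] with
#'   at least `cfg$steps_per_day` rows.
#' @param cfg A [scenario_config()].
#' @param log_events If `TRUE`, also return a per-step event log.
#' @return A list with `birds` (end-of-day tibble), `completion` (tibble
#'   `step`, `pct`: percent of interior birds finished after each step),
#'   `end_pct`, and (with `log_events`) `events`: a tibble of `step`, `id`,
#'   `behavior` (the behavior the bird chose), `sang` (whether a song was
#'   actually produced — an induced bird sings regardless of its chosen
#'   behavior, while a bird that finished mid-step may not realise its
#'   chosen song) and `penalized` (the bird's song reached no neighbor, so
#'   its next step is move-or-rest).
#' @examples
#' set.seed(1)
#' g <- hex_grid(3, 3, 500)
#' w <- synthetic_weather(days = 1, seed = 1)
#' day <- run_day(g, init_birds(g), morning_window(w, 1),
#'                scenario_config(freq = 4000, rows = 3, cols = 3,
#'                                diameter = 500))
#' day$end_pct
#' @export
run_day <- function(grid, birds, window, cfg = scenario_config(),
                    log_events = FALSE) {
  stopifnot(inherits(grid, "hex_grid"), inherits(cfg, "scenario_config"))
  steps <- cfg$steps_per_day
  if (nrow(window) < steps) {
    abort(sprintf("weather window has %d steps; %d required.",
                  nrow(window), steps),
          class = "songscape_data_error")
  }
  n <- nrow(grid$territories)
  contact <- matrix(FALSE, n, n)
  for (i in seq_len(n)) contact[i, birds$contacts[[i]]] <- TRUE
  init <- list(x = birds$x, y = birds$y, tewl = birds$tewl,
               penalty = birds$penalty, finished = birds$finished,
               incapacitated = birds$incapacitated, contact = contact)
  rps <- radius_schedule(window[seq_len(steps), ], cfg$song, cfg$settings)
  res <- run_day_core(grid, rps, window$tair[seq_len(steps)], cfg$ewl,
                      steps = steps, init = init, log_events = log_events)
  out <- birds
  out$x <- res$x
  out$y <- res$y
  out$tewl <- res$tewl
  out$penalty <- res$penalty
  out$finished <- res$finished
  out$incapacitated <- res$incapacitated
  out$contacts <- purrr::map(seq_len(n), ~ which(res$contact[.x, ]))
  p <- behavior_probs(out$penalty, out$finished, out$incapacitated, out$tewl,
                      cfg$ewl)
  out$p_sing <- p$p_sing
  out$p_move <- p$p_move
  out$p_rest <- p$p_rest
  ret <- list(birds = out,
              completion = tibble::tibble(step = seq_len(steps),
                                          pct = res$completion * 100),
              end_pct = res$completion[steps] * 100)
  if (log_events) {
    ret$events <- tibble::tibble(
      step = rep(seq_len(steps), each = n),
      id = rep(seq_len(n), times = steps),
      behavior = c("sing", "move", "rest")[t(res$events$behavior)],
      sang = as.vector(t(res$events$sang)),
      penalized = as.vector(t(res$events$penalty))
    )
  }
  ret
}

#' Run a population completion-percentage scenario
#'
#' The main experiment: simulates `iterations` independent replicates of
#' `days` mornings for a full territory grid and reports what percentage of
#' interior birds (those with six neighbors) contacted all of their
#' neighbors. All per-day state resets between days. The headline quantity
#' is the end-of-day completion percentage averaged over days, with mean
#' and standard error across iterations.
#'
#' @param weather A weather series tibble (e.g. from [synthetic_weather()],
#'   [read_weather_csv()], optionally piped through
#'   [apply_climate_delta()]).
#' @param cfg A [scenario_config()].
#' @return An object of class `completion_summary`: list with `summary`
#'   (tibble: `mean_pct`, `se`, `n`), `by_iteration`, `daily` (tibble:
#'   `iteration`, `day`, `pct`), `curve` (tibble: `step`, `mean_pct`,
#'   per-step mean over days and iterations) and `config`. Explore with
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' w <- synthetic_weather(days = 2, seed = 42)
#' run_scenario(w, scenario_config(freq = 4000, iterations = 2, seed = 42))
#' @export
run_scenario <- function(weather, cfg = scenario_config()) {
  stopifnot(is.data.frame(weather), inherits(cfg, "scenario_config"))
  days_avail <- sort(unique(weather$day))
  n_days <- cfg$days %||% length(days_avail)
  if (length(days_avail) < n_days) {
    abort(sprintf("weather series has %d days; %d requested.",
                  length(days_avail), n_days),
          class = "songscape_data_error")
  }
  steps <- cfg$steps_per_day
  grid <- hex_grid(cfg$rows, cfg$cols, cfg$diameter)

  # radii depend only on weather: precompute once per day
  windows <- purrr::map(seq_len(n_days),
                        ~ morning_window(weather, .x, steps = steps))
  radii <- purrr::map(windows, ~ radius_schedule(.x, cfg$song, cfg$settings))

  set.seed(cfg$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1, cfg$iterations)

  daily <- vector("list", cfg$iterations)
  curve_sum <- numeric(steps)
  for (it in seq_len(cfg$iterations)) {
    set.seed(iter_seeds[it])
    end_pct <- numeric(n_days)
    for (dd in seq_len(n_days)) {
      res <- run_day_core(grid, radii[[dd]], windows[[dd]]$tair, cfg$ewl,
                          steps = steps)
      end_pct[dd] <- res$completion[steps] * 100
      curve_sum <- curve_sum + res$completion * 100
    }
    daily[[it]] <- tibble::tibble(iteration = it, day = seq_len(n_days),
                                  pct = end_pct)
  }
  daily <- dplyr::bind_rows(daily)
  by_iteration <- daily |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(mean_pct = mean(.data$pct), .groups = "drop")
  summ <- summarize_iterations(by_iteration$mean_pct)
  structure(
    list(summary = tibble::tibble(mean_pct = summ$mean, se = summ$se,
                                  n = summ$n),
         by_iteration = by_iteration,
         daily = daily,
         curve = tibble::tibble(step = seq_len(steps),
                                mean_pct = curve_sum /
                                  (cfg$iterations * n_days)),
         config = cfg),
    class = "completion_summary"
  )
}

#' Two-bird frequency-by-territory-size sweep
#'
#' The simplified two-bird experiment: a pair of birds on adjacent
#' hexagonal territories, run for one day's weather over a grid of song
#' frequencies and territory radii (half the flat-to-flat diameter). Each
#' cell reports the percentage of that day's song attempts that reached
#' the other bird, averaged over both birds and over iterations. The birds
#' run the standard state machine without the finished rule, so the
#' percentage stays a continuous measure of contact success.
#'
#' @param weather A weather series tibble.
#' @param day Which day of the series to use (index or Date).
#' @param freqs Song frequencies, Hz.
#' @param radii Territory radii, m.
#' @param iterations Replicates per cell.
#' @param seed Master seed (per-cell streams derived from it).
#' @param cfg A [scenario_config()] supplying song level, propagation
#'   settings, step count and the EWL model (disabled by default, as in the
#'   two-bird design).
#' @param label Scenario label carried into results.
#' @return An object of class `sweep_result`: list with `grid` (tibble:
#'   `freq`, `radius`, `contact_pct`), `label`, `iterations`.
#' @examples
#' w <- synthetic_weather(days = 1, seed = 3)
#' run_pairwise_sweep(w, freqs = c(2000, 8000), radii = c(100, 400),
#'                    iterations = 2, seed = 3)
#' @export
run_pairwise_sweep <- function(weather, day = 1,
                               freqs = 1000 * (1:12),
                               radii = seq(25, 1500, by = 25),
                               iterations = 5, seed = 1,
                               cfg = scenario_config(),
                               label = "scenario") {
  stopifnot(is.data.frame(weather))
  steps <- cfg$steps_per_day
  window <- morning_window(weather, day, steps = steps)
  set.seed(seed)
  cell_seeds <- matrix(
    sample.int(.Machine$integer.max - 1,
               length(freqs) * length(radii) * iterations),
    nrow = iterations)

  cells <- tidyr::crossing(freq = freqs, radius = radii)
  pct <- numeric(nrow(cells))
  for (fi in seq_along(freqs)) {
    song <- song_spec(freqs[fi], cfg$song$source_level,
                      cfg$song$ref_distance)
    rps <- radius_schedule(window, song, cfg$settings)
    for (ri in seq_along(radii)) {
      cell <- (fi - 1) * length(radii) + ri
      vals <- numeric(iterations)
      for (it in seq_len(iterations)) {
        set.seed(cell_seeds[it, cell])
        vals[it] <- sim_pair_day(2 * radii[ri], rps, window$tair, cfg$ewl,
                                 steps = steps)
      }
      pct[cell] <- mean(vals)
    }
  }
  cells$contact_pct <- pct
  structure(list(grid = cells, label = label, iterations = iterations),
            class = "sweep_result")
}

#' Difference between two sweep results
#'
#' Cell-wise difference `a - b` between two sweeps on the same
#' frequency-by-radius grid; used to map which frequencies and territory
#' sizes lose the most contact under harsher weather.
#'
#' @param a,b [run_pairwise_sweep()] results with identical axes.
#' @return An object of class `sweep_diff` with `grid` (tibble: `freq`,
#'   `radius`, `diff_pct`) and `label`.
#' @export
diff_grid <- function(a, b) {
  stopifnot(inherits(a, "sweep_result"), inherits(b, "sweep_result"))
  if (!identical(dim(a$grid), dim(b$grid)) ||
      !identical(a$grid$freq, b$grid$freq) ||
      !identical(a$grid$radius, b$grid$radius)) {
    abort("sweep grids have mismatched dimensions or axes.",
          class = "songscape_invalid_input")
  }
  grid <- a$grid |>
    dplyr::mutate(diff_pct = .data$contact_pct - b$grid$contact_pct) |>
    dplyr::select("freq", "radius", "diff_pct")
  structure(list(grid = grid, label = paste(a$label, "-", b$label)),
            class = "sweep_diff")
}

#' Mean and standard error over iterations
#'
#' @param values Numeric vector of per-iteration outcomes (length >= 1).
#' @return A list with `mean`, `se` (sample SD / sqrt(n); 0 for a single
#'   or constant input) and `n`.
#' @examples
#' summarize_iterations(c(0, 100))  # mean 50, se 50
#' @export
summarize_iterations <- function(values) {
  n <- length(values)
  if (n == 0) {
    abort("`values` must have length >= 1.", class = "songscape_invalid_input")
  }
  se <- if (n == 1) 0 else sd(values) / sqrt(n)
  list(mean = mean(values), se = se, n = n)
}
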