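#' Read a Mesonet-style weather table
#'
#' Reads a CSV with (case-insensitive) columns `TAIR` (degrees C), `RELH`
#' (%), `PRES`, and a timestamp column (`TIME`, `TIMESTAMP` or `DATETIME`).
#' Sentinel missing values (any reading at or below -900, the Mesonet
#' convention) are dropped and gap-filled by carrying the previous record
#' forward. Pressure may be recorded in Pa, hPa, or atm; with
#' `pres_unit = "auto"` the unit is inferred from the magnitude of the
#' median value.
#'
#' @param path Path to a CSV file.
#' @param pres_unit One of `"auto"`, `"pa"`, `"hpa"`, `"atm"`.
#' @return A weather series tibble with columns `timestamp` (POSIXct, UTC),
#'   `day` (Date), `tair`, `relh`, `pres` (Pa), ordered by timestamp.
#' @export
read_weather_csv <- function(path, pres_unit = c("auto", "pa", "hpa", "atm")) {
  pres_unit <- match.arg(pres_unit)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(raw))
  names(raw) <- nm
  for (col in c("tair", "relh", "pres")) {
    if (!col %in% nm) {
      abort(paste0("weather file lacks required column `", toupper(col), "`."),
            class = "songscape_format_error")
    }
  }
  ts_col <- intersect(c("timestamp", "time", "datetime"), nm)[1]
  if (is.na(ts_col)) {
    abort("weather file lacks a timestamp column (TIME/TIMESTAMP/DATETIME).",
          class = "songscape_format_error")
  }
  ts <- raw[[ts_col]]
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(as.character(ts), tz = "UTC")
  }
  out <- tibble::tibble(
    timestamp = ts,
    tair = as.numeric(raw$tair),
    relh = as.numeric(raw$relh),
    pres = as.numeric(raw$pres)
  ) |>
    dplyr::arrange(.data$timestamp) |>
    dplyr::mutate(dplyr::across(c("tair", "relh", "pres"),
                                ~ dplyr::if_else(.x <= -900, NA_real_, .x))) |>
    tidyr::fill("tair", "relh", "pres", .direction = "down") |>
    dplyr::filter(!is.na(.data$tair), !is.na(.data$relh), !is.na(.data$pres))
  if (nrow(out) == 0) {
    abort("no usable weather records after cleaning.",
          class = "songscape_data_error")
  }
  med <- stats::median(out$pres)
  unit <- if (pres_unit != "auto") pres_unit
          else if (med < 2) "atm" else if (med < 2000) "hpa" else "pa"
  out$pres <- switch(unit,
                     pa = out$pres,
                     hpa = out$pres * 100,
                     atm = out$pres * 1.01325e5)
  out$day <- as.Date(out$timestamp, tz = "UTC")
  check_weather_fields(out$tair, out$relh, out$pres)
  dplyr::relocate(out, "timestamp", "day")
}

#' Write a weather series as CSV
#'
#' Inverse of [read_weather_csv()]: writes `TIME`, `TAIR`, `RELH`, `PRES`
#' (Pa) columns.
#'
#' @param weather A weather series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  out <- tibble::tibble(
    TIME = format(weather$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    TAIR = weather$tair, RELH = weather$relh, PRES = weather$pres
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Climate-change weather transform
#'
#' Scenario delta applied uniformly to a weather series. The projected-2070
#' aridification scenario for the south-central semi-arid prairies adds
#' 7.5 degrees C to air temperature and subtracts 6 percentage points of
#' relative humidity.
#'
#' @param d_tair Temperature shift, degrees C.
#' @param d_relh Relative humidity shift, percentage points.
#' @return An object of class `climate_delta`.
#' @examples
#' climate_delta()  # the 2070 projection: +7.5 C, -6 %
#' @export
climate_delta <- function(d_tair = 7.5, d_relh = -6) {
  structure(list(d_tair = d_tair, d_relh = d_relh), class = "climate_delta")
}

#' Apply a climate delta to a weather series
#'
#' Shifts temperature and relative humidity by the scenario delta; humidity
#' is clamped to `[0, 100]` and pressure and timestamps are untouched.
#'
#' @param weather A weather series tibble (columns `tair`, `relh`, ...).
#' @param delta A [climate_delta()].
#' @return The transformed weather series tibble.
#' @examples
#' w <- synthetic_weather(days = 1, seed = 1)
#' summary(apply_climate_delta(w)$tair - w$tair)  # +7.5 everywhere
#' @export
apply_climate_delta <- function(weather, delta = climate_delta()) {
  stopifnot(is.data.frame(weather), inherits(delta, "climate_delta"))
  weather |>
    dplyr::mutate(
      tair = .data$tair + delta$d_tair,
      relh = pmin(100, pmax(0, .data$relh + delta$d_relh))
    )
}

#' Per-minute morning window for one day
#'
#' Extracts one day's morning singing window from a 5-minute weather series
#' and disaggregates it to the model's 1-minute time steps by holding each
#' 5-minute record constant for five consecutive steps. The window starts
#' at the day's first record (series are assumed pre-restricted to the
#' sunrise to sunrise + 6 h singing period) and spans
#' `steps` minutes, so it needs `steps / 5` records.
#'
#' @param weather A weather series tibble with a `day` column.
#' @param day Which day: a `Date`, or an integer index into the series'
#'   ordered distinct days.
#' @param steps Number of 1-minute model steps (default 360 = 6 h).
#' @return A tibble with columns `step` (1..steps), `tair`, `relh`, `pres`.
#' @examples
#' w <- synthetic_weather(days = 2, seed = 1)
#' nrow(morning_window(w, day = 1))  # 360
#' @export
morning_window <- function(weather, day, steps = 360) {
  stopifnot(is.data.frame(weather))
  days <- sort(unique(weather$day))
  the_day <- if (inherits(day, "Date")) day else days[day]
  recs <- weather |>
    dplyr::filter(.data$day == the_day) |>
    dplyr::arrange(.data$timestamp)
  need <- ceiling(steps / 5)
  if (nrow(recs) < need) {
    abort(sprintf(
      "day %s has only %d five-minute records (%d min); %d needed for %d steps.",
      format(the_day), nrow(recs), nrow(recs) * 5, need, steps),
      class = "songscape_data_error")
  }
  recs <- recs[seq_len(need), ]
  idx <- rep(seq_len(need), each = 5)[seq_len(steps)]
  tibble::tibble(
    step = seq_len(steps),
    tair = recs$tair[idx],
    relh = recs$relh[idx],
    pres = recs$pres[idx]
  )
}

#' Synthetic morning weather series
#'
#' Generates a weather series emulating the shape of warm-season morning
#' (sunrise to sunrise + 6 h) station records at 5-minute cadence: air
#' temperature ramps up linearly, relative humidity falls linearly, and
#' pressure is constant, each with optional Gaussian noise. Two built-in
#' profiles bracket the study region's conditions: `"contemporary"`
#' (18 to 29 degrees C, 85 to 45 % RH) and `"drought"` (24 to 36 degrees C,
#' 55 to 20 % RH), both at 96.5 kPa. These are fixtures emulating typical
#' morning profiles, not the deposited station data.
#'
#' @param days Number of days to generate.
#' @param profile `"contemporary"` or `"drought"`; sets the default ramps.
#' @param tair_start,tair_end Temperature ramp endpoints, degrees C.
#' @param relh_start,relh_end Relative humidity ramp endpoints, %.
#' @param pres Constant station pressure, Pa.
#' @param noise_sd Named numeric: per-record Gaussian noise SD for `tair`
#'   (degrees C), `relh` (%), `pres` (Pa). Use zeros for exact ramps.
#' @param seed Optional integer seed (local to this call).
#' @param start First day's window start, POSIXct or string (UTC).
#' @return A weather series tibble (`timestamp`, `day`, `tair`, `relh`,
#'   `pres`), 72 records per day.
#' @examples
#' synthetic_weather(days = 1, profile = "drought", seed = 7)
#' @export
synthetic_weather <- function(days = 1,
                              profile = c("contemporary", "drought"),
                              tair_start = NULL, tair_end = NULL,
                              relh_start = NULL, relh_end = NULL,
                              pres = 96500,
                              noise_sd = c(tair = 0.5, relh = 2, pres = 50),
                              seed = NULL,
                              start = "2011-05-01 06:30:00") {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    contemporary = list(tair = c(18, 29), relh = c(85, 45)),
    drought      = list(tair = c(24, 36), relh = c(55, 20))
  )
  tair_start <- tair_start %||% defaults$tair[1]
  tair_end   <- tair_end   %||% defaults$tair[2]
  relh_start <- relh_start %||% defaults$relh[1]
  relh_end   <- relh_end   %||% defaults$relh[2]
  noise_sd <- noise_sd[c("tair", "relh", "pres")]
  noise_sd[is.na(noise_sd)] <- 0
  if (any(noise_sd < 0)) {
    abort("`noise_sd` must be non-negative.", class = "songscape_invalid_input")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  start <- as.POSIXct(start, tz = "UTC")
  n_rec <- 72L                       # 6 h at 5-min cadence
  frac <- (seq_len(n_rec) - 1) / (n_rec - 1)
  purrr::map_dfr(seq_len(days), function(d) {
    tibble::tibble(
      timestamp = start + (d - 1) * 86400 + (seq_len(n_rec) - 1) * 300,
      tair = tair_start + frac * (tair_end - tair_start) +
        rnorm(n_rec, 0, noise_sd[["tair"]]),
      relh = pmin(100, pmax(0, relh_start + frac * (relh_end - relh_start) +
        rnorm(n_rec, 0, noise_sd[["relh"]]))),
      pres = pres + rnorm(n_rec, 0, noise_sd[["pres"]])
    )
  }) |>
    dplyr::mutate(day = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::relocate("timestamp", "day")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
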