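#' Song specification
#'
#' Describes an emitted song as a single carrier frequency with a source
#' level referenced to a fixed distance. The default 90 dB at 1 m is a
#' calibration choice (see the methods vignette): against the 30 dB
#' detection threshold it leaves a 60 dB attenuation budget, which under
#' mild morning air yields a 4 kHz audible radius that spans adjacent
#' 1-km territories.
#'
#' @param freq Carrier frequency, Hz (> 0).
#' @param source_level Emitted sound pressure level, dB at `ref_distance`.
#' @param ref_distance Reference distance for `source_level`, m.
#' @return An object of class `song_spec`.
#' @examples
#' song_spec(8000)
#' @export
song_spec <- function(freq, source_level = 90, ref_distance = 1) {
  if (!is.numeric(freq) || length(freq) != 1 || !is.finite(freq) || freq <= 0) {
    abort("`freq` must be a single positive number (Hz).",
          class = "songscape_invalid_input")
  }
  if (ref_distance <= 0) {
    abort("`ref_distance` must be positive.", class = "songscape_invalid_input")
  }
  structure(
    list(freq = freq, source_level = source_level, ref_distance = ref_distance),
    class = "song_spec"
  )
}

#' @export
print.song_spec <- function(x, ...) {
  cat(sprintf("<song_spec> %.0f Hz, %.1f dB at %.1f m\n",
              x$freq, x$source_level, x$ref_distance))
  invisible(x)
}

#' Propagation settings
#'
#' Controls how a song decays with distance and when it stops being
#' audible. `absorption_only` (the default) attenuates purely by the
#' atmospheric absorption coefficient; `spreading_plus_absorption` adds
#' spherical spreading (20 log10 r). The threshold defaults to 30 dB,
#' the assumed ambient noise floor below which a song cannot be detected.
#'
#' @param threshold Audibility floor, dB.
#' @param mode One of `"absorption_only"` or `"spreading_plus_absorption"`.
#' @param max_radius Solver bracket ceiling, m; the audible radius is capped
#'   here. Must be at least the arena diagonal of any grid it is used with.
#' @return An object of class `propagation_settings`.
#' @examples
#' propagation_settings(threshold = 30)
#' @export
propagation_settings <- function(threshold = 30,
                                 mode = c("absorption_only",
                                          "spreading_plus_absorption"),
                                 max_radius = 5e4) {
  mode <- match.arg(mode)
  if (!is.finite(threshold)) {
    abort("`threshold` must be finite (dB).", class = "songscape_invalid_input")
  }
  if (max_radius <= 0) {
    abort("`max_radius` must be positive.", class = "songscape_invalid_input")
  }
  structure(list(threshold = threshold, mode = mode, max_radius = max_radius),
            class = "propagation_settings")
}

#' Received sound level at distance
#'
#' Level of a song heard `r` meters from the singer given an atmospheric
#' attenuation coefficient. In `spreading_plus_absorption` mode
#' `L(r) = SL - 20 log10(r / r_ref) - alpha (r - r_ref)`; in
#' `absorption_only` mode the spreading term is dropped.
#'
#' @param song A [song_spec()].
#' @param r Distance from the singer, m (vectorised, `>= ref_distance`).
#' @param alpha Attenuation coefficient, dB/m.
#' @param settings A [propagation_settings()].
#' @return Numeric vector of received levels, dB.
#' @examples
#' received_level(song_spec(4000), r = 500, alpha = 0.023,
#'                propagation_settings())
#' @export
received_level <- function(song, r, alpha, settings = propagation_settings()) {
  stopifnot(inherits(song, "song_spec"), inherits(settings, "propagation_settings"))
  if (any(r < song$ref_distance)) {
    abort("`r` must be at least the song's reference distance.",
          class = "songscape_invalid_input")
  }
  level <- song$source_level - alpha * (r - song$ref_distance)
  if (settings$mode == "spreading_plus_absorption") {
    level <- level - 20 * log10(r / song$ref_distance)
  }
  level
}

# scalar bisection solve of received_level(r) = threshold; alpha >= 0
solve_radius <- function(song, alpha, settings, tol = 0.01) {
  if (alpha == 0 && settings$mode == "absorption_only") {
    return(settings$max_radius)
  }
  lo <- song$ref_distance
  hi <- settings$max_radius
  f <- function(r) received_level(song, r, alpha, settings) - settings$threshold
  if (f(lo) <= 0) return(0)
  if (f(hi) > 0) return(settings$max_radius)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Audible radius of a song
#'
#' Distance at which the received level of a song falls to the detection
#' threshold, i.e. the radius of the song's active space under the given
#' weather. The monotone level-distance curve is solved by bisection to
#' 0.01 m; if the song is still above threshold at `max_radius` the radius
#' is capped there, and if it is already below threshold at the reference
#' distance the radius is 0 (the song is inaudible anywhere).
#'
#' @param song A [song_spec()].
#' @param weather A data frame with columns `tair`, `relh`, `pres` (one
#'   radius is returned per row), or `NULL` if `alpha` is given directly.
#' @param settings A [propagation_settings()].
#' @param alpha Optional: attenuation coefficient(s) in dB/m, bypassing the
#'   weather-based computation.
#' @return Numeric vector of radii, m.
#' @examples
#' w <- tibble::tibble(tair = 20, relh = 70, pres = 101325)
#' audible_radius(song_spec(4000), w)
#' @export
audible_radius <- function(song, weather = NULL,
                           settings = propagation_settings(), alpha = NULL) {
  stopifnot(inherits(song, "song_spec"), inherits(settings, "propagation_settings"))
  if (is.null(alpha)) {
    stopifnot(is.data.frame(weather))
    alpha <- attenuation_coefficient(song$freq, weather$tair, weather$relh,
                                     weather$pres)
  }
  if (any(!is.finite(alpha)) || any(alpha < 0)) {
    abort("`alpha` must be finite and non-negative (non-monotone level curve).",
          class = "songscape_invalid_input")
  }
  vapply(alpha, function(a) solve_radius(song, a, settings), numeric(1))
}
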