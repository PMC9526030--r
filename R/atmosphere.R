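#' Physical constants for humid-air sound absorption
#'
#' Reference values used throughout the atmospheric absorption model:
#' the 20 degree C reference temperature `t0` (293.15 K), the triple-point
#' temperature `t01` (273.16 K) that enters the saturation vapor pressure
#' exponent, the reference pressure `p0` (one standard atmosphere, Pa), and
#' the neper-to-decibel conversion factor `np_to_db` (20 / ln 10).
#'
#' @return A named list with elements `t0`, `t01`, `p0`, `np_to_db` (all
#'   numeric scalars).
#' @examples
#' acoustic_constants()$np_to_db  # 8.6858896...
#' @export
acoustic_constants <- function() {
  list(
    t0       = 293.15,
    t01      = 273.16,
    p0       = 1.01325e5,
    np_to_db = 20 / log(10)
  )
}

# range checks shared by the absorption functions; names the offending field
check_weather_fields <- function(tair, relh, pres) {
  if (any(!is.finite(tair)) || any(tair < -50) || any(tair > 60)) {
    abort("`tair` must be finite and within [-50, 60] degrees C.",
          class = "songscape_invalid_input")
  }
  if (any(!is.finite(relh)) || any(relh < 0) || any(relh > 100)) {
    abort("`relh` must be finite and within [0, 100] %.",
          class = "songscape_invalid_input")
  }
  if (any(!is.finite(pres)) || any(pres < 3e4) || any(pres > 1.2e5)) {
    abort("`pres` must be finite and within [3e4, 1.2e5] Pa.",
          class = "songscape_invalid_input")
  }
  invisible(TRUE)
}

#' Percentage molar concentration of water vapor
#'
#' Converts relative humidity into the percentage molar concentration of
#' water vapor H used by the relaxation-frequency formulas. The saturation
#' vapor pressure ratio is `10^C_sat` with
#' `C_sat = -6.8346 * (T01/T)^1.261 + 4.6151`, where `T01` is the
#' triple-point temperature (273.16 K), so that
#' `H = relh * 10^C_sat * p0 / pres`.
#'
#' @param tair Air temperature, degrees C (vectorised).
#' @param relh Relative humidity, % in `[0, 100]`.
#' @param pres Station pressure, Pa.
#' @return Numeric vector of molar water vapor concentrations, %.
#' @examples
#' molar_water_vapor(20, 70, 101325)
#' @export
molar_water_vapor <- function(tair, relh, pres) {
  check_weather_fields(tair, relh, pres)
  k <- acoustic_constants()
  t_kelvin <- tair + 273.15
  c_sat <- -6.8346 * (k$t01 / t_kelvin)^1.261 + 4.6151
  relh * 10^c_sat * k$p0 / pres
}

#' Nitrogen and oxygen relaxation frequencies
#'
#' Vibrational relaxation frequencies of N2 and O2 in humid air. Both grow
#' with the molar water vapor concentration `h_molar` and scale linearly
#' with pressure:
#' \deqn{f_{r,N} = (p_s/p_0) (T_0/T)^{1/2} (9 + 280 H e^{-4.17((T_0/T)^{1/3} - 1)})}
#' \deqn{f_{r,O} = (p_s/p_0) (24 + 4.04 \times 10^4 H (0.02 + H)/(0.391 + H))}
#'
#' @param h_molar Percentage molar concentration of water vapor (from
#'   [molar_water_vapor()]).
#' @param tair Air temperature, degrees C.
#' @param pres Station pressure, Pa.
#' @return A tibble with columns `fr_n` and `fr_o` (Hz), one row per input.
#' @examples
#' relaxation_frequencies(0, 20, 101325)  # collapses to 9 and 24 Hz
#' @export
relaxation_frequencies <- function(h_molar, tair, pres) {
  if (any(!is.finite(h_molar)) || any(h_molar < 0)) {
    abort("`h_molar` must be finite and non-negative.",
          class = "songscape_invalid_input")
  }
  k <- acoustic_constants()
  t_kelvin <- tair + 273.15
  t_ratio <- k$t0 / t_kelvin
  p_ratio <- pres / k$p0
  fr_n <- p_ratio * sqrt(t_ratio) *
    (9 + 280 * h_molar * exp(-4.17 * (t_ratio^(1 / 3) - 1)))
  fr_o <- p_ratio *
    (24.0 + 4.04e4 * h_molar * (0.02 + h_molar) / (0.391 + h_molar))
  tibble::tibble(fr_n = fr_n, fr_o = fr_o)
}

#' Atmospheric sound attenuation coefficient
#'
#' Humid-air absorption coefficient in dB per meter for a pure tone,
#' combining the classical (viscous/thermal) term with the nitrogen and
#' oxygen vibrational relaxation terms, in the standard ISO 9613-1 style
#' formulation. The coefficient is evaluated in Np/m,
#' \deqn{\alpha_{Np/m} = f^2 \Big[ 1.84\times10^{-11}
#'   \frac{p_0}{p_s}\Big(\frac{T}{T_0}\Big)^{1/2}
#'   + \Big(\frac{T}{T_0}\Big)^{-5/2}\Big(
#'     0.10680\, e^{-3352/T} \frac{f_{r,N}}{f_{r,N}^2 + f^2}
#'   + 0.01278\, e^{-2239.1/T} \frac{f_{r,O}}{f_{r,O}^2 + f^2}\Big)\Big]}
#' and converted to dB/m with the factor 20 / ln 10, so that downstream
#' audibility arithmetic stays in decibels.
#'
#' Attenuation increases steeply with frequency and, in the warm season, is
#' higher in hot dry air than in cool humid air — the mechanism by which
#' drought shrinks birdsong active space.
#'
#' @param freq Sound frequency, Hz (vectorised; recycled against weather).
#' @param tair,relh,pres Weather: air temperature (degrees C), relative
#'   humidity (%), station pressure (Pa).
#' @return Numeric vector of attenuation coefficients, dB/m.
#' @examples
#' attenuation_coefficient(4000, tair = 20, relh = 70, pres = 101325)
#' @export
attenuation_coefficient <- function(freq, tair, relh, pres) {
  if (any(!is.finite(freq)) || any(freq < 0)) {
    abort("`freq` must be finite and non-negative (Hz).",
          class = "songscape_invalid_input")
  }
  k <- acoustic_constants()
  h <- molar_water_vapor(tair, relh, pres)
  fr <- relaxation_frequencies(h, tair, pres)
  t_kelvin <- tair + 273.15
  tt <- t_kelvin / k$t0
  classical <- 1.84e-11 * (k$p0 / pres) * sqrt(tt)
  relaxation <- tt^(-2.5) * (
    0.10680 * exp(-3352.0 / t_kelvin) * fr$fr_n / (fr$fr_n^2 + freq^2) +
    0.01278 * exp(-2239.1 / t_kelvin) * fr$fr_o / (fr$fr_o^2 + freq^2)
  )
  k$np_to_db * freq^2 * (classical + relaxation)
}

#' Add attenuation coefficients to a weather table
#'
#' Data-frame-first wrapper around [attenuation_coefficient()]: takes any
#' table with `tair`, `relh` and `pres` columns and appends one attenuation
#' column per requested frequency.
#'
#' @param weather A data frame with columns `tair` (degrees C), `relh` (%),
#'   `pres` (Pa).
#' @param freq Numeric vector of frequencies, Hz.
#' @return The input as a tibble with added columns `freq` and `alpha_db_m`
#'   (long format: one row per weather record per frequency).
#' @examples
#' w <- tibble::tibble(tair = c(20, 35), relh = c(70, 20), pres = 101325)
#' attenuate(w, freq = c(4000, 8000))
#' @export
attenuate <- function(weather, freq) {
  stopifnot(is.data.frame(weather))
  missing_cols <- setdiff(c("tair", "relh", "pres"), names(weather))
  if (length(missing_cols)) {
    abort(paste0("`weather` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "songscape_format_error")
  }
  tidyr::crossing(tibble::as_tibble(weather), freq = freq) |>
    dplyr::mutate(alpha_db_m = attenuation_coefficient(
      .data$freq, .data$tair, .data$relh, .data$pres))
}
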