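# Independent oracles, written without reference to the package internals.

# Scalar humid-air absorption routine (standard ISO-9613-1-style form,
# triple point 273.16 K in the saturation exponent), coded step by step.
oracle_absorption_db_m <- function(freq, tair, relh, pres) {
  t_k <- tair + 273.15
  t_ref <- 293.15
  t_tri <- 273.16
  p_ref <- 101325
  psat_over_pref <- 10^(4.6151 - 6.8346 * (t_tri / t_k)^1.261)
  h <- relh * psat_over_pref * p_ref / pres
  fr_n <- (pres / p_ref) * sqrt(t_ref / t_k) *
    (9 + 280 * h * exp(-4.17 * ((t_ref / t_k)^(1 / 3) - 1)))
  fr_o <- (pres / p_ref) * (24 + 40400 * h * (0.02 + h) / (0.391 + h))
  classical <- 1.84e-11 * (p_ref / pres) * sqrt(t_k / t_ref)
  nitrogen <- 0.10680 * exp(-3352 / t_k) * fr_n / (fr_n^2 + freq^2)
  oxygen <- 0.01278 * exp(-2239.1 / t_k) * fr_o / (fr_o^2 + freq^2)
  (20 / log(10)) * freq^2 * (classical + (t_ref / t_k)^2.5 * (nitrogen + oxygen))
}

# Brute-force audible radius: dense scan of the received-level curve.
oracle_radius_scan <- function(song, alpha, settings, upper = 5000,
                               step = 0.001) {
  r <- seq(song$ref_distance, upper, by = step)
  level <- song$source_level - alpha * (r - song$ref_distance)
  if (settings$mode == "spreading_plus_absorption") {
    level <- level - 20 * log10(r / song$ref_distance)
  }
  below <- which(level < settings$threshold)
  if (length(below) == 0) return(settings$max_radius)
  r[below[1]]
}

# Brute-force hexagonal adjacency: centers closer than 1.01 * diameter.
oracle_adjacency <- function(grid) {
  xy <- grid$territories
  lapply(seq_len(nrow(xy)), function(i) {
    d <- sqrt((xy$x - xy$x[i])^2 + (xy$y - xy$y[i])^2)
    sort(which(d > 1e-9 & d < 1.01 * grid$diameter))
  })
}

# Shared tiny fixtures.
make_weather <- function(days = 1, seed = 99, profile = "contemporary") {
  synthetic_weather(days = days, profile = profile, seed = seed)
}
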