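#' Evaporative water loss model
#'
#' Mass-specific evaporative water loss (EWL) rate as a function of air
#' temperature, plus the rules that couple cumulative water loss (TEWL) to
#' behavior. The rate is a baseline plus an exponential term above an upper
#' critical temperature:
#' `rate(T) = a * exp(b * max(0, T - t_upper)) + c` in g water per g body
#' mass per minute. Once a bird's TEWL reaches `lethal_fraction` of its
#' body mass it is incapacitated: it no longer sings or moves and only
#' rests for the remainder of the day. Below that bound the singing and
#' moving probabilities shrink with the fraction of the lethal budget
#' already spent; `rule = "multiplicative"` scales them by
#' `1 - tewl/(lethal_fraction * body_mass)` (reaching exactly zero at the
#' bound), while `rule = "subtractive"` subtracts that fraction from each
#' probability, clipped at zero.
#'
#' @param enabled Is the water budget active?
#' @param body_mass Bird body mass, g (default: house finch).
#' @param lethal_fraction Fraction of body mass whose loss incapacitates.
#' @param a,b,t_upper,c Rate parameters: scale (g/g/min), exponent (1/degC),
#'   upper critical temperature (degrees C), baseline (g/g/min).
#' @param rule How TEWL depresses sing/move probabilities.
#' @return An object of class `ewl_model`.
#' @examples
#' ewl_model()
#' ewl_model(enabled = FALSE)
#' @export
ewl_model <- function(enabled = TRUE, body_mass = 21, lethal_fraction = 0.15,
                      a = 5e-5, b = 0.2, t_upper = 30, c = 2e-5,
                      rule = c("multiplicative", "subtractive")) {
  rule <- match.arg(rule)
  if (body_mass <= 0 || lethal_fraction <= 0 || lethal_fraction > 1) {
    abort("`body_mass` must be positive and `lethal_fraction` in (0, 1].",
          class = "songscape_invalid_input")
  }
  if (a < 0 || c < 0) {
    abort("EWL rate parameters `a` and `c` must be non-negative.",
          class = "songscape_invalid_input")
  }
  structure(list(enabled = enabled, body_mass = body_mass,
                 lethal_fraction = lethal_fraction,
                 a = a, b = b, t_upper = t_upper, c = c, rule = rule),
            class = "ewl_model")
}

#' Mass-specific EWL rate at a given air temperature
#'
#' @param tair Air temperature, degrees C (vectorised).
#' @param model An [ewl_model()].
#' @return Numeric vector of rates, g water / g body mass / min.
#' @examples
#' ewl_rate(c(25, 35, 43), ewl_model())
#' @export
ewl_rate <- function(tair, model = ewl_model()) {
  stopifnot(inherits(model, "ewl_model"))
  model$a * exp(model$b * pmax(0, tair - model$t_upper)) + model$c
}

#' Initialise a population of birds on a grid
#'
#' One bird per territory, at a uniform random position in its hexagon,
#' with empty contact sets, zero TEWL, and equal sing/move/rest
#' probabilities (1/3 each). Bird ids coincide with territory ids.
#'
#' @param grid A [hex_grid()].
#' @return A birds tibble with columns `id`, `territory`, `x`, `y`,
#'   `p_sing`, `p_move`, `p_rest`, `tewl`, `penalty`, `finished`,
#'   `incapacitated`, and list-column `contacts` (integer neighbor ids
#'   contacted so far).
#' @examples
#' set.seed(1)
#' init_birds(hex_grid(3, 3, 1000))
#' @export
init_birds <- function(grid) {
  stopifnot(inherits(grid, "hex_grid"))
  n <- nrow(grid$territories)
  pos <- purrr::map_dfr(seq_len(n), ~ random_position(grid, .x))
  tibble::tibble(
    id = seq_len(n),
    territory = seq_len(n),
    x = pos$x, y = pos$y,
    p_sing = 1 / 3, p_move = 1 / 3, p_rest = 1 / 3,
    tewl = 0,
    penalty = FALSE,
    finished = FALSE,
    incapacitated = FALSE,
    contacts = purrr::map(seq_len(n), ~ integer(0))
  )
}

#' Behavior probabilities under penalty and water-budget state
#'
#' Computes each bird's (sing, move, rest) probabilities from its current
#' flags. Base probabilities are uniform (1/3 each). A bird whose last song
#' reached no neighbor is penalised for exactly one step: (0, 0.5, 0.5).
#' Cumulative water loss then depresses sing and move in favour of rest
#' (see [ewl_model()]); finished or incapacitated birds rest with
#' probability 1.
#'
#' @param penalty,finished,incapacitated Logical vectors.
#' @param tewl Cumulative water loss, g.
#' @param model An [ewl_model()].
#' @return A tibble with columns `p_sing`, `p_move`, `p_rest` summing to 1.
#' @examples
#' behavior_probs(penalty = c(FALSE, TRUE), finished = c(FALSE, FALSE),
#'                incapacitated = c(FALSE, FALSE), tewl = c(0, 0))
#' @export
behavior_probs <- function(penalty, finished, incapacitated, tewl,
                           model = ewl_model(enabled = FALSE)) {
  n <- length(penalty)
  p_sing <- ifelse(penalty, 0, 1 / 3)
  p_move <- ifelse(penalty, 0.5, 1 / 3)
  if (model$enabled) {
    budget <- model$lethal_fraction * model$body_mass
    frac <- pmin(1, tewl / budget)
    if (model$rule == "multiplicative") {
      p_sing <- p_sing * (1 - frac)
      p_move <- p_move * (1 - frac)
    } else {
      p_sing <- pmax(0, p_sing - frac)
      p_move <- pmax(0, p_move - frac)
    }
  }
  out <- finished | incapacitated
  p_sing[out] <- 0
  p_move[out] <- 0
  tibble::tibble(p_sing = p_sing, p_move = p_move, p_rest = 1 - p_sing - p_move)
}

#' Sample one behavior per bird
#'
#' Draws each bird's behavior for a time step from its current
#' probabilities (one uniform draw per bird, in id order, so results are
#' reproducible under a fixed seed).
#'
#' @param birds A birds tibble (see [init_birds()]).
#' @param model An [ewl_model()]; used to refresh probabilities from flags.
#' @return Character vector: `"sing"`, `"move"` or `"rest"` per bird.
#' @export
choose_behavior <- function(birds, model = ewl_model(enabled = FALSE)) {
  p <- behavior_probs(birds$penalty, birds$finished, birds$incapacitated,
                      birds$tewl, model)
  u <- runif(nrow(birds))
  dplyr::case_when(
    u < p$p_sing ~ "sing",
    u < p$p_sing + p$p_move ~ "move",
    .default = "rest"
  )
}

#' Advance the water budget by one time step
#'
#' Adds `rate(tair) * body_mass * dt` grams to each bird's cumulative
#' water loss, flags birds that reach the lethal fraction as incapacitated,
#' and refreshes behavior probabilities.
#'
#' @param birds A birds tibble.
#' @param tair Air temperature for the step, degrees C.
#' @param dt Step length, minutes (>= 0).
#' @param model An [ewl_model()] with `enabled = TRUE`.
#' @return The updated birds tibble.
#' @export
ewl_step <- function(birds, tair, dt = 1, model = ewl_model()) {
  stopifnot(inherits(model, "ewl_model"))
  if (dt < 0) {
    abort("`dt` must be non-negative (minutes).",
          class = "songscape_invalid_input")
  }
  if (!model$enabled) return(birds)
  birds$tewl <- birds$tewl + ewl_rate(tair, model) * model$body_mass * dt
  birds$incapacitated <- birds$incapacitated |
    birds$tewl >= model$lethal_fraction * model$body_mass
  p <- behavior_probs(birds$penalty, birds$finished, birds$incapacitated,
                      birds$tewl, model)
  birds$p_sing <- p$p_sing
  birds$p_move <- p$p_move
  birds$p_rest <- p$p_rest
  birds
}

#' One bird's song attempt
#'
#' The singer's song carries to every point within `radius` of its current
#' position. Each neighbor (bird on an adjacent territory) standing inside
#' that radius records a mutual contact with the singer and — unless it is
#' finished or incapacitated — is induced to sing during the same time
#' step. If no neighbor is in range the attempt fails and the singer is
#' penalised for the next step.
#'
#' @param birds A birds tibble.
#' @param grid A [hex_grid()].
#' @param singer_id Id of the singing bird.
#' @param radius Audible radius for this step, m.
#' @return A list: `birds` (updated tibble), `induced` (integer ids queued
#'   to sing this step), `success` (logical).
#' @export
attempt_song <- function(birds, grid, singer_id, radius) {
  stopifnot(inherits(grid, "hex_grid"))
  s <- singer_id
  if (birds$finished[s] || birds$incapacitated[s]) {
    abort("finished or incapacitated birds cannot sing.",
          class = "songscape_invalid_input")
  }
  nb <- grid$adjacency[[birds$territory[s]]]
  d <- sqrt((birds$x[nb] - birds$x[s])^2 + (birds$y[nb] - birds$y[s])^2)
  hit <- nb[d <= radius]
  if (length(hit) == 0) {
    birds$penalty[s] <- TRUE
    return(list(birds = birds, induced = integer(0), success = FALSE))
  }
  birds$contacts[[s]] <- sort(union(birds$contacts[[s]], hit))
  for (t in hit) {
    birds$contacts[[t]] <- sort(union(birds$contacts[[t]], s))
  }
  induced <- hit[!birds$finished[hit] & !birds$incapacitated[hit]]
  list(birds = birds, induced = induced, success = TRUE)
}

#' Update finished flags from contact sets
#'
#' A bird is finished once it has contacted every bird on an adjacent
#' territory; it then rests for the remainder of the day (it can still be
#' contacted by neighbors). Idempotent. Edge birds finish on their smaller
#' neighbor sets but are excluded from population metrics.
#'
#' @param birds A birds tibble.
#' @param grid A [hex_grid()].
#' @return The updated birds tibble.
#' @export
check_completion <- function(birds, grid) {
  stopifnot(inherits(grid, "hex_grid"))
  full <- lengths(grid$adjacency[birds$territory])
  birds$finished <- birds$finished | lengths(birds$contacts) >= full
  birds
}
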