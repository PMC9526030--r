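# Internal fast simulation core. The exported agents functions present the
# same rules on tidy birds tibbles; the core works on plain vectors and a
# logical contact matrix so that full population runs (110 birds x 360
# steps x 61 days x 5 iterations) stay fast in pure R.

# uniform offsets within a flat-to-flat-d hexagon centered at the origin,
# vectorised rejection sampling (acceptance 3/4)
sample_hex_offsets <- function(m, d) {
  r_c <- d / sqrt(3)
  ox <- numeric(m)
  oy <- numeric(m)
  got <- 0L
  while (got < m) {
    k <- max(2L * (m - got), 8L)
    px <- runif(k, -d / 2, d / 2)
    py <- runif(k, -r_c, r_c)
    ok <- abs(py) <= r_c - abs(px) / sqrt(3)
    take <- min(sum(ok), m - got)
    if (take > 0L) {
      idx <- which(ok)[seq_len(take)]
      ox[got + seq_len(take)] <- px[idx]
      oy[got + seq_len(take)] <- py[idx]
      got <- got + take
    }
  }
  cbind(ox, oy)
}

# behavior codes: 1 sing, 2 move, 3 rest
sample_behaviors <- function(p_sing, p_move) {
  u <- runif(length(p_sing))
  ifelse(u < p_sing, 1L, ifelse(u < p_sing + p_move, 2L, 3L))
}

step_probs <- function(penalty, finished, incap, tewl, ewl) {
  p_sing <- ifelse(penalty, 0, 1 / 3)
  p_move <- ifelse(penalty, 0.5, 1 / 3)
  if (ewl$enabled) {
    frac <- pmin(1, tewl / (ewl$lethal_fraction * ewl$body_mass))
    if (ewl$rule == "multiplicative") {
      p_sing <- p_sing * (1 - frac)
      p_move <- p_move * (1 - frac)
    } else {
      p_sing <- pmax(0, p_sing - frac)
      p_move <- pmax(0, p_move - frac)
    }
  }
  out <- finished | incap
  p_sing[out] <- 0
  p_move[out] <- 0
  list(p_sing = p_sing, p_move = p_move)
}

# one morning for a full population; returns per-step completion fraction
# of interior birds plus the final state. Positions, contacts, penalties
# and TEWL all start fresh (daily reset).
run_day_core <- function(grid, radius_per_step, tair_per_step, ewl,
                         steps = 360, init = NULL, log_events = FALSE) {
  n <- nrow(grid$territories)
  adj <- grid$adjacency
  cx <- grid$territories$x
  cy <- grid$territories$y
  d <- grid$diameter
  interior <- grid$territories$interior
  n_int <- sum(interior)
  full <- lengths(adj)
  budget <- ewl$lethal_fraction * ewl$body_mass

  if (is.null(init)) {
    off <- sample_hex_offsets(n, d)
    x <- cx + off[, 1]
    y <- cy + off[, 2]
    tewl <- numeric(n)
    penalty <- logical(n)
    finished <- logical(n)
    incap <- logical(n)
    contact <- matrix(FALSE, n, n)
    ncontact <- integer(n)
  } else {
    x <- init$x; y <- init$y; tewl <- init$tewl; penalty <- init$penalty
    finished <- init$finished; incap <- init$incapacitated
    contact <- init$contact
    ncontact <- as.integer(rowSums(contact))
    finished <- finished | (ncontact >= full)
  }

  comp <- numeric(steps)
  if (log_events) {
    log_beh <- matrix(NA_integer_, steps, n)
    log_sang <- matrix(NA, steps, n)
    log_pen <- matrix(NA, steps, n)
  }
  for (st in seq_len(steps)) {
    radius2 <- radius_per_step[st]^2
    p <- step_probs(penalty, finished, incap, tewl, ewl)
    beh <- sample_behaviors(p$p_sing, p$p_move)
    penalty[] <- FALSE

    movers <- which(beh == 2L)
    if (length(movers)) {
      offm <- sample_hex_offsets(length(movers), d)
      x[movers] <- cx[movers] + offm[, 1]
      y[movers] <- cy[movers] + offm[, 2]
    }

    # same-step induced-singing cascade, FIFO, each bird sings at most once
    queue <- which(beh == 1L)
    sang <- logical(n)
    qi <- 1L
    while (qi <= length(queue)) {
      s <- queue[qi]
      qi <- qi + 1L
      if (sang[s] || finished[s] || incap[s]) next
      sang[s] <- TRUE
      nb <- adj[[s]]
      dx <- x[nb] - x[s]
      dy <- y[nb] - y[s]
      hit <- nb[dx * dx + dy * dy <= radius2]
      if (length(hit)) {
        new_c <- hit[!contact[s, hit]]
        if (length(new_c)) {
          contact[s, new_c] <- TRUE
          contact[new_c, s] <- TRUE
          ncontact[s] <- ncontact[s] + length(new_c)
          ncontact[new_c] <- ncontact[new_c] + 1L
          done <- c(s, new_c)[ncontact[c(s, new_c)] >= full[c(s, new_c)]]
          finished[done] <- TRUE
        }
        induced <- hit[!sang[hit] & !finished[hit] & !incap[hit]]
        if (length(induced)) queue <- c(queue, induced)
      } else {
        penalty[s] <- TRUE
      }
    }

    if (ewl$enabled) {
      tewl <- tewl + ewl_rate(tair_per_step[st], ewl) * ewl$body_mass
      incap <- incap | tewl >= budget
    }
    comp[st] <- sum(finished & interior) / n_int
    if (log_events) {
      log_beh[st, ] <- beh
      log_sang[st, ] <- sang
      log_pen[st, ] <- penalty
    }
  }

  out <- list(completion = comp, x = x, y = y, tewl = tewl, penalty = penalty,
              finished = finished, incapacitated = incap, contact = contact)
  if (log_events) {
    out$events <- list(behavior = log_beh, sang = log_sang, penalty = log_pen)
  }
  out
}

# per-step audible radii for one day's window, memoised over the 5-min
# weather blocks (weather is constant within a block, so is the radius)
radius_schedule <- function(window, song, settings) {
  steps <- nrow(window)
  block_rows <- seq(1, steps, by = 5)
  alpha <- attenuation_coefficient(song$freq, window$tair[block_rows],
                                   window$relh[block_rows],
                                   window$pres[block_rows])
  r_block <- audible_radius(song, settings = settings, alpha = alpha)
  rep(r_block, each = 5)[seq_len(steps)]
}

# one morning for a two-bird pair on adjacent hexagons; returns the
# percentage of song attempts that reached the other bird, averaged over
# the two birds (standard state machine minus the finished rule)
sim_pair_day <- function(d, radius_per_step, tair_per_step, ewl, steps = 360) {
  cx <- c(0, d)
  off <- sample_hex_offsets(2L, d)
  x <- cx + off[, 1]
  y <- off[, 2]
  penalty <- c(FALSE, FALSE)
  tewl <- c(0, 0)
  incap <- c(FALSE, FALSE)
  attempts <- c(0L, 0L)
  successes <- c(0L, 0L)
  budget <- ewl$lethal_fraction * ewl$body_mass
  fin2 <- c(FALSE, FALSE)
  for (st in seq_len(steps)) {
    r2 <- radius_per_step[st]^2
    p <- step_probs(penalty, fin2, incap, tewl, ewl)
    beh <- sample_behaviors(p$p_sing, p$p_move)
    penalty <- c(FALSE, FALSE)
    mv <- beh == 2L
    if (any(mv)) {
      offm <- sample_hex_offsets(sum(mv), d)
      x[mv] <- cx[mv] + offm[, 1]
      y[mv] <- offm[, 2]
    }
    sing <- beh == 1L & !incap
    if (any(sing)) {
      within <- (x[1] - x[2])^2 + (y[1] - y[2])^2 <= r2
      for (s in which(sing)) {
        attempts[s] <- attempts[s] + 1L
        if (within) successes[s] <- successes[s] + 1L else penalty[s] <- TRUE
      }
      if (within) {
        for (t in which(!sing & !incap)) {   # induced song, always in range
          attempts[t] <- attempts[t] + 1L
          successes[t] <- successes[t] + 1L
        }
      }
    }
    if (ewl$enabled) {
      tewl <- tewl + ewl_rate(tair_per_step[st], ewl) * ewl$body_mass
      incap <- incap | tewl >= budget
    }
  }
  frac <- ifelse(attempts > 0L, successes / attempts, NA_real_)
  if (all(is.na(frac))) return(0)
  mean(frac, na.rm = TRUE) * 100
}
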