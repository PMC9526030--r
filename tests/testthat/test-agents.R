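test_that("behavior probabilities cover the base, penalty and terminal states", {
  off <- ewl_model(enabled = FALSE)
  p <- behavior_probs(FALSE, FALSE, FALSE, 0, off)
  expect_equal(unlist(p), c(p_sing = 1 / 3, p_move = 1 / 3, p_rest = 1 / 3))
  p <- behavior_probs(TRUE, FALSE, FALSE, 0, off)
  expect_equal(unlist(p), c(p_sing = 0, p_move = 0.5, p_rest = 0.5))
  for (flags in list(c(TRUE, FALSE), c(FALSE, TRUE))) {
    p <- behavior_probs(FALSE, flags[1], flags[2], 0, off)
    expect_equal(unlist(p), c(p_sing = 0, p_move = 0, p_rest = 1))
  }
  # vectorised and always a proper distribution
  p <- behavior_probs(c(TRUE, FALSE), c(FALSE, FALSE), c(FALSE, TRUE),
                      c(0, 0), off)
  expect_equal(p$p_sing + p$p_move + p$p_rest, c(1, 1), tolerance = 1e-9)
})

test_that("water loss depresses sing and move toward rest", {
  m <- ewl_model(enabled = TRUE, body_mass = 20, lethal_fraction = 0.15)
  budget <- 0.15 * 20
  # half the lethal budget spent: sing/move at half their base values
  p <- behavior_probs(FALSE, FALSE, FALSE, budget / 2, m)
  expect_equal(p$p_sing, (1 / 3) / 2, tolerance = 1e-12)
  expect_equal(p$p_move, (1 / 3) / 2, tolerance = 1e-12)
  expect_equal(p$p_rest, 1 - (1 / 3), tolerance = 1e-12)
  # exactly at the bound: no singing, no moving
  p <- behavior_probs(FALSE, FALSE, FALSE, budget, m)
  expect_identical(p$p_sing, 0)
  expect_identical(p$p_move, 0)
  expect_identical(p$p_rest, 1)
  # the literal subtractive reading: decrement the probabilities directly
  ms <- ewl_model(enabled = TRUE, body_mass = 20, rule = "subtractive")
  p <- behavior_probs(FALSE, FALSE, FALSE, budget / 10, ms)
  expect_equal(p$p_sing, 1 / 3 - 0.1, tolerance = 1e-12)
  expect_equal(p$p_move, 1 / 3 - 0.1, tolerance = 1e-12)
})

test_that("EWL rate is non-negative, nondecreasing in temperature", {
  m <- ewl_model()
  t <- seq(-10, 50, by = 1)
  r <- ewl_rate(t, m)
  expect_true(all(r >= 0))
  expect_true(all(diff(r) >= 0))
  # flat baseline below the upper critical temperature
  expect_equal(ewl_rate(10, m), ewl_rate(25, m))
  expect_gt(ewl_rate(40, m), ewl_rate(30, m))
})

test_that("ewl_step accumulates loss and incapacitates at the lethal bound", {
  g <- hex_grid(3, 3, 500)
  set.seed(2)
  birds <- init_birds(g)
  m <- ewl_model(enabled = TRUE, body_mass = 20)
  expect_identical(ewl_step(birds, 30, dt = 0, m)$tewl, birds$tewl)
  expect_error(ewl_step(birds, 30, dt = -1, m),
               class = "songscape_invalid_input")
  b2 <- ewl_step(birds, 35, dt = 1, m)
  expect_equal(b2$tewl, rep(ewl_rate(35, m) * 20, nrow(birds)))
  # drive a bird over the bound
  b2$tewl[1] <- 0.15 * 20
  b3 <- ewl_step(b2, 35, dt = 0, m)
  expect_true(b3$incapacitated[1])
  expect_identical(b3$p_sing[1], 0)
  expect_identical(b3$p_move[1], 0)
})

test_that("song attempts record mutual contacts and induce in-range neighbors", {
  g <- hex_grid(3, 3, 1000)
  set.seed(5)
  birds <- init_birds(g)
  center <- 5
  # park every bird at its territory center for a deterministic geometry
  birds$x <- g$territories$x
  birds$y <- g$territories$y
  res <- attempt_song(birds, g, center, radius = 1001)
  expect_true(res$success)
  nb <- g$adjacency[[center]]
  expect_setequal(res$birds$contacts[[center]], nb)
  for (j in nb) expect_true(center %in% res$birds$contacts[[j]])
  expect_setequal(res$induced, nb)
  expect_false(res$birds$penalty[center])

  # out of range: failure flips the penalty flag, no contacts
  res0 <- attempt_song(birds, g, center, radius = 0)
  expect_false(res0$success)
  expect_true(res0$birds$penalty[center])
  expect_length(res0$birds$contacts[[center]], 0)

  # finished neighbors still count as contacts but are not induced
  birds2 <- birds
  birds2$finished[nb[1]] <- TRUE
  res2 <- attempt_song(birds2, g, center, radius = 1001)
  expect_true(nb[1] %in% res2$birds$contacts[[center]])
  expect_false(nb[1] %in% res2$induced)
  expect_error(attempt_song(res2$birds |> dplyr::mutate(finished = TRUE),
                            g, center, 100),
               class = "songscape_invalid_input")
})

test_that("completion requires the full neighbor set and is idempotent", {
  g <- hex_grid(3, 3, 1000)
  set.seed(6)
  birds <- init_birds(g)
  nb <- g$adjacency[[5]]
  birds$contacts[[5]] <- nb[-1]          # 5 of 6
  b <- check_completion(birds, g)
  expect_false(b$finished[5])
  b$contacts[[5]] <- nb
  b <- check_completion(b, g)
  expect_true(b$finished[5])
  expect_identical(check_completion(b, g)$finished, b$finished)
  # an edge bird finishes on its smaller neighbor set
  corner <- 1
  b$contacts[[corner]] <- g$adjacency[[corner]]
  b <- check_completion(b, g)
  expect_true(b$finished[corner])
})

test_that("sampled behaviors follow the assigned probabilities", {
  g <- hex_grid(3, 3, 500)
  set.seed(11)
  birds <- init_birds(g)
  n_rep <- 4000
  draws <- replicate(n_rep, choose_behavior(birds)[1])
  freq <- table(factor(draws, levels = c("sing", "move", "rest"))) / n_rep
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / n_rep)))
  birds$penalty[1] <- TRUE
  draws <- replicate(n_rep, choose_behavior(birds)[1])
  expect_false(any(draws == "sing"))
})
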