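test_that("necrosis is strict at the threshold and absorbing", {
  st <- world_state(5, phi = 0.5)
  st$phi[2, 2] <- 0.01
  st$phi[3, 3] <- 0.05
  st$n_prolif[2, 2] <- 2L; st$n_invasive[2, 2] <- 1L
  st$n_prolif[3, 3] <- 2L
  st$n_necrotic[4, 4] <- 3L
  out <- apply_necrosis(st, phi_c = 0.05)
  expect_identical(out$n_prolif[2, 2] + out$n_invasive[2, 2], 0L)
  expect_identical(out$n_necrotic[2, 2], 3L)
  expect_identical(out$n_prolif[3, 3], 2L)    # phi == phi_c survives
  expect_identical(out$n_necrotic[4, 4], 3L)  # necrotic-only grid unchanged
})

test_that("game increments aggregate the payoff matrix over living partners", {
  pay <- payoff_matrix(a_pp = -0.1, a_pi = 0, b_ip = 0, b_ii = 0.1)
  gi0 <- game_increments(0, 0, pay)
  expect_equal(c(gi0$delta_p, gi0$delta_i), c(0, 0))

  gi1 <- game_increments(0, 1, pay)       # one invasive partner
  expect_equal(gi1$delta_i, 0.1)

  gi <- game_increments(3, 1, pay, aggregation = "mean")
  expect_equal(gi$delta_p, -0.075)        # (3 * -0.1 + 0) / 4
  expect_equal(gi$delta_i, 0.025)         # (0 + 0.1) / 4
  gs <- game_increments(3, 1, pay, aggregation = "sum")
  expect_equal(gs$delta_p, -0.3)
  expect_equal(gs$delta_i, 0.1)
  expect_error(game_increments(-1, 0, pay), "non-negative")
})

test_that("fate probabilities follow the nutrient-per-cell closed forms", {
  expect_equal(proliferation_probability(0, 1, theta_p = 0.3), 0)
  expect_equal(invasion_probability(0, 1, theta_i = 0.3), 1)
  # phi equal to the per-cell scale N_T * theta puts the exponent at 1
  expect_equal(proliferation_probability(0.6, 2, theta_p = 0.3), 1 - exp(-1))
  expect_equal(invasion_probability(0.6, 2, theta_i = 0.3), exp(-1))
  # monotonicity
  p <- proliferation_probability(seq(0, 1, 0.1), 1, 0.3)
  expect_true(all(diff(p) >= 0))
  q <- invasion_probability(seq(0, 1, 0.1), 1, 0.3)
  expect_true(all(diff(q) <= 0))
  # clamping
  expect_equal(proliferation_probability(0.9, 1, 0.3, delta_p = 0.5), 1)
  expect_equal(invasion_probability(0.9, 1, 0.3, delta_i = -0.5), 0)
  expect_error(proliferation_probability(0.5, 1, theta_p = 0), "theta_p")
  expect_error(invasion_probability(0.5, 0, theta_i = 0.3), "n_t")
})

test_that("fate draws are binomial with the normalised split, with a hold state", {
  p <- fate_probabilities(0.2, 0.6)
  expect_equal(p$p_prolif + p$p_invade, 1)
  expect_false(p$hold)

  degenerate <- fate_probabilities(0, 0.4)
  set.seed(1)
  expect_identical(draw_fates(degenerate, 7L),
                   c(n_prolif_fated = 0L, n_invade_fated = 7L))

  hold <- fate_probabilities(0, 0)
  expect_true(hold$hold)
  expect_identical(sum(draw_fates(hold, 5L)), 0L)

  set.seed(2)
  half <- fate_probabilities(0.5, 0.5)
  f <- draw_fates(half, 10000L)
  expect_identical(sum(f), 10000L)
  expect_lt(abs(f[["n_prolif_fated"]] / 10000 - 0.5), 4 * sqrt(0.25 / 10000))
})

test_that("site choice is lexicographic: count, then nutrient, then uniform", {
  expect_identical(
    choose_site(data.frame(site = c("a", "b"), count = c(2, 5),
                           phi = c(0.1, 0.9))), "a")
  expect_identical(
    choose_site(data.frame(site = c("a", "b"), count = c(3, 3),
                           phi = c(0.4, 0.7))), "b")
  expect_error(choose_site(data.frame()), "no candidate")

  set.seed(31)
  picks <- replicate(30000, choose_site(
    data.frame(site = 1:3, count = 2, phi = 0.5)))
  freq <- tabulate(picks, 3) / 30000
  expect_true(all(abs(freq - 1 / 3) < 4 * sqrt((1 / 3) * (2 / 3) / 30000)))
})

test_that("offspring placement and invader movement respect ECM and conserve cells", {
  st <- world_state(5, phi = 0.5, rho_ecm = 1)
  st$rho_ecm[3, 3] <- 0
  st$n_prolif[3, 3] <- 2L
  # all neighbours blocked: daughter lands on the current grid
  res <- place_offspring(st, c(3, 3))
  expect_identical(res$target, c(3, 3))
  expect_identical(res$state$n_prolif[3, 3], 3L)

  # one eligible empty neighbour with higher phi than the crowded origin
  st2 <- st
  st2$rho_ecm[2, 3] <- 0
  st2$phi[2, 3] <- 0.9
  res2 <- place_offspring(st2, c(3, 3))
  expect_equal(res2$target, c(2, 3))
  expect_identical(sum(total_counts(res2$state)) -
                     sum(total_counts(st2)), 1L)

  # invader: blocked everywhere -> stays; cell count conserved
  sti <- world_state(5, phi = 0.5, rho_ecm = 1)
  sti$rho_ecm[3, 3] <- 0
  sti$n_invasive[3, 3] <- 1L
  resi <- move_invader(sti, c(3, 3))
  expect_false(resi$moved)
  expect_identical(resi$state$n_invasive[3, 3], 1L)

  sti$rho_ecm[4, 4] <- 0
  resm <- move_invader(sti, c(3, 3))
  expect_true(resm$moved)
  expect_equal(resm$target, c(4, 4))
  expect_identical(sum(total_counts(resm$state)), sum(total_counts(sti)))
  expect_error(move_invader(world_state(3), c(2, 2)), "no invasive")
})

test_that("a lone founder either divides or migrates with the enumerated probabilities", {
  # phi = 1 everywhere, no consumption, cleared ECM, zero payoffs,
  # theta_p = theta_i = 1: normalised division probability is 1 - exp(-1).
  cfg <- tiny_config(L = 9L, k = 0, gamma = 0, theta_p = 1, theta_i = 1,
                     payoff = payoff_matrix())
  base <- world_state(9, phi = 1, rho_ecm = 0)
  base$n_prolif[5, 5] <- 1L
  p_div <- 1 - exp(-1)

  set.seed(123)
  n_rep <- 10000
  divided <- logical(n_rep)
  moved_to <- integer(n_rep)
  for (i in seq_len(n_rep)) {
    nxt <- step_world(base, cfg)
    tot <- sum(living_counts(nxt))
    divided[i] <- tot == 2L
    expect_true(tot %in% c(1L, 2L))
    if (!divided[i]) moved_to[i] <- which(nxt$n_invasive > 0)
  }
  expect_lt(abs(mean(divided) - p_div),
            4 * sqrt(p_div * (1 - p_div) / n_rep))
  # migration destination uniform over the 8 Moore neighbours
  mig <- table(moved_to[moved_to > 0])
  expect_identical(length(mig), 8L)
  expect_gt(stats::chisq.test(as.vector(mig))$p.value, 0.01)
})

test_that("one step preserves the structural invariants of the world", {
  cfg <- tiny_config(L = 41L, t_max = 15L)
  st <- initialize_world(cfg)
  tot_prev <- sum(total_counts(st))
  nec_prev <- 0L
  for (i in 1:15) {
    st <- step_world(st, cfg)
    tot <- sum(total_counts(st))
    nec <- sum(st$n_necrotic)
    expect_gte(tot, tot_prev)
    expect_gte(nec, nec_prev)
    occ <- total_counts(st) > 0L
    expect_true(all(st$rho_ecm[occ] == 0))
    expect_true(all(st$phi >= 0 & st$phi <= 1))
    expect_true(all(st$phi[c(1, 41), ] == 1))
    tot_prev <- tot
    nec_prev <- nec
  }
  expect_identical(st$t, 15L)
})

test_that("a fully necrotic world only evolves its fields", {
  cfg <- tiny_config(L = 7L)
  st <- world_state(7, phi = 0.5, rho_ecm = 0.3)
  st$n_necrotic[3:5, 3:5] <- 4L
  st$rho_ecm[3:5, 3:5] <- 0
  set.seed(9)
  out <- step_world(st, cfg)
  expect_identical(out$n_necrotic, st$n_necrotic)
  expect_identical(sum(out$n_prolif) + sum(out$n_invasive), 0L)
  expect_identical(out$rho_ecm, st$rho_ecm)  # no living cells, no degradation
})

test_that("stepping is deterministic under a fixed RNG state", {
  cfg <- tiny_config(L = 21L)
  st <- initialize_world(cfg)
  set.seed(77); a <- step_world(step_world(st, cfg), cfg)
  set.seed(77); b <- step_world(step_world(st, cfg), cfg)
  expect_identical(a, b)
})

test_that("run_simulation bookkeeping: records, halts and snapshots", {
  cfg0 <- tiny_config(L = 21L, t_max = 0L)
  sim0 <- run_simulation(cfg0)
  expect_identical(nrow(sim0$records), 1L)
  expect_identical(sim0$halt_reason, "t_max")

  # generous nutrients on a tiny lattice: the colony must reach the edge
  cfg1 <- tiny_config(L = 11L, t_max = 50L, k = 0, phi_c = 0.01)
  sim1 <- run_simulation(cfg1)
  expect_true(sim1$halted_early)
  expect_identical(sim1$halt_reason, "edge_contact")
  expect_lt(max(sim1$records$t), 50)

  cfg2 <- tiny_config(L = 61L, t_max = 12L, snapshot_times = c(5L, 10L))
  sim2 <- run_simulation(cfg2)
  expect_identical(nrow(sim2$records), 13L)
  expect_identical(names(sim2$snapshots), c("5", "10"))
  expect_identical(sim2$snapshots[["5"]]$t, 5L)

  # same seed, same trajectory
  sim3 <- run_simulation(cfg2)
  expect_identical(sim2$records, sim3$records)
  expect_identical(sim2$final_state, sim3$final_state)
})
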