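# Full weight dynamics: competition, self-depression, growth, bounds.

test_that("competition terms implement the thresholded row/column excesses", {
  W <- matrix(0.1, 4, 4); diag(W) <- 0
  ct <- competition_terms(W, W_max = 0.5)
  expect_equal(ct$delta_in, rep(0, 4))
  expect_equal(ct$delta_out, rep(0, 4))
  W[1, 2] <- 0.4  # row 1 sums to 0.6
  ct2 <- competition_terms(W, W_max = 0.3)
  expect_equal(ct2$delta_in[1], 0.3)
  expect_equal(ct2$delta_out[2], 0.3)
  # Heaviside convention: exactly at the bound there is no excess force
  W3 <- matrix(0, 2, 2); W3[1, 2] <- 0.3
  expect_equal(competition_terms(W3, 0.3)$delta_in[1], 0)
})

test_that("a single Euler step respects the cap, the bounds and degenerate configs", {
  ker <- default_kernel()
  tab <- motif_table(c("1,0" = 1))
  st <- generate_initial_weights(6, 2, 0.45, seed = 3)
  zero_drift <- truncated_drift(st, 1, motif_table(c("1,0" = 0)), 1)
  # all rates zero: nothing moves
  cfg0 <- plasticity_config(eta = 0, psi = 0, mu = 0, gamma = 0, M = 2,
                            w_max = 0.45, drift_mode = "table",
                            coeff_table = tab)
  step0 <- deterministic_step(st, cfg0, zero_drift)
  expect_identical(step0$state$W_ex, st$W_ex)
  # growth only: uniform increase until the per-synapse clip
  cfgg <- plasticity_config(eta = 1e-8, psi = 0, mu = 0, gamma = 225, M = 2,
                            w_max = 0.45, drift_mode = "table",
                            coeff_table = motif_table(c("1,0" = 0)),
                            step_cap = 0.01)
  stg <- st
  for (k in 1:5) stg <- deterministic_step(stg, cfgg, zero_drift)$state
  expect_equal(stg$W_ex[1, 2], min(st$W_ex[1, 2] + 5 * 0.01, 0.45))
  expect_true(all(diag(stg$W_ex) == 0))
  # realized max change equals the configured cap away from the bounds
  stc <- deterministic_step(st, cfgg, zero_drift)
  expect_equal(stc$max_change, 0.01, tolerance = 1e-12)
})

test_that("initial weights are uniform below the scaled bound and reproducible", {
  st <- generate_initial_weights(N = 20, M = 5, w_max = 0.18, scale = 1.5,
                                 seed = 4)
  ub <- 1.5 * 0.18 * 5 / 20
  expect_true(all(st$W_ex <= ub))
  expect_true(all(diag(st$W_ex) == 0))
  expect_gt(max(st$W_ex), 0.9 * ub)  # the draw actually fills the range
  st2 <- generate_initial_weights(N = 20, M = 5, w_max = 0.18, scale = 1.5,
                                  seed = 4)
  expect_identical(st$W_ex, st2$W_ex)
})

test_that("trajectories stay inside the hard bounds and adaptive stepping tracks a fine-step integration", {
  cfg <- figure_preset("fig7_latency_sweep", latency_d = 0.006,
                       max_iters = 60, step_cap = 5e-4)
  W0 <- generate_initial_weights(12, 5, cfg$w_max, scale = 1.5, seed = 5)
  traj <- run_deterministic(W0, cfg)
  for (cp in traj$checkpoints) {
    expect_true(all(cp$W_ex >= 0 & cp$W_ex <= cfg$w_max + 1e-12))
    expect_true(all(diag(cp$W_ex) == 0))
  }
  # fixed-tiny-step Euler oracle integrated to the same biological time
  T_end <- traj$time
  h_fine <- T_end / 4000
  Wf <- W0
  t <- 0
  while (t < T_end - 1e-12) {
    drift <- truncated_drift(Wf, stationary_rates(
      effective_connectivity(Wf), cfg$b), cfg$coeff_table, 3)
    rhs <- unclass(drift); rhs[is.na(rhs)] <- 0
    comp <- competition_terms(Wf$W_ex, cfg$W_max)
    slow <- -cfg$psi * outer(comp$delta_in, rep(1, 12)) -
      cfg$psi * outer(rep(1, 12), comp$delta_out) -
      cfg$mu * Wf$W_ex + cfg$gamma
    diag(slow) <- 0
    h <- min(h_fine, T_end - t)
    Wn <- pmin(pmax(Wf$W_ex + h * cfg$eta * (rhs + slow), 0), cfg$w_max)
    diag(Wn) <- 0
    Wf <- connectivity_state(Wn, cfg$w_max)
    t <- t + h
  }
  expect_lt(max(abs(traj$final_state$W_ex - Wf$W_ex)), 1e-3)
})

test_that("competition keeps row and column sums near the total bound, tighter for larger psi", {
  run_sums <- function(psi) {
    cfg <- figure_preset("fig7_latency_sweep", latency_d = 0.006, psi = psi,
                         max_iters = 4000)
    W0 <- generate_initial_weights(20, 5, cfg$w_max, scale = 1.5, seed = 6)
    traj <- run_deterministic(W0, cfg)
    max(c(rowSums(traj$final_state$W_ex), colSums(traj$final_state$W_ex)))
  }
  s_table <- run_sums(5e4)
  # with the learning rate multiplying all terms, the equilibrium excess is
  # set by (drift scale)/psi: small at the preset psi, smaller still at
  # 10x psi
  expect_lt(s_table, 0.9 * 1.10)
  s_big <- run_sums(5e5)
  expect_lt(s_big - 0.9, (s_table - 0.9) / 2)
})

test_that("stochastic plasticity is frozen at zero learning rate and seed-deterministic", {
  cfg <- figure_preset("fig8_eta_sweep", eta = 0, duration = 5, seed = 31)
  W0 <- generate_initial_weights(10, 5, cfg$w_max, scale = 1, seed = 7)
  traj <- run_stochastic(W0, cfg, checkpoint_times = c(2.5, 5))
  # eta = 0 freezes STDP but not the slow terms; freeze those too
  cfg_frozen <- figure_preset("fig8_eta_sweep", eta = 0, psi = 0, mu = 0,
                              gamma = 0, duration = 5, seed = 31)
  traj_frozen <- run_stochastic(W0, cfg_frozen, checkpoint_times = c(5))
  expect_equal(traj_frozen$final_state$W_ex, W0$W_ex)
  cfg2 <- figure_preset("fig8_eta_sweep", duration = 5, seed = 31)
  t1 <- run_stochastic(W0, cfg2, checkpoint_times = c(5))
  t2 <- run_stochastic(W0, cfg2, checkpoint_times = c(5))
  expect_identical(t1$final_state$W_ex, t2$final_state$W_ex)
  expect_identical(t1$n_spikes, t2$n_spikes)
  t3 <- run_stochastic(W0, figure_preset("fig8_eta_sweep", duration = 5,
                                         seed = 32),
                       checkpoint_times = c(5))
  expect_false(identical(t1$final_state$W_ex, t3$final_state$W_ex))
})

test_that("stochastic and deterministic engines agree on short-horizon weight growth", {
  # gamma-dominated regime: both engines should grow weights at eta*gamma
  cfg <- plasticity_config(eta = 1e-5, psi = 0, mu = 0, gamma = 10, M = 2,
                           w_max = 0.45, b = 5, drift_mode = "table",
                           coeff_table = motif_table(c("1,0" = 0)),
                           stdp = make_stdp("antisymmetric", h0 = 0),
                           duration = 50, seed = 41)
  W0 <- generate_initial_weights(5, 2, 0.45, seed = 8)
  traj <- run_stochastic(W0, cfg, checkpoint_times = c(50))
  expected <- pmin(W0$W_ex + 1e-5 * 10 * 50, 0.45)
  diag(expected) <- 0
  expect_equal(traj$final_state$W_ex, expected, tolerance = 1e-6)
})
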