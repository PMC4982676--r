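# Full weight dynamics: STDP drift + heterosynaptic competition +
# self-depression + constant growth + hard bounds, with balanced inhibition.
#
#   dW_ij/dt = eta * [ Delta_STDP_ij - psi*(Din_i + Dout_j) - mu*W_ij + gamma ]
#
# (the learning rate multiplies all plasticity terms by default -- the
# self-depression rate is eta*mu; set `eta_scales_slow_terms = FALSE` for the
# variant in which eta multiplies only the STDP term). Excitatory weights are
# clipped to [0, w_max] after each step.

#' Plasticity configuration
#'
#' Bundles the network, kernel/window, plasticity-rate and integration
#' parameters for the deterministic and stochastic engines.
#'
#' @param eta learning rate (dimensionless).
#' @param psi heterosynaptic competition rate (1/s).
#' @param mu self-depression rate (1/s); the conventional `300 * b`
#'   parameterization is `mu = 300 * b` with `b` in Hz.
#' @param gamma constant growth rate (1/s).
#' @param M group-size parameter: the row/column bound is
#'   `W_max = M * w_max`.
#' @param w_max per-synapse hard bound.
#' @param b external input rate (Hz).
#' @param kernel a \code{"synaptic_kernel"}.
#' @param stdp an \code{"stdp_function"}.
#' @param drift_mode `"exact"` (frequency-domain drift), `"truncated"`
#'   (motif expansion of `order` with coefficients computed from
#'   `stdp`/`kernel`), or `"table"` (motif expansion with a hand-set
#'   `coeff_table`).
#' @param order truncation order for `"truncated"` mode.
#' @param coeff_table a \code{"motif_table"} for `"table"` mode (computed
#'   automatically in `"truncated"` mode).
#' @param step_cap adaptive-Euler cap: the step size is chosen so the
#'   maximal weight change per step equals this value.
#' @param convergence_tol elementwise change threshold; the run converges
#'   when the change stays below it for 10 consecutive iterations (default
#'   `exp(-15)`).
#' @param max_iters deterministic iteration cap.
#' @param duration stochastic simulated time (s).
#' @param dt stochastic step (s, default 0.25 ms).
#' @param seed RNG seed for the stochastic engine.
#' @param use_inhibition include the balanced inhibitory component in the
#'   neural (and drift) dynamics.
#' @param eta_scales_slow_terms if `TRUE` (default) the learning rate
#'   multiplies the competition/self-depression/growth terms as well.
#' @param omega_max,domega frequency grid for `"exact"` drift.
#' @param n_checkpoints number of trajectory snapshots to keep.
#' @return an object of class \code{"plasticity_config"}.
#' @export
plasticity_config <- function(eta = 1e-8, psi = 5e4, mu = 0, gamma = 0,
                              M = 5, w_max = 0.9 / M, b = 15,
                              kernel = make_alpha_kernel(),
                              stdp = make_stdp("antisymmetric"),
                              drift_mode = c("exact", "truncated", "table"),
                              order = 3, coeff_table = NULL,
                              step_cap = 0.02,
                              convergence_tol = exp(-15),
                              max_iters = 20000, duration = 600,
                              dt = 2.5e-4, seed = 1,
                              use_inhibition = TRUE,
                              eta_scales_slow_terms = TRUE,
                              omega_max = 3e4, domega = 2,
                              n_checkpoints = 60) {
  drift_mode <- match.arg(drift_mode)
  if (eta < 0 || psi < 0 || gamma < 0) stop("eta, psi, gamma must be >= 0")
  if (drift_mode == "table" && is.null(coeff_table))
    stop("`coeff_table` is required in table mode")
  if (drift_mode == "truncated" && is.null(coeff_table))
    coeff_table <- coefficient_table(stdp, kernel, max_order = order)
  structure(list(eta = eta, psi = psi, mu = mu, gamma = gamma, M = M,
                 w_max = w_max, W_max = M * w_max, b = b, kernel = kernel,
                 stdp = stdp, drift_mode = drift_mode, order = order,
                 coeff_table = coeff_table, step_cap = step_cap,
                 convergence_tol = convergence_tol, max_iters = max_iters,
                 duration = duration, dt = dt, seed = seed,
                 use_inhibition = use_inhibition,
                 eta_scales_slow_terms = eta_scales_slow_terms,
                 omega_max = omega_max, domega = domega,
                 n_checkpoints = n_checkpoints),
            class = "plasticity_config")
}

#' @export
print.plasticity_config <- function(x, ...) {
  cat(sprintf(
    "plasticity config: drift %s%s, eta %g, psi %g, mu %g, gamma %g, M %d, w_max %g (W_max %g), b %g Hz\n",
    x$drift_mode,
    if (x$drift_mode != "exact") sprintf(" (order %d)", x$order) else "",
    x$eta, x$psi, x$mu, x$gamma, x$M, x$w_max, x$W_max, x$b))
  invisible(x)
}

#' Heterosynaptic competition terms
#'
#' Row-sum (input) and column-sum (output) excesses over the total bound:
#' \eqn{\Delta^{in}_i = \max(\sum_k W^{ex}_{ik} - W_{max}, 0)} and the
#' analogous column quantity (Heaviside convention gives 0 at equality).
#'
#' @param W_ex excitatory weight matrix.
#' @param W_max total input/output bound.
#' @return list with vectors `delta_in`, `delta_out`.
#' @export
competition_terms <- function(W_ex, W_max) {
  list(delta_in = pmax(rowSums(W_ex) - W_max, 0),
       delta_out = pmax(colSums(W_ex) - W_max, 0))
}

compute_drift <- function(state, config) {
  if (config$drift_mode == "exact") {
    exact_drift(state, config$kernel, config$stdp, config$b,
                use_inhibition = config$use_inhibition,
                omega_max = config$omega_max, domega = config$domega)
  } else {
    W <- if (config$use_inhibition) effective_connectivity(state)
         else state$W_ex
    # motif-table runs with zero external input use the dimensionless
    # convention r = 1 (a uniform rate factor is absorbed in the table)
    rv <- if (all(config$b == 0)) rep(1, nrow(W))
          else stationary_rates(W, config$b)$r
    truncated_drift(state, rv, config$coeff_table,
                    order = min(config$order, config$coeff_table$max_order),
                    use_inhibition = config$use_inhibition)
  }
}

#' One adaptive Euler step of the deterministic dynamics
#'
#' Sums the plasticity terms, chooses the step size so the maximal absolute
#' weight change equals `step_cap`, applies the step, clips to
#' `[0, w_max]`, re-applies the adjacency mask and zeroes the diagonal.
#'
#' @param state a \code{"connectivity_state"}.
#' @param config a \code{"plasticity_config"}.
#' @param drift a \code{"drift_matrix"} (diagonal ignored).
#' @return list with the new `state`, the step `h` (seconds of biological
#'   time) and the realized `max_change`.
#' @export
deterministic_step <- function(state, config, drift) {
  W <- state$W_ex
  N <- nrow(W)
  rhs <- unclass(drift)
  rhs[is.na(rhs)] <- 0
  if (any(!is.finite(rhs))) stop("non-finite drift")
  comp <- competition_terms(W, config$W_max)
  slow <- -config$psi * outer(comp$delta_in, rep(1, N)) -
    config$psi * outer(rep(1, N), comp$delta_out) -
    config$mu * W + config$gamma
  diag(slow) <- 0
  rhs <- if (config$eta_scales_slow_terms)
    config$eta * (rhs + slow)
  else config$eta * rhs + slow
  mx <- max(abs(rhs))
  if (mx == 0) return(list(state = state, h = 0, max_change = 0))
  h <- config$step_cap / mx
  Wnew <- pmin(pmax(W + h * rhs, 0), config$w_max)
  diag(Wnew) <- 0
  if (!is.null(state$adjacency_mask)) Wnew[!state$adjacency_mask] <- 0
  list(state = connectivity_state(Wnew, config$w_max,
                                  state$adjacency_mask),
       h = h, max_change = max(abs(Wnew - W)))
}

#' Run the deterministic (average) plasticity dynamics
#'
#' Iterates [deterministic_step()] with the drift recomputed every step
#' (exact or motif-truncated per the config), until the elementwise change
#' stays below `convergence_tol` for 10 consecutive iterations or the
#' iteration cap is reached. Snapshots are kept at geometrically spaced
#' iterations.
#'
#' @param W0 initial \code{"connectivity_state"} (e.g. from
#'   [generate_initial_weights()]).
#' @param config a \code{"plasticity_config"}.
#' @return an object of class \code{"trajectory"}: `checkpoints` (list of
#'   `time`, `iteration`, `W_ex`), `converged`, `iterations`,
#'   `final_state`, `time` (total biological time, s).
#' @export
run_deterministic <- function(W0, config) {
  stopifnot(inherits(W0, "connectivity_state"))
  state <- W0
  t_bio <- 0
  small <- 0L
  cps <- list(list(time = 0, iteration = 0L, W_ex = state$W_ex))
  next_cp <- 1
  converged <- FALSE
  it <- 0L
  while (it < config$max_iters) {
    it <- it + 1L
    drift <- tryCatch(compute_drift(state, config), error = function(e) e)
    if (inherits(drift, "error")) {
      warning(sprintf("aborting at iteration %d: %s", it,
                      conditionMessage(drift)))
      break
    }
    stepped <- deterministic_step(state, config, drift)
    state <- stepped$state
    t_bio <- t_bio + stepped$h
    small <- if (stepped$max_change < config$convergence_tol) small + 1L
             else 0L
    if (it >= next_cp) {
      cps[[length(cps) + 1]] <- list(time = t_bio, iteration = it,
                                     W_ex = state$W_ex)
      next_cp <- max(next_cp + 1, ceiling(next_cp * 1.25))
    }
    if (small >= 10L) { converged <- TRUE; break }
  }
  cps[[length(cps) + 1]] <- list(time = t_bio, iteration = it,
                                 W_ex = state$W_ex)
  structure(list(checkpoints = cps, converged = converged, iterations = it,
                 final_state = state, time = t_bio),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "plasticity trajectory: %d iterations (%.4g s biological time), %s, %d checkpoints\n",
    x$iterations, x$time, if (x$converged) "converged" else "not converged",
    length(x$checkpoints)))
  invisible(x)
}

#' Run the stochastic plasticity dynamics
#'
#' Spiking simulation with online plasticity: each 0.25 ms step draws
#' Poisson spikes, applies the pair-based STDP increments continuously via
#' exponential traces (windowed pair scan for the mexican-hat family),
#' applies the slow terms (competition, self-depression, growth) scaled by
#' `dt`, and clips to the hard bounds.
#'
#' @param W0 initial \code{"connectivity_state"}.
#' @param config a \code{"plasticity_config"} (uses `duration`, `dt`,
#'   `seed`).
#' @param checkpoint_times times (s) at which to snapshot the weights;
#'   default `n_checkpoints` uniformly spaced.
#' @return a \code{"trajectory"} (checkpoint times in seconds of simulated
#'   biological time).
#' @export
run_stochastic <- function(W0, config, checkpoint_times = NULL) {
  stopifnot(inherits(W0, "connectivity_state"))
  if (!is.null(W0$adjacency_mask))
    stop("the stochastic engine does not support adjacency masks")
  if (is.null(checkpoint_times))
    checkpoint_times <- seq(0, config$duration,
                            length.out = config$n_checkpoints + 1)[-1]
  ker <- config$kernel
  F <- config$stdp
  dsteps <- as.integer(round(ker$latency_d / config$dt))
  if (F$family == "mexican_hat") {
    family <- 2L
    window <- sqrt(log(1e16) / F$p)
    pars <- list(h0 = F$A, Ap = window, An = 0, t1p = F$sigma, t1n = F$cq,
                 t2 = F$p)
  } else {
    family <- 1L
    pars <- list(h0 = F$h0, Ap = F$Ap, An = F$An, t1p = F$tau1p,
                 t1n = F$tau1n, t2 = F$tau2)
  }
  set.seed(config$seed)
  res <- cpp_run_stochastic(
    W0$W_ex, rep_len(config$b, nrow(W0$W_ex)), ker$a0, ker$tau1, ker$tau2,
    dsteps, family, pars$h0, pars$Ap, pars$An, pars$t1p, pars$t1n, pars$t2,
    config$eta, config$psi, config$mu, config$gamma, config$w_max,
    config$W_max, config$duration, config$dt,
    if (config$eta_scales_slow_terms) config$eta else 1,
    config$use_inhibition, checkpoint_times)
  cps <- c(list(list(time = 0, iteration = 0L, W_ex = W0$W_ex)),
           lapply(seq_along(checkpoint_times), function(q)
             list(time = checkpoint_times[q],
                  iteration = as.integer(round(checkpoint_times[q] /
                                               config$dt)),
                  W_ex = res$checkpoints[, , q])))
  final <- connectivity_state(res$Wex, config$w_max, W0$adjacency_mask)
  structure(list(checkpoints = cps, converged = NA, iterations =
                   as.integer(round(config$duration / config$dt)),
                 final_state = final, time = config$duration,
                 n_spikes = res$n_spikes),
            class = "trajectory")
}
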