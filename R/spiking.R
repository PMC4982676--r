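# Stochastic simulation of the linear Poisson network and explicit
# spike-pair STDP accumulation.

#' Simulate a linear Poisson spiking network
#'
#' Stochastic Euler dynamics: at each step of length `dt` every neuron fires
#' a Bernoulli spike with probability `clip(lambda_i * dt, 0, 1)`, where
#' `lambda_i` is the spike history of the network filtered through the
#' synaptic kernel, weighted by the connectivity, plus the external input.
#' Negative intensities (possible with inhibition) are floored at zero. The
#' synaptic filter is carried as exact exponential state variables, so the
#' slow saturation constant is handled without truncation.
#'
#' @param state a \code{"connectivity_state"} (the balanced-inhibition
#'   effective matrix is used when `use_inhibition`) or a plain effective
#'   matrix used as-is.
#' @param kernel a \code{"synaptic_kernel"}; its latency is rounded to whole
#'   steps.
#' @param b external input rates (Hz).
#' @param duration simulated time (s).
#' @param dt step size (s, default 0.25 ms).
#' @param seed RNG seed (required for reproducibility).
#' @param use_inhibition add the balanced inhibitory component (default
#'   `TRUE` when `state` is a connectivity state).
#' @return an object of class \code{"spike_record"}: per-neuron sorted spike
#'   times plus `times`/`ids` event vectors, `N`, `duration`, `dt`, `seed`.
#' @export
simulate_spikes <- function(state, kernel, b, duration, dt = 2.5e-4,
                            seed = 1, use_inhibition = TRUE) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a finite number")
  if (duration <= 0) stop("`duration` must be positive")
  W <- if (inherits(state, "connectivity_state")) {
    if (use_inhibition) effective_connectivity(state) else state$W_ex
  } else as.matrix(state)
  N <- nrow(W)
  b <- rep_len(b, N)
  if (max(b) * dt > 0.5)
    warning("lambda * dt > 0.5 for the external input alone; reduce `dt`")
  dsteps <- as.integer(round(kernel$latency_d / dt))
  set.seed(seed)
  sim <- cpp_simulate(W, b, kernel$a0, kernel$tau1, kernel$tau2, dsteps,
                      duration, dt)
  new_spike_record(sim$times, sim$ids, N, duration, dt, seed)
}

#' Assemble a spike record from per-neuron spike-time lists
#'
#' @param spikes list of numeric vectors, one (sorted) spike-time vector per
#'   neuron.
#' @param duration record duration (s); defaults to just past the last spike.
#' @param dt nominal step size (s).
#' @param seed seed annotation (bookkeeping only).
#' @return a \code{"spike_record"}.
#' @export
spike_record <- function(spikes, duration = NULL, dt = 2.5e-4, seed = NA) {
  spikes <- lapply(spikes, sort)
  all_t <- unlist(spikes)
  if (is.null(duration))
    duration <- if (length(all_t)) max(all_t) + dt else dt
  if (length(all_t) && (min(all_t) < 0 || max(all_t) > duration))
    stop("spike times must lie within [0, duration]")
  ids <- rep(seq_along(spikes), vapply(spikes, length, 0L))
  ord <- order(all_t)
  new_spike_record(all_t[ord], ids[ord], length(spikes), duration, dt, seed)
}

new_spike_record <- function(times, ids, N, duration, dt, seed) {
  spikes <- split(times, factor(ids, levels = seq_len(N)))
  names(spikes) <- NULL
  structure(list(spikes = spikes, times = times, ids = ids, N = N,
                 duration = duration, dt = dt, seed = seed),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf(
    "spike record: N = %d, duration = %g s, dt = %g ms, %d spikes (mean rate %.3g Hz)\n",
    x$N, x$duration, x$dt * 1e3, length(x$times),
    length(x$times) / (x$N * x$duration)))
  invisible(x)
}

#' Empirical firing rates of a spike record
#'
#' @param record a \code{"spike_record"}.
#' @return per-neuron rates in Hz.
#' @export
spike_rates <- function(record) {
  vapply(record$spikes, length, 0L) / record$duration
}

#' Filtered spike history
#'
#' The per-neuron convolution of the recorded spike trains with the synaptic
#' kernel, evaluated at time `t` by an event-driven exponential-state
#' recursion (exact between events; equivalent to the direct sum of
#' `a(t - t')` over spikes).
#'
#' @param record a \code{"spike_record"}.
#' @param kernel a \code{"synaptic_kernel"}.
#' @param t evaluation time (s, `t <= duration`).
#' @return numeric vector of filtered activities (1/s), one per neuron.
#' @export
filtered_history <- function(record, kernel, t) {
  if (t > record$duration) stop("`t` exceeds the record duration")
  k1 <- 1 / kernel$tau1
  k2 <- 1 / kernel$tau1 + 1 / kernel$tau2
  vapply(record$spikes, function(ts) {
    ts <- ts[ts + kernel$latency_d < t]
    if (!length(ts)) return(0)
    u <- 0; v <- 0; tprev <- ts[1]
    for (s in ts) {
      dec <- s - tprev
      u <- u * exp(-k1 * dec) + 1
      v <- v * exp(-k2 * dec) + 1
      tprev <- s
    }
    rem <- t - kernel$latency_d - tprev
    kernel$a0 * (u * exp(-k1 * rem) - v * exp(-k2 * rem))
  }, 0)
}

#' Accumulated STDP change over a spike record
#'
#' Sums `F(t_post - t_pre)` over all ordered spike pairs (all-to-all
#' pairing), giving the total efficacy change per synapse before the
#' learning-rate factor. For the exponential window families the sum is
#' evaluated with per-neuron decaying traces in O(n_spikes * N); for the
#' mexican-hat family a windowed pair scan is used. The diagonal is `NA`
#' (self-pairing is meaningless).
#'
#' @param record a \code{"spike_record"}.
#' @param F an \code{"stdp_function"}.
#' @return N x N matrix of accumulated change (class
#'   \code{"drift_matrix"}-like with `NA` diagonal).
#' @export
accumulate_stdp <- function(record, F) {
  stopifnot(inherits(record, "spike_record"), inherits(F, "stdp_function"))
  if (!length(record$times)) {
    out <- matrix(0, record$N, record$N)
    diag(out) <- NA_real_
    return(out)
  }
  ord <- order(record$times)
  times <- record$times[ord]
  ids <- as.integer(record$ids[ord])
  if (F$family == "mexican_hat") {
    window <- sqrt(log(1e16) / F$p)
    out <- cpp_accumulate_mexhat(times, ids, record$N, F$A, F$sigma, F$cq,
                                 F$p, window)
  } else {
    out <- cpp_accumulate_exp(times, ids, record$N, F$h0, F$Ap, F$An,
                              F$tau1p, F$tau1n, F$tau2)
  }
  diag(out) <- NA_real_
  out
}

#' Empirical binned cross-correlogram
#'
#' Standard estimate of the pair correlation
#' \eqn{C_{ij}(\tau) = \langle S_i(t+\tau) S_j(t)\rangle}: pair counts per
#' lag bin, normalized per unit time and bin width. For `i == j` the zero
#' bin contains the autocorrelation atom (approximately `r_i / bin`).
#'
#' @param record a \code{"spike_record"}.
#' @param i,j post- and pre-synaptic neuron indices.
#' @param tau_grid bin centers (s), uniformly spaced.
#' @param bin bin width (s); defaults to the grid spacing.
#' @return list with `tau`, `value` (rate^2 units), `n_pairs`, and an
#'   `empty` flag when either train has no spikes.
#' @export
empirical_correlation <- function(record, i, j, tau_grid, bin = NULL) {
  ti <- record$spikes[[i]]
  tj <- record$spikes[[j]]
  if (is.null(bin)) bin <- diff(tau_grid[1:2])
  if (bin <= 0) stop("`bin` must be positive")
  if (!length(ti) || !length(tj)) {
    return(list(tau = tau_grid, value = numeric(length(tau_grid)),
                n_pairs = 0, empty = TRUE))
  }
  edges <- c(tau_grid - bin / 2, tau_grid[length(tau_grid)] + bin / 2)
  counts <- cpp_correlogram_counts(sort(ti), sort(tj), edges)
  list(tau = tau_grid, value = counts / (record$duration * bin),
       n_pairs = sum(counts), empty = FALSE)
}

#' Write / read a spike record as two-column text
#'
#' Header lines (prefixed `#`) carry `N`, `duration`, `dt` and `seed`; the
#' body is `neuron_index time_s`, one event per line.
#'
#' @param record a \code{"spike_record"}.
#' @param path file path.
#' @return `write_spike_record` the path; `read_spike_record` the record.
#' @export
write_spike_record <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# N %d", record$N),
               sprintf("# duration %.17g", record$duration),
               sprintf("# dt %.17g", record$dt),
               sprintf("# seed %d", as.integer(record$seed)),
               "neuron_index time_s"), con)
  writeLines(sprintf("%d %.17g", record$ids, record$times), con)
  invisible(path)
}

#' @rdname write_spike_record
#' @export
read_spike_record <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop(sprintf("missing header field '%s'", key))
    as.numeric(sub(paste0("^# ", key, " "), "", ln[1]))
  }
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  new_spike_record(body$time_s, as.integer(body$neuron_index),
                   as.integer(get("N")), get("duration"), get("dt"),
                   get("seed"))
}
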