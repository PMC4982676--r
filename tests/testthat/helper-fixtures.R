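# Shared fixtures and independent oracles used across the test files.

# random non-negative matrix with zero diagonal, rescaled to a target
# spectral radius
random_stable_W <- function(N, radius = 0.5, seed = 1, wmax_frac = 1) {
  set.seed(seed)
  W <- matrix(stats::runif(N * N), N, N)
  diag(W) <- 0
  W * radius / max(Mod(eigen(W, only.values = TRUE)$values))
}

# adjusted Rand index between two partitions (closed-form pair counting)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# brute-force all-pair STDP accumulation (O(n^2) oracle)
pairloop_stdp <- function(record, F) {
  N <- record$N
  out <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    ti <- record$spikes[[i]]; tj <- record$spikes[[j]]
    if (length(ti) && length(tj))
      out[i, j] <- sum(stdp_value(F, outer(ti, tj, "-")))
  }
  out
}

# time-domain drift oracle: integrate F * C over a fine time grid
# (rate-rate part in closed form via the window area)
drift_time_oracle <- function(W, kernel, F, b, dt = 1e-4, span = 1) {
  r <- stationary_rates(W, b)
  ct <- correlation_time(W, kernel, r, dt = dt, span = span)
  Fv <- stdp_value(F, ct$tau)
  f0 <- Re(stdp_fourier(F, 0))
  out <- f0 * ct$baseline
  N <- nrow(out)
  for (i in seq_len(N)) for (j in seq_len(N))
    out[i, j] <- out[i, j] + sum(Fv * ct$values[i, j, ]) * dt
  out
}

offdiag <- function(m) m[row(m) != col(m)]

default_kernel <- function(d = 0) make_alpha_kernel(latency_d = d)
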