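# Motif correlations, motif coefficients, exact drift and its truncations.

test_that("motif correlations reduce to the kernel, keep unit mass and match a direct convolution", {
  ker <- default_kernel()
  dt <- 5e-5
  c10 <- motif_correlation(ker, 1, 0, dt = dt)
  g <- function_grid(ker, dt = dt)
  expect_equal(c10$value[seq_along(g$t)], g$value, tolerance = 1e-10)
  for (ab in list(c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(2, 1), c(3, 2))) {
    cc <- motif_correlation(ker, ab[1], ab[2], dt = dt)
    expect_lt(abs(sum(cc$value) * dt - 1), 1e-4)
  }
  # direct O(n^2) discrete-convolution oracle for the {2, 0} motif
  dtc <- 2e-4
  av <- kernel_value(ker, seq(0, 0.1, by = dtc))
  n <- length(av)
  direct <- vapply(seq_len(n), function(k)
    sum(av[1:k] * av[k:1]) * dtc, 0)
  c20 <- motif_correlation(ker, 2, 0, dt = dtc)
  expect_equal(c20$value[seq_len(n)], direct, tolerance = 1e-8)
  expect_error(motif_correlation(ker, 0, 0), "at least 1")
})

test_that("time-domain and frequency-domain motif coefficients agree for all families", {
  ker <- default_kernel(0.003)
  pairs <- expand.grid(alpha = 0:5, beta = 0:5)
  pairs <- pairs[pairs$alpha + pairs$beta >= 1 &
                 pairs$alpha + pairs$beta <= 5, ]
  for (fam in c("antisymmetric", "mexican_hat", "asymmetric")) {
    F <- make_stdp(fam)
    ft <- mapply(function(a, b) motif_coefficient(F, ker, a, b, "time"),
                 pairs$alpha, pairs$beta)
    ff <- mapply(function(a, b) motif_coefficient(F, ker, a, b, "frequency"),
                 pairs$alpha, pairs$beta)
    # relative to the family's coefficient scale (antisymmetric windows have
    # exact zeros at alpha == beta, where a ratio test is ill-posed)
    expect_lt(max(abs(ft - ff)) / max(abs(ft)), 1e-3)
  }
})

test_that("antisymmetric windows give antisymmetric coefficient tables", {
  ker <- default_kernel()
  Fa <- make_stdp("antisymmetric")
  tab <- coefficient_table(Fa, ker, max_order = 4)
  scale <- max(abs(tab$coeffs$f))
  for (q in seq_len(nrow(tab$coeffs))) {
    a <- tab$coeffs$alpha[q]; b <- tab$coeffs$beta[q]
    fba <- table_lookup(tab, b, a)
    expect_lt(abs(tab$coeffs$f[q] + fba) / scale, 1e-6)
    if (a == b) expect_lt(abs(tab$coeffs$f[q]) / scale, 1e-6)
  }
  expect_lt(abs(motif_coefficient(Fa, ker, 1, 1)) / scale, 1e-8)
  # even window: symmetric table
  Fm <- make_stdp("mexican_hat")
  tabm <- coefficient_table(Fm, ker, max_order = 3)
  for (q in seq_len(nrow(tabm$coeffs)))
    expect_equal(tabm$coeffs$f[q],
                 table_lookup(tabm, tabm$coeffs$beta[q],
                              tabm$coeffs$alpha[q]),
                 tolerance = 1e-6)
  # order-1 table holds exactly the two first-order coefficients
  tab1 <- coefficient_table(Fa, ker, max_order = 1)
  expect_setequal(paste(tab1$coeffs$alpha, tab1$coeffs$beta),
                  c("1 0", "0 1"))
})

test_that("synaptic latency reshapes coefficients by the path-length difference", {
  Fa <- make_stdp("antisymmetric")
  ds <- seq(0, 0.010, by = 0.002)
  co <- function(a, b) vapply(ds, function(d)
    motif_coefficient(Fa, default_kernel(d), a, b), 0)
  f10 <- co(1, 0); f20 <- co(2, 0); f21 <- co(2, 1); f11 <- co(1, 1)
  f22 <- co(2, 2); f31 <- co(3, 1); f32 <- co(3, 2)
  # alpha - beta = 1 and 2: strictly decreasing over 0-10 ms
  expect_true(all(diff(f10) < 0))
  expect_true(all(diff(f20) < 0))
  # the third-order {2,1} coefficient barely moves while {1,0} and {2,0}
  # lose most of their magnitude
  rel21 <- max(abs(f21 - f21[1])) / abs(f21[1])
  expect_lt(rel21, 0.5)
  expect_lt(rel21, 0.5 * max(abs(f10 - f10[1])) / abs(f10[1]))
  expect_lt(rel21, 0.5 * max(abs(f20 - f20[1])) / abs(f20[1]))
  # alpha == beta: zero for an antisymmetric window, at every latency
  expect_lt(max(abs(c(f11, f22))) / abs(f21[1]), 1e-6)
  # same alpha - beta means similar latency dependence: {3,2} tracks {2,1}
  expect_lt(max(abs(f32 - f32[1])) / abs(f32[1]), 0.5)
  # alpha - beta = 2 decays rapidly, like {2,0}
  expect_lt(f31[length(ds)] / f31[1], 0.25)
})

test_that("exact drift reduces to the rate-rate term at zero coupling", {
  ker <- default_kernel()
  r <- c(10, 15, 20)
  # antisymmetric window: zero area, zero drift
  Da <- exact_drift(matrix(0, 3, 3), ker, make_stdp("antisymmetric"), r)
  expect_lt(max(abs(drift_offdiag(Da))), 1e-6)
  # mexican hat: f0 r_i r_j off-diagonal
  Fm <- make_stdp("mexican_hat")
  Dm <- exact_drift(matrix(0, 3, 3), ker, Fm, r)
  f0 <- Re(stdp_fourier(Fm, 0))
  expect_equal(drift_offdiag(unclass(Dm)), drift_offdiag(f0 * outer(r, r)),
               tolerance = 1e-6)
})

test_that("frequency-domain drift matches the time-domain overlap integral", {
  ker <- default_kernel(0.002)
  W <- random_stable_W(4, radius = 0.5, seed = 21)
  for (fam in c("antisymmetric", "mexican_hat")) {
    F <- make_stdp(fam)
    D <- exact_drift(W, ker, F, 15)
    oracle <- drift_time_oracle(W, ker, F, 15)
    expect_lt(max(abs(drift_offdiag(D) - offdiag(oracle))) /
                max(abs(offdiag(oracle))), 1e-3)
  }
})

test_that("the truncated expansion reproduces the first-order terms and converges to the exact drift", {
  ker <- default_kernel()
  Fa <- make_stdp("antisymmetric")
  tab <- coefficient_table(Fa, ker, max_order = 6)
  W <- random_stable_W(5, radius = 0.5, seed = 22)
  r <- stationary_rates(W, 15)
  # order 0: rate-rate term only
  D0 <- truncated_drift(W, r, tab, order = 0)
  expect_equal(drift_offdiag(unclass(D0)),
               offdiag(tab$f0 * outer(r$r, r$r)))
  # order 1 equals the local learning rule written out by hand
  D1 <- truncated_drift(W, r, tab, order = 1)
  f10 <- table_lookup(tab, 1, 0); f01 <- table_lookup(tab, 0, 1)
  hand <- tab$f0 * outer(r$r, r$r) +
    f10 * W * matrix(r$r, 5, 5, byrow = TRUE) + f01 * t(W) * r$r
  expect_equal(drift_offdiag(unclass(D1)), offdiag(hand), tolerance = 1e-12)
  # monotone error decay toward the exact drift
  Dex <- exact_drift(W, ker, Fa, 15)
  errs <- vapply(1:6, function(o)
    max(abs(drift_offdiag(truncated_drift(W, r, tab, o)) -
            drift_offdiag(Dex))), 0)
  expect_true(all(diff(errs) < 0))
  expect_error(truncated_drift(W, r, tab, order = 7), "exceeds")
})

test_that("stochastically accumulated STDP scatters around the exact drift and tightens with time", {
  # fixed random connectivity, balanced inhibition, rates near 15 Hz
  N <- 10
  set.seed(77)
  Wex <- matrix(runif(N * N, 0, 2 * 0.9 / N), N, N); diag(Wex) <- 0
  st <- connectivity_state(Wex, w_max = 0.9)
  ker <- default_kernel()
  Fa <- make_stdp("antisymmetric")
  Dth <- exact_drift(st, ker, Fa, 15)
  acc <- function(T, seed) {
    rec <- simulate_spikes(st, ker, 15, duration = T, seed = seed)
    accumulate_stdp(rec, Fa) / T
  }
  d_short <- acc(120, 1)
  d_long <- acc(960, 2)
  off <- row(Wex) != col(Wex)
  expect_gt(stats::cor(d_long[off], unclass(Dth)[off]), 0.9)
  s_short <- stats::sd(d_short[off] - unclass(Dth)[off])
  s_long <- stats::sd(d_long[off] - unclass(Dth)[off])
  # scatter shrinks like 1/sqrt(T): variance ratio 8, within a factor of 2
  expect_gt((s_short / s_long)^2, 4)
  expect_lt((s_short / s_long)^2, 16)
})
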