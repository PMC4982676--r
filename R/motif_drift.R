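# Exact STDP drift, motif coefficients, and the truncated motif expansion.
#
# The drift (expected efficacy change per unit time, averaged over Poisson
# realizations) is, in the frequency domain,
#   Delta = f0 r r^T +
#     (1/2pi) Int dw Ftil(-w) (I - atil(w) W)^-1 D (I - atil(-w) W^T)^-1,
# and its power-series expansion in W reads
#   Delta_ij = f0 r_i r_j + sum_{a,b} f_{a,b} [W^a D (W^b)^T]_ij,
# where f_{a,b} couples the STDP window to the correlation time course
# induced by the {a,b} structural motif.

drift_matrix <- function(delta) {
  diag(delta) <- NA_real_  # no self-synapses: diagonal drift is meaningless
  structure(delta, class = c("drift_matrix", "matrix"))
}

#' @export
print.drift_matrix <- function(x, ...) {
  off <- x[row(x) != col(x)]
  cat(sprintf(
    "drift matrix (%d x %d, diagonal ignored): off-diagonal range [%.4g, %.4g]\n",
    nrow(x), ncol(x), min(off), max(off)))
  invisible(x)
}

#' Off-diagonal entries of a drift matrix
#'
#' @param delta a \code{"drift_matrix"} (or any square matrix).
#' @return numeric vector of the off-diagonal entries.
#' @export
drift_offdiag <- function(delta) {
  delta <- unclass(delta)
  delta[row(delta) != col(delta)]
}

default_omega_grid <- function(omega_max = 3e4, domega = 2) {
  seq(0, omega_max, by = domega)
}

#' Exact STDP drift (frequency-domain evaluation)
#'
#' Evaluates the exact drift on a uniform frequency grid using closed-form
#' transforms of the kernel and the STDP window. The rate-rate term
#' `f0 r r^T` uses the closed-form window area. The diagonal is flagged
#' `NA` (no self-synapses) and is never applied by the plasticity engine.
#'
#' @param state a \code{"connectivity_state"} or effective matrix.
#' @param kernel a \code{"synaptic_kernel"}.
#' @param F an \code{"stdp_function"}.
#' @param b external input rates (Hz).
#' @param use_inhibition if `TRUE` (default) and `state` is a connectivity
#'   state, the balanced-inhibition effective matrix enters both the rates
#'   and the correlation structure.
#' @param omega_max,domega frequency-grid extent and step (rad/s).
#' @param rates optional precomputed rates (overrides `b`); in particular the
#'   motif-table convention `rates = 1` for input-free artificial runs.
#' @return a \code{"drift_matrix"} (units 1/s).
#' @export
exact_drift <- function(state, kernel, F, b, use_inhibition = TRUE,
                        omega_max = 3e4, domega = 2, rates = NULL) {
  W <- if (inherits(state, "connectivity_state")) {
    if (use_inhibition) effective_connectivity(state) else state$W_ex
  } else as.matrix(state)
  N <- nrow(W)
  if (stability_margin(W) <= 0)
    stop(sprintf("unstable connectivity: max |eigenvalue| = %.6g >= 1",
                 max(Mod(eigen(W, only.values = TRUE)$values))))
  rv <- if (is.null(rates)) stationary_rates(W, b)$r else as_rates(rates, N)
  omega <- default_omega_grid(omega_max, domega)
  atil <- kernel_fourier(kernel, omega)
  Fmw <- stdp_fourier(F, -omega)
  # tail check: the off-diagonal integrand (which carries at least one
  # kernel factor) must be negligible at the grid edge
  env <- Mod(Fmw) * Mod(atil)
  if (max(env) > 0 && env[length(env)] / max(env) > 1e-6)
    stop("frequency integral not converged: increase `omega_max`")
  f0 <- Re(stdp_fourier(F, 0))
  delta <- f0 * outer(rv, rv) + cpp_drift_freq(W, rv, omega, atil, Fmw)
  drift_matrix(delta)
}

#' Motif-induced correlation time course
#'
#' The correlation shape induced by the `{alpha, beta}` structural motif:
#' the `alpha`-fold convolution of the kernel `a(t)` with the `beta`-fold
#' convolution of `a(-t)`. Computed by FFT on a uniform grid whose support
#' is extended with the motif order to avoid wrap-around. The result has
#' unit integral (convolution of unit-area functions).
#'
#' @param kernel a \code{"synaptic_kernel"}.
#' @param alpha,beta non-negative path lengths, `alpha + beta >= 1`.
#' @param dt grid step in seconds.
#' @return list with `t` (times) and `value` (density, 1/s).
#' @export
motif_correlation <- function(kernel, alpha, beta, dt = 5e-5) {
  if (alpha < 0 || beta < 0 || alpha + beta < 1)
    stop("`alpha + beta` must be at least 1 (non-negative orders)")
  g <- function_grid(kernel, dt = dt)
  n <- length(g$t)
  total <- alpha + beta
  # linear convolution by zero-padded FFT of `total` copies
  Lfull <- total * (n - 1) + 1
  Lpad <- stats::nextn(Lfull, 2)
  fa <- stats::fft(c(g$value, numeric(Lpad - n)))
  spec <- fa^alpha * Conj(fa)^beta
  conv <- Re(stats::fft(spec, inverse = TRUE)) / Lpad * dt^(total - 1)
  # Conj(fa)^beta corresponds to the reversed sequence circularly shifted;
  # time origin: index 1 is lag 0 of (alpha forward - beta backward) samples.
  # Equivalent time axis: (k - beta*(n-1)) * dt for k = 0..Lfull-1 after
  # rotating the negative-lag part from the end of the circular buffer.
  vals <- conv[1:Lfull]
  if (beta > 0) {
    nneg <- beta * (n - 1)
    vals <- c(conv[(Lpad - nneg + 1):Lpad], conv[1:(Lfull - nneg)])
  }
  tt <- (seq_len(Lfull) - 1 - beta * (n - 1)) * dt
  list(t = tt, value = vals)
}

#' Motif coefficient f_{alpha, beta}
#'
#' Overlap integral of the STDP window with the motif correlation time
#' course, \eqn{f_{\alpha\beta} = \int F(t)\, c_{\alpha\beta}(t)\, dt}
#' (time-domain route, the default), or equivalently
#' \eqn{\frac{1}{2\pi}\int d\omega\, \tilde F(-\omega)\,
#' \tilde a(\omega)^\alpha \tilde a(-\omega)^\beta} (frequency-domain route,
#' used as an independent cross-check). Dimensionless.
#'
#' @param F an \code{"stdp_function"}.
#' @param kernel a \code{"synaptic_kernel"}.
#' @param alpha,beta motif path lengths (`alpha + beta >= 1`).
#' @param method `"time"` or `"frequency"`.
#' @param dt time-grid step (`"time"` method).
#' @param omega_max,domega frequency grid (`"frequency"` method).
#' @return scalar coefficient.
#' @export
motif_coefficient <- function(F, kernel, alpha, beta,
                              method = c("time", "frequency"),
                              dt = 5e-5, omega_max = 4e4, domega = 1) {
  method <- match.arg(method)
  if (alpha + beta < 1) stop("`alpha + beta` must be at least 1")
  if (method == "time") {
    cc <- motif_correlation(kernel, alpha, beta, dt = dt)
    sum(stdp_value(F, cc$t) * cc$value) * dt
  } else {
    omega <- seq(0, omega_max, by = domega)
    atil <- kernel_fourier(kernel, omega)
    integrand <- stdp_fourier(F, -omega) * atil^alpha * Conj(atil)^beta
    # fold the negative-frequency half: term(-w) = conj(term(w))
    (Re(integrand[1]) + 2 * sum(Re(integrand[-1]))) * domega / (2 * pi)
  }
}

#' Table of motif coefficients up to a maximum order
#'
#' Computes `f0` and all `f_{alpha,beta}` with
#' `1 <= alpha + beta <= max_order` for a given STDP window / kernel pair.
#'
#' @param F an \code{"stdp_function"}.
#' @param kernel a \code{"synaptic_kernel"}.
#' @param max_order maximum motif order (`alpha + beta`).
#' @param method,dt passed to [motif_coefficient()].
#' @return an object of class \code{"motif_table"}: list with `f0`, `coeffs`
#'   (data.frame `alpha`, `beta`, `f`), `max_order`, `provenance`.
#' @export
coefficient_table <- function(F, kernel, max_order,
                              method = c("time", "frequency"), dt = 5e-5) {
  method <- match.arg(method)
  if (max_order < 1) stop("`max_order` must be at least 1")
  pairs <- expand.grid(alpha = 0:max_order, beta = 0:max_order)
  pairs <- pairs[pairs$alpha + pairs$beta >= 1 &
                 pairs$alpha + pairs$beta <= max_order, ]
  pairs <- pairs[order(pairs$alpha + pairs$beta, pairs$alpha), ]
  f <- mapply(function(a, b)
    motif_coefficient(F, kernel, a, b, method = method, dt = dt),
    pairs$alpha, pairs$beta)
  structure(list(f0 = Re(stdp_fourier(F, 0)),
                 coeffs = data.frame(alpha = pairs$alpha, beta = pairs$beta,
                                     f = as.numeric(f)),
                 max_order = max_order,
                 provenance = if (method == "time") "time_domain"
                              else "frequency_domain"),
            class = "motif_table")
}

#' Assemble a motif table from explicit coefficients
#'
#' Used for runs in which the coefficients are tuned by hand rather than
#' derived from a window/kernel pair (e.g. selected-motif simulations).
#'
#' @param coeffs named numeric vector like `c("1,0" = 1, "0,1" = -1)` or a
#'   data.frame with columns `alpha`, `beta`, `f`.
#' @param f0 the rate-rate coefficient (default 0).
#' @return a \code{"motif_table"}.
#' @export
motif_table <- function(coeffs, f0 = 0) {
  if (is.data.frame(coeffs)) {
    df <- coeffs
  } else {
    ab <- do.call(rbind, lapply(strsplit(names(coeffs), ","), as.integer))
    df <- data.frame(alpha = ab[, 1], beta = ab[, 2],
                     f = as.numeric(coeffs))
  }
  structure(list(f0 = f0, coeffs = df, max_order = max(df$alpha + df$beta),
                 provenance = "manual"),
            class = "motif_table")
}

#' @export
print.motif_table <- function(x, ...) {
  cat(sprintf("motif coefficient table (%s): f0 = %.6g, %d coefficients up to order %d\n",
              x$provenance, x$f0, nrow(x$coeffs), x$max_order))
  print(utils::head(x$coeffs, 10))
  invisible(x)
}

table_lookup <- function(table, alpha, beta) {
  hit <- table$coeffs$alpha == alpha & table$coeffs$beta == beta
  if (!any(hit)) 0 else table$coeffs$f[hit][1]
}

#' Truncated motif-expansion drift
#'
#' Evaluates the power-series drift
#' \eqn{\Delta_{ij} = f_0 r_i r_j + \sum_{1 \le \alpha+\beta \le n}
#' f_{\alpha\beta} [W^\alpha D (W^\beta)^T]_{ij}} with \eqn{W^0 = I}, so the
#' first-order terms reduce to \eqn{f_{1,0} r_j W_{ij} + f_{0,1} r_i W_{ji}}.
#'
#' @param state connectivity state or effective matrix.
#' @param r rates (a `rate_vector`, a numeric vector, or a scalar).
#' @param table a \code{"motif_table"}.
#' @param order truncation order (`<= table$max_order`).
#' @param use_inhibition as in [exact_drift()].
#' @return a \code{"drift_matrix"}.
#' @export
truncated_drift <- function(state, r, table, order = table$max_order,
                            use_inhibition = TRUE) {
  if (order > table$max_order)
    stop("`order` exceeds the table's maximum order")
  W <- if (inherits(state, "connectivity_state")) {
    if (use_inhibition) effective_connectivity(state) else state$W_ex
  } else as.matrix(state)
  N <- nrow(W)
  rv <- as_rates(r, N)
  # powers of W up to `order` (index p + 1 holds W^p)
  pows <- vector("list", order + 1)
  pows[[1]] <- diag(N)
  for (p in seq_len(order)) pows[[p + 1]] <- pows[[p]] %*% W
  delta <- table$f0 * outer(rv, rv)
  keep <- table$coeffs$alpha + table$coeffs$beta <= order
  cf <- table$coeffs[keep, , drop = FALSE]
  for (q in seq_len(nrow(cf))) {
    a <- cf$alpha[q]; b <- cf$beta[q]; f <- cf$f[q]
    if (f == 0) next
    Wa <- pows[[a + 1]]
    Wb <- pows[[b + 1]]
    delta <- delta + f * (Wa %*% (rv * t(Wb)))
  }
  drift_matrix(delta)
}

#' Export a motif table as long-format text
#'
#' @param table a \code{"motif_table"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_motif_table <- function(table, path) {
  df <- rbind(data.frame(alpha = 0, beta = 0, f = table$f0), table$coeffs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("alpha beta f_value", con)
  writeLines(sprintf("%d %d %.17g", df$alpha, df$beta, df$f), con)
  invisible(path)
}

#' @rdname write_motif_table
#' @export
read_motif_table <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  names(df) <- c("alpha", "beta", "f")
  f0row <- df$alpha == 0 & df$beta == 0
  motif_table(df[!f0row, , drop = FALSE],
              f0 = if (any(f0row)) df$f[f0row][1] else 0)
}
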