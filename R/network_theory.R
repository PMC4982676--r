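# Exact stationary rates and spike cross-correlation functions for the
# linear Poisson network.

#' Stationary firing rates
#'
#' Solves \eqn{r = (I - \tilde a(0) W)^{-1} b} with \eqn{\tilde a(0) = 1}
#' (unit-area kernel). Requires a stable connectivity (spectral radius of `W`
#' below 1).
#'
#' @param W effective connectivity matrix.
#' @param b external input rates (Hz); recycled to length N.
#' @return an object of class \code{"rate_vector"}: list with `r`, `b`.
#' @export
stationary_rates <- function(W, b) {
  W <- as.matrix(W)
  N <- nrow(W)
  b <- rep_len(b, N)
  m <- stability_margin(W)
  if (m <= 0)
    stop(sprintf(
      "unstable connectivity: max |eigenvalue| = %.6g >= 1", 1 - m))
  r <- solve(diag(N) - W, b)
  structure(list(r = as.numeric(r), b = b), class = "rate_vector")
}

#' @export
print.rate_vector <- function(x, ...) {
  cat(sprintf("stationary rates (Hz): mean %.4g, range [%.4g, %.4g]\n",
              mean(x$r), min(x$r), max(x$r)))
  invisible(x)
}

as_rates <- function(r, N) {
  if (inherits(r, "rate_vector")) r$r else rep_len(as.numeric(r), N)
}

#' Spike cross-covariance spectrum
#'
#' Non-singular part of the correlation spectrum of the linear Poisson
#' network,
#' \deqn{\tilde C(\omega) = 2\pi\delta(\omega) r r^T +
#'   (I - \tilde a(\omega) W)^{-1} D (I - \tilde a(-\omega) W^T)^{-1},}
#' with \eqn{D = \mathrm{diag}(r)}. The delta atom at zero frequency is
#' carried symbolically in the `rate_outer` field; the returned array is the
#' non-singular matrix factor per frequency.
#'
#' @param W effective connectivity matrix (spectral radius < 1).
#' @param kernel a \code{"synaptic_kernel"}.
#' @param r rates: a \code{"rate_vector"} or numeric vector.
#' @param omega frequency grid (rad/s).
#' @return list with `omega`, `values` (complex N x N x length(omega) array)
#'   and `rate_outer` (the \eqn{r r^T} coefficient of the delta atom).
#' @export
correlation_spectrum <- function(W, kernel, r, omega) {
  W <- as.matrix(W)
  if (stability_margin(W) <= 0)
    stop(sprintf("unstable connectivity: max |eigenvalue| = %.6g >= 1",
                 max(Mod(eigen(W, only.values = TRUE)$values))))
  rv <- as_rates(r, nrow(W))
  atil <- kernel_fourier(kernel, omega)
  vals <- cpp_correlation_spectrum(W, rv, atil)
  list(omega = omega, values = vals, rate_outer = outer(rv, rv))
}

#' Spike cross-correlation functions in the time domain
#'
#' Inverse Fourier transform of the non-singular spectrum part, plus the
#' constant \eqn{r_i r_j} baseline. The Poisson self-correlation atom
#' \eqn{r_i \delta(\tau)} on the diagonal is carried symbolically in
#' `delta_atom` (never as a grid spike). Satisfies
#' \eqn{C_{ij}(\tau) = C_{ji}(-\tau)}.
#'
#' @param W effective connectivity matrix.
#' @param kernel a \code{"synaptic_kernel"}.
#' @param r rates.
#' @param dt time-grid step (seconds).
#' @param span half-width of the time grid (seconds).
#' @return list with `tau`, `values` (N x N x L array: the smooth covariance
#'   part \eqn{C_{ij}(\tau) - r_i r_j} without atoms), `baseline`
#'   (\eqn{r_i r_j}), `delta_atom` (vector of diagonal atom masses `r_i`).
#' @export
correlation_time <- function(W, kernel, r, dt = 2e-4, span = 0.6) {
  W <- as.matrix(W)
  N <- nrow(W)
  rv <- as_rates(r, N)
  L <- 2 * ceiling(span / dt)
  # FFT-layout frequencies: k = 0..L-1, with k > L/2 aliased to negative
  k <- 0:(L - 1)
  ksigned <- ifelse(k >= L / 2, k - L, k)
  omega <- 2 * pi * ksigned / (L * dt)
  if (stability_margin(W) <= 0)
    stop("unstable connectivity")
  atil <- kernel_fourier(kernel, omega)
  vals <- cpp_correlation_spectrum(W, rv, atil)
  # subtract the white D part (its transform is the diagonal delta atom)
  phi <- array(0, dim = c(N, N, L))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    spec <- vals[i, j, ]
    if (i == j) spec <- spec - rv[i]
    phi_ij <- stats::fft(spec, inverse = TRUE) / (L * dt)
    phi[i, j, ] <- Re(phi_ij)
  }
  # reorder from FFT layout (0..T, -T..0) to symmetric times
  ord <- c((L / 2 + 1):L, 1:(L / 2))
  tau <- ksigned[ord] * dt
  phi <- phi[, , ord, drop = FALSE]
  list(tau = tau, values = phi, baseline = outer(rv, rv), delta_atom = rv)
}

#' Export correlograms as long-format text
#'
#' @param ct result of [correlation_time()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_correlogram <- function(ct, path) {
  N <- dim(ct$values)[1]
  idx <- expand.grid(i = seq_len(N), j = seq_len(N))
  rows <- do.call(rbind, lapply(seq_len(nrow(idx)), function(q) {
    i <- idx$i[q]; j <- idx$j[q]
    data.frame(i = i, j = j, tau_s = ct$tau,
               value = ct$values[i, j, ] + ct$baseline[i, j])
  }))
  utils::write.table(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
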