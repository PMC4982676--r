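# Synaptic-current kernels and STDP window functions.
#
# Both families used throughout the package are differences of exponentials,
#   e(t; tau_a, tau_2) = exp(-t/tau_a) * (1 - exp(-t/tau_2)),   t > 0,
# for which the one-sided Fourier transform has the closed form
#   q(tau_a, tau_2, i*w) = 1/(1/tau_a + i*w) - 1/(1/tau_a + 1/tau_2 + i*w).
# Closed forms are used for evaluation and transforms; uniform-grid
# tabulations are used for convolutions and as independent cross-checks.

one_sided_exp_transform <- function(tau_a, tau_2, s) {
  1 / (1 / tau_a + s) - 1 / (1 / tau_a + 1 / tau_2 + s)
}

#' Construct a synaptic current kernel
#'
#' Builds the post-synaptic current time course
#' \deqn{a(t) = a_0 \exp(-(t-d)/\tau_1)\,(1 - \exp(-(t-d)/\tau_2))} for
#' \eqn{t > d} and 0 otherwise, with the normalization coefficient \eqn{a_0}
#' chosen so that \eqn{\int a(t)\,dt = 1}. With this normalization a synapse
#' of efficacy 1 adds, on average, one spike to the post-synaptic neuron per
#' pre-synaptic spike.
#'
#' @param tau1 decay time constant in seconds (default 5 ms).
#' @param tau2 rise-saturation time constant in seconds (default 1 s).
#' @param latency_d synaptic latency in seconds (delay of current onset
#'   relative to the pre-synaptic spike), must be non-negative.
#' @return An object of class \code{"synaptic_kernel"}.
#' @examples
#' ker <- make_alpha_kernel()
#' kernel_value(ker, c(0.001, 0.005, 0.02))
#' @export
make_alpha_kernel <- function(tau1 = 0.005, tau2 = 1, latency_d = 0) {
  if (!is.numeric(tau1) || length(tau1) != 1L || !is.finite(tau1) || tau1 <= 0)
    stop("`tau1` must be a positive number (seconds)")
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 <= 0)
    stop("`tau2` must be a positive number (seconds)")
  if (!is.numeric(latency_d) || length(latency_d) != 1L ||
      !is.finite(latency_d) || latency_d < 0)
    stop("`latency_d` must be a non-negative number (seconds)")
  # integral of the unnormalized shape: tau1^2 / (tau1 + tau2)
  a0 <- (tau1 + tau2) / tau1^2
  structure(list(tau1 = tau1, tau2 = tau2, latency_d = latency_d, a0 = a0),
            class = "synaptic_kernel")
}

#' @export
print.synaptic_kernel <- function(x, ...) {
  cat(sprintf(
    "synaptic kernel: tau1 = %g ms, tau2 = %g ms, latency = %g ms, a0 = %g /s\n",
    x$tau1 * 1e3, x$tau2 * 1e3, x$latency_d * 1e3, x$a0))
  invisible(x)
}

#' Evaluate a synaptic kernel
#'
#' Piecewise evaluation of the current time course; vectorized over `t`.
#'
#' @param kernel a \code{"synaptic_kernel"}.
#' @param t times in seconds (any numeric vector).
#' @return current density values (1/s), zero for `t <= latency_d`.
#' @export
kernel_value <- function(kernel, t) {
  stopifnot(inherits(kernel, "synaptic_kernel"))
  s <- t - kernel$latency_d
  out <- numeric(length(t))
  pos <- s > 0
  out[pos] <- kernel$a0 * exp(-s[pos] / kernel$tau1) *
    (1 - exp(-s[pos] / kernel$tau2))
  out
}

#' Fourier transform of a synaptic kernel
#'
#' Uses the convention \eqn{\tilde g(\omega) = \int e^{-i\omega t} g(t) dt}.
#' The transform satisfies \eqn{\tilde a(0) = 1} and
#' \eqn{|\tilde a(\omega)| \le 1}; a latency `d` contributes the phase factor
#' \eqn{e^{-i\omega d}}.
#'
#' @param kernel a \code{"synaptic_kernel"}.
#' @param omega angular frequencies (rad/s).
#' @return complex vector of the same length as `omega`.
#' @export
kernel_fourier <- function(kernel, omega) {
  stopifnot(inherits(kernel, "synaptic_kernel"), is.numeric(omega))
  kernel$a0 * exp(-1i * omega * kernel$latency_d) *
    one_sided_exp_transform(kernel$tau1, kernel$tau2, 1i * omega)
}

#' Tabulate a kernel or STDP window on a uniform grid
#'
#' Helper used by the convolution machinery and exportable as two-column
#' text. The span is chosen so the truncated tail mass is below `tail_tol`
#' relative to the total (the ms-scale decay constants make the supports a
#' few hundred ms despite the second-scale saturation constants).
#'
#' @param f a \code{"synaptic_kernel"} or \code{"stdp_function"}.
#' @param dt grid step in seconds (default 0.05 ms).
#' @param tail_tol relative tolerance on the discarded tail mass.
#' @return list with `t` (times) and `value`.
#' @export
function_grid <- function(f, dt = 5e-5, tail_tol = 1e-8) {
  if (inherits(f, "synaptic_kernel")) {
    t_max <- f$latency_d - f$tau1 * log(tail_tol * 1e-2)
    t <- seq(0, t_max, by = dt)
    list(t = t, value = kernel_value(f, t))
  } else if (inherits(f, "stdp_function")) {
    if (f$family == "mexican_hat") {
      t_max <- f$sigma * sqrt(-log(tail_tol * 1e-2) / (f$p * f$sigma^2))
    } else {
      t_max <- -max(f$tau1p, f$tau1n) * log(tail_tol * 1e-2)
    }
    tp <- seq(0, t_max, by = dt)
    t <- c(-rev(tp[-1]), tp)  # exactly symmetric grid
    list(t = t, value = stdp_value(f, t))
  } else stop("unsupported object")
}

#' Construct an STDP window function
#'
#' Three parametric families of the learning window F(tau), where tau is the
#' post-minus-pre spike time difference:
#' \describe{
#'   \item{antisymmetric}{\eqn{F = h_0 h(t)} with
#'     \eqn{h(t) = A_\pm e^{\mp t/\tau_1}(1 - e^{\mp t/\tau_2})} on the two
#'     branches; defaults \eqn{h_0 = 10^4}, \eqn{\tau_1} = 3 ms,
#'     \eqn{\tau_2} = 2 s, \eqn{A_+ = 0.8/\tau_1}, \eqn{A_- = -A_+}.}
#'   \item{mexican_hat}{\eqn{F(t) = A (1 - t^2/(c_q\sigma^2))
#'     \exp(-8 t^2/(c_e \sigma^2))}; defaults \eqn{\sigma} = 12 ms,
#'     \eqn{A = 5.2\cdot 10^4}, \eqn{c_q = 2}, \eqn{c_e = 5} (both
#'     denominators switchable, see `quad_denom`/`exp_denom`).}
#'   \item{asymmetric}{as antisymmetric but with distinct branch constants
#'     \eqn{\tau_1^+} = 3 ms, \eqn{\tau_1^-} = 4.5 ms,
#'     \eqn{A_+ = 0.8/\tau_1^+}, \eqn{A_- = -0.525/\tau_1^-}, and \eqn{h_0}
#'     fixed so that the (positive) area under F equals 150.}
#' }
#'
#' @param family one of `"antisymmetric"`, `"mexican_hat"`, `"asymmetric"`.
#' @param h0 overall amplitude (antisymmetric family; computed internally for
#'   the asymmetric family).
#' @param tau1,tau1_plus,tau1_minus,tau2 branch time constants in seconds.
#' @param A_plus,A_minus branch amplitudes; `NULL` means family default.
#' @param A,sigma mexican-hat amplitude and width.
#' @param quad_denom `"2sigma2"` (default) or `"sigma2"`: denominator of the
#'   quadratic term.
#' @param exp_denom `"5sigma2"` (default) or `"25sigma2"`: denominator of the
#'   Gaussian exponent (times \eqn{\sigma^2/8}).
#' @param area asymmetric family only: target area under F (default 150).
#' @return An object of class \code{"stdp_function"}.
#' @examples
#' Fa <- make_stdp("antisymmetric")
#' stdp_value(Fa, c(-0.003, 0.003))
#' @export
make_stdp <- function(family = c("antisymmetric", "mexican_hat", "asymmetric"),
                      h0 = 1e4, tau1 = 0.003, tau2 = 2,
                      A_plus = NULL, A_minus = NULL,
                      A = 5.2e4, sigma = 0.012,
                      quad_denom = c("2sigma2", "sigma2"),
                      exp_denom = c("5sigma2", "25sigma2"),
                      tau1_plus = 0.003, tau1_minus = 0.0045, area = 150) {
  family <- match.arg(family)
  obj <- list(family = family)
  if (family == "antisymmetric") {
    if (tau1 <= 0 || tau2 <= 0) stop("time constants must be positive")
    Ap <- if (is.null(A_plus)) 0.8 / tau1 else A_plus
    An <- if (is.null(A_minus)) -Ap else A_minus
    obj <- c(obj, list(h0 = h0, tau1p = tau1, tau1n = tau1, tau2 = tau2,
                       Ap = Ap, An = An))
  } else if (family == "asymmetric") {
    if (tau1_plus <= 0 || tau1_minus <= 0 || tau2 <= 0)
      stop("time constants must be positive")
    Ap <- if (is.null(A_plus)) 0.8 / tau1_plus else A_plus
    An <- if (is.null(A_minus)) -0.525 / tau1_minus else A_minus
    # area of h in closed form; h0 scales it to `area`
    h_area <- Ap * Re(one_sided_exp_transform(tau1_plus, tau2, 0)) +
      An * Re(one_sided_exp_transform(tau1_minus, tau2, 0))
    if (abs(h_area) < .Machine$double.eps)
      stop("asymmetric window has zero area; cannot normalize")
    obj <- c(obj, list(h0 = area / h_area, tau1p = tau1_plus,
                       tau1n = tau1_minus, tau2 = tau2, Ap = Ap, An = An))
  } else {
    quad_denom <- match.arg(quad_denom)
    exp_denom <- match.arg(exp_denom)
    if (sigma <= 0) stop("`sigma` must be positive")
    cq <- if (quad_denom == "2sigma2") 2 else 1
    ce <- if (exp_denom == "5sigma2") 5 else 25
    obj <- c(obj, list(A = A, sigma = sigma, cq = cq, ce = ce,
                       p = 8 / (ce * sigma^2)))
  }
  structure(obj, class = "stdp_function")
}

#' @export
print.stdp_function <- function(x, ...) {
  if (x$family == "mexican_hat") {
    cat(sprintf("STDP window (mexican hat): sigma = %g ms, A = %g\n",
                x$sigma * 1e3, x$A))
  } else {
    cat(sprintf(
      "STDP window (%s): h0 = %g, tau1+ = %g ms, tau1- = %g ms, tau2 = %g s\n",
      x$family, x$h0, x$tau1p * 1e3, x$tau1n * 1e3, x$tau2))
  }
  invisible(x)
}

#' Evaluate an STDP window
#'
#' @param F a \code{"stdp_function"}.
#' @param t post-minus-pre spike time differences, in seconds.
#' @return window values (efficacy change per spike pair); vectorized.
#' @export
stdp_value <- function(F, t) {
  stopifnot(inherits(F, "stdp_function"))
  if (F$family == "mexican_hat") {
    return(F$A * (1 - t^2 / (F$cq * F$sigma^2)) * exp(-F$p * t^2))
  }
  out <- numeric(length(t))
  pos <- t > 0
  neg <- t < 0
  out[pos] <- F$h0 * F$Ap * exp(-t[pos] / F$tau1p) *
    (1 - exp(-t[pos] / F$tau2))
  out[neg] <- F$h0 * F$An * exp(t[neg] / F$tau1n) *
    (1 - exp(t[neg] / F$tau2))
  out
}

#' Fourier transform of an STDP window (closed form)
#'
#' Same sign convention as [kernel_fourier()]. For the mexican-hat family the
#' transform is real and even; for the exponential families it is the sum of
#' the two one-sided branch transforms.
#'
#' @param F a \code{"stdp_function"}.
#' @param omega angular frequencies (rad/s).
#' @return complex vector.
#' @export
stdp_fourier <- function(F, omega) {
  stopifnot(inherits(F, "stdp_function"), is.numeric(omega))
  if (F$family == "mexican_hat") {
    p <- F$p
    g <- sqrt(pi / p) * exp(-omega^2 / (4 * p))
    return(as.complex(F$A * g *
      (1 - (1 / (F$cq * F$sigma^2)) * (1 / (2 * p) - omega^2 / (4 * p^2)))))
  }
  F$h0 * (F$Ap * one_sided_exp_transform(F$tau1p, F$tau2, 1i * omega) +
          F$An * one_sided_exp_transform(F$tau1n, F$tau2, -1i * omega))
}

#' Area under an STDP window (the zeroth motif coefficient f0)
#'
#' Computed by quadrature on a dense uniform grid; has dimensions of time.
#' For the antisymmetric family the odd integrand gives 0 (to grid
#' tolerance); the closed-form value is available as
#' `Re(stdp_fourier(F, 0))`.
#'
#' @param F a \code{"stdp_function"}.
#' @param dt quadrature step (seconds).
#' @return scalar f0.
#' @export
stdp_area <- function(F, dt = 5e-5) {
  g <- function_grid(F, dt = dt)
  sum(g$value) * dt
}

#' Export a tabulated function as two-column text
#'
#' @param f a kernel or STDP window.
#' @param path output file.
#' @param dt grid step (seconds).
#' @return the path, invisibly.
#' @export
write_function_table <- function(f, path, dt = 5e-5) {
  g <- function_grid(f, dt = dt)
  utils::write.table(data.frame(time_s = g$t, value = g$value), path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}
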