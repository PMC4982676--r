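# Connectivity containers and the balanced-inhibition effective matrix.

#' Construct a connectivity state
#'
#' Holds the excitatory weight matrix `W_ex` (non-negative, zero diagonal,
#' bounded by `w_max` elementwise) together with the per-synapse bound and an
#' optional structural adjacency mask (masked entries are forced to zero).
#'
#' @param W_ex numeric N x N matrix of excitatory efficacies.
#' @param w_max per-synapse hard bound.
#' @param adjacency_mask optional logical N x N matrix; `FALSE` entries are
#'   structurally absent synapses.
#' @return an object of class \code{"connectivity_state"}.
#' @export
connectivity_state <- function(W_ex, w_max, adjacency_mask = NULL) {
  W_ex <- as.matrix(W_ex)
  if (nrow(W_ex) != ncol(W_ex)) stop("`W_ex` must be square")
  if (!is.numeric(w_max) || length(w_max) != 1L || w_max <= 0)
    stop("`w_max` must be a positive scalar")
  if (any(!is.finite(W_ex))) stop("`W_ex` contains non-finite entries")
  if (any(W_ex < 0)) stop("`W_ex` must be non-negative")
  if (any(W_ex > w_max + 1e-12)) stop("`W_ex` exceeds `w_max`")
  if (any(diag(W_ex) != 0)) stop("`W_ex` must have a zero diagonal")
  if (!is.null(adjacency_mask)) {
    adjacency_mask <- as.matrix(adjacency_mask)
    if (!identical(dim(adjacency_mask), dim(W_ex)))
      stop("`adjacency_mask` dimensions do not match `W_ex`")
    if (any(W_ex[!adjacency_mask] != 0))
      stop("masked entries of `W_ex` must be zero")
  }
  structure(list(W_ex = W_ex, w_max = w_max, adjacency_mask = adjacency_mask),
            class = "connectivity_state")
}

#' @export
print.connectivity_state <- function(x, ...) {
  N <- nrow(x$W_ex)
  cat(sprintf(
    "connectivity state: N = %d, w_max = %g, %d nonzero synapses%s\n",
    N, x$w_max, sum(x$W_ex > 0),
    if (is.null(x$adjacency_mask)) "" else ", masked"))
  invisible(x)
}

#' Effective connectivity with balanced inhibition
#'
#' Adds to the excitatory matrix an effective inhibitory component
#' \eqn{W^{in}_{ik} = -\frac{1}{N}\sum_l W^{ex}_{il}} (constant along each
#' row, including the diagonal), modelling a global inhibitory drive that
#' balances the summed excitation into each neuron. Every row of the
#' returned matrix sums to zero.
#'
#' @param state a \code{"connectivity_state"} or a plain excitatory matrix.
#' @return the effective N x N matrix `W = W_ex + W_in`.
#' @export
effective_connectivity <- function(state) {
  W_ex <- if (inherits(state, "connectivity_state")) state$W_ex else
    as.matrix(state)
  N <- nrow(W_ex)
  W_ex - matrix(rowSums(W_ex) / N, N, N)
}

#' Stability margin of a connectivity matrix
#'
#' Returns `1 - max(|eigenvalues(W)|)`. The linear Poisson network is stable,
#' and the motif power series converges for every frequency, exactly when the
#' margin is positive (the kernel normalization puts \eqn{\tilde a(0) = 1}).
#'
#' @param W effective connectivity matrix (or a `connectivity_state`, whose
#'   excitatory matrix is then used).
#' @return scalar margin.
#' @export
stability_margin <- function(W) {
  if (inherits(W, "connectivity_state")) W <- W$W_ex
  1 - max(Mod(eigen(W, only.values = TRUE)$values))
}

#' Random initial weights
#'
#' Draws i.i.d. uniform weights on `[0, scale * w_max * M / N]` with a zero
#' diagonal, the initial condition used throughout the self-organization
#' experiments (`scale` 1 or 1.5 depending on the experiment).
#'
#' @param N number of neurons.
#' @param M group-size parameter (sets the total bound `W_max = M * w_max`).
#' @param w_max per-synapse bound.
#' @param scale upper-bound multiplier (1 or 1.5).
#' @param seed RNG seed.
#' @return a \code{"connectivity_state"}.
#' @export
generate_initial_weights <- function(N, M, w_max, scale = 1, seed = 1) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a finite number")
  set.seed(seed)
  W <- matrix(stats::runif(N * N, 0, scale * w_max * M / N), N, N)
  diag(W) <- 0
  connectivity_state(W, w_max = w_max)
}

#' Write / read a connectivity matrix as dense whitespace-delimited text
#'
#' The one-line header carries `N` and `w_max`; values are written in full
#' precision so a roundtrip is bitwise exact.
#'
#' @param state a \code{"connectivity_state"}.
#' @param path file path.
#' @return `write_connectivity` the path; `read_connectivity` the state.
#' @export
write_connectivity <- function(state, path) {
  stopifnot(inherits(state, "connectivity_state"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %.17g", nrow(state$W_ex), state$w_max), con)
  writeLines(apply(state$W_ex, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  lines <- readLines(path)
  hdr <- scan(text = lines[1], quiet = TRUE)
  if (length(hdr) != 2) stop("malformed connectivity header at line 1")
  N <- as.integer(hdr[1])
  if (length(lines) < N + 1) stop("truncated connectivity file")
  W <- do.call(rbind, lapply(seq_len(N), function(i) {
    v <- scan(text = lines[i + 1], quiet = TRUE)
    if (length(v) != N) stop(sprintf("malformed row at line %d", i + 1))
    v
  }))
  connectivity_state(W, w_max = hdr[2])
}
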