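# Chain / assembly structure score: similarity of a connectivity matrix to
# an ideal wide synfire chain or to ideal self-connected assemblies.
#
# Pipeline: k-means on the concatenated input+output weight vectors of each
# neuron, greedy ordering of the groups by feed-forward drive, comparison of
# the max-scaled matrix with the ideal binary matrix, and maximization of
# 1 - x over group counts, restarts and head-group choices.

#' Cluster neurons by their synaptic profiles
#'
#' k-means (squared Euclidean distance, multiple restarts) on the N vectors
#' that concatenate each neuron's excitatory input row and output column.
#'
#' @param W_ex excitatory weight matrix.
#' @param k number of groups (`2 <= k <= N`).
#' @param seed RNG seed for the restarts.
#' @param n_restarts k-means restarts (best inertia kept).
#' @return integer vector of group labels (1..k), with attribute
#'   `"degenerate"` set when fewer than `k` distinct profiles exist.
#' @export
cluster_neurons <- function(W_ex, k, seed = 1, n_restarts = 10) {
  W_ex <- as.matrix(W_ex)
  N <- nrow(W_ex)
  if (k < 2 || k > N) stop("`k` must be between 2 and N")
  X <- cbind(W_ex, t(W_ex))
  ndistinct <- nrow(unique(X))
  if (ndistinct < k) {
    # fewer distinct profiles than clusters: assign by profile identity
    labels <- as.integer(factor(apply(X, 1, paste, collapse = "\r")))
    attr(labels, "degenerate") <- TRUE
    return(labels)
  }
  set.seed(seed)
  # convergence warnings are benign here: a sub-optimal partition can only
  # lower the similarity score, and the best of `n_restarts` starts is kept
  km <- tryCatch(
    suppressWarnings(
      stats::kmeans(X, centers = k, nstart = n_restarts, iter.max = 200)),
    error = function(e) e)
  if (inherits(km, "error")) {
    set.seed(seed + 1000003L)
    km <- suppressWarnings(
      stats::kmeans(X, centers = k, nstart = n_restarts, iter.max = 200,
                    algorithm = "Lloyd"))
  }
  as.integer(km$cluster)
}

#' Greedy feed-forward ordering of groups
#'
#' Starting from a chosen head group, repeatedly appends the unused group
#' that receives the largest total synaptic input from the current group
#' (ties broken by lowest group index).
#'
#' @param labels per-neuron group labels.
#' @param W_ex excitatory weight matrix.
#' @param first head group (default: group 1).
#' @return permutation of the group labels (the chain order).
#' @export
order_groups_chain <- function(labels, W_ex, first = NULL) {
  groups <- sort(unique(labels))
  if (length(groups) < 2) return(groups)
  if (is.null(first)) first <- groups[1]
  ordering <- first
  remaining <- setdiff(groups, first)
  current <- first
  while (length(remaining)) {
    drive <- vapply(remaining, function(g)
      sum(W_ex[labels == g, labels == current, drop = FALSE]), 0)
    nxt <- remaining[which.max(drive)]  # which.max takes the first maximum
    ordering <- c(ordering, nxt)
    remaining <- setdiff(remaining, nxt)
    current <- nxt
  }
  ordering
}

#' Ideal binary connectivity matrix
#'
#' Chain mode: entry `(i, j)` is 1 iff the group of `j` immediately precedes
#' the group of `i` in the ordering (optionally wrapping the last group onto
#' the first). Assembly mode: 1 iff `i` and `j` share a group and differ.
#' The diagonal is always zero.
#'
#' @param labels per-neuron group labels.
#' @param ordering group ordering (chain mode).
#' @param mode `"chain"` or `"assembly"`.
#' @param wrap close the chain into a ring (default `FALSE`).
#' @return binary N x N matrix.
#' @export
ideal_matrix <- function(labels, ordering = sort(unique(labels)),
                         mode = c("chain", "assembly"), wrap = FALSE) {
  mode <- match.arg(mode)
  N <- length(labels)
  B <- matrix(0, N, N)
  if (mode == "assembly") {
    B <- outer(labels, labels, "==") * 1
  } else {
    ng <- length(ordering)
    succ <- if (wrap) c(ordering[-1], ordering[1]) else ordering[-1]
    pred <- if (wrap) ordering else ordering[-ng]
    for (q in seq_along(succ))
      B[labels == succ[q], labels == pred[q]] <- 1
  }
  diag(B) <- 0
  B
}

score_against <- function(A_scaled, B) {
  x <- sum((A_scaled - B)^2) / max(sum(B^2), 1)
  min(max(1 - x, 0), 1)
}

#' Chain / assembly structure score
#'
#' For each group count `k` and restart: cluster, order (every group tried
#' as the head in chain mode), build the ideal binary matrix `B` and compute
#' the normalized squared distance
#' \eqn{x = \|A/\max(A) - B\|_F^2 / \|B\|_F^2} of the max-scaled weight
#' matrix. The score is `1 - x` clipped to `[0, 1]`, maximized over `k`,
#' restarts and head choices; 1 is a perfect match.
#'
#' @param W_ex excitatory weight matrix (or a `connectivity_state`).
#' @param k_range candidate group counts (default `2:floor(N/2)`).
#' @param seeds restart seeds for the clustering (one k-means multi-restart
#'   per seed).
#' @param mode `"chain"` or `"assembly"`.
#' @param wrap chain wrap-around flag (see [ideal_matrix()]).
#' @return an object of class \code{"score_result"}: `score`, `best_k`,
#'   `labels`, `ordering`, `mode`.
#' @export
chain_score <- function(W_ex, k_range = NULL, seeds = 1:2,
                        mode = c("chain", "assembly"), wrap = FALSE) {
  mode <- match.arg(mode)
  if (inherits(W_ex, "connectivity_state")) W_ex <- W_ex$W_ex
  W_ex <- as.matrix(W_ex)
  N <- nrow(W_ex)
  if (is.null(k_range)) k_range <- 2:max(2, floor(N / 2))
  mx <- max(W_ex)
  A <- if (mx > 0) W_ex / mx else W_ex
  best <- list(score = -Inf, best_k = NA_integer_, labels = NULL,
               ordering = NULL, mode = mode)
  for (k in k_range) {
    if (k > N) next
    for (sd in seeds) {
      labels <- tryCatch(cluster_neurons(W_ex, k, seed = sd),
                         error = function(e) NULL)
      if (is.null(labels)) next
      groups <- sort(unique(labels))
      if (mode == "assembly") {
        B <- ideal_matrix(labels, mode = "assembly")
        sc <- score_against(A, B)
        if (sc > best$score)
          best <- list(score = sc, best_k = k, labels = labels,
                       ordering = groups, mode = mode)
      } else {
        for (head in groups) {
          ordering <- order_groups_chain(labels, W_ex, first = head)
          B <- ideal_matrix(labels, ordering, mode = "chain", wrap = wrap)
          sc <- score_against(A, B)
          if (sc > best$score)
            best <- list(score = sc, best_k = k, labels = labels,
                         ordering = ordering, mode = mode)
        }
      }
      if (isTRUE(attr(labels, "degenerate"))) break  # same labels for all seeds
    }
  }
  structure(best, class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("%s score: %.6g (best k = %d)\n",
              x$mode, x$score, x$best_k))
  invisible(x)
}

#' Build an ideal block feed-forward (or assembly) connectivity state
#'
#' Convenience generator for calibration and fixtures: `n_groups` ordered
#' groups of `group_size` neurons, every neuron projecting with weight
#' `weight` to every neuron of the next group (chain) or of its own group
#' (assembly).
#'
#' @param n_groups number of groups.
#' @param group_size neurons per group.
#' @param weight synaptic weight of present connections.
#' @param mode `"chain"` or `"assembly"`.
#' @return a \code{"connectivity_state"} with `w_max = weight`.
#' @export
ideal_connectivity <- function(n_groups, group_size, weight = 1,
                               mode = c("chain", "assembly")) {
  mode <- match.arg(mode)
  labels <- rep(seq_len(n_groups), each = group_size)
  B <- ideal_matrix(labels, seq_len(n_groups), mode = mode)
  connectivity_state(B * weight, w_max = weight)
}

#' Write a score result as a small key-value report
#'
#' @param result a \code{"score_result"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_score_result <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("mode %s", result$mode),
               sprintf("score %.17g", result$score),
               sprintf("best_k %d", result$best_k),
               sprintf("labels %s", paste(result$labels, collapse = " ")),
               sprintf("ordering %s", paste(result$ordering, collapse = " "))),
             con)
  invisible(path)
}
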