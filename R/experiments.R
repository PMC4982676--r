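# Config-driven reproduction of the self-organization sweep experiments at
# desk scale, plus per-experiment parameter presets.
#
# The presets encode the per-experiment reference parameters verbatim
# (N = 20 throughout; b = 15 Hz except the assembly experiment's 5 Hz and
# the selected-motif runs' 0; M = 5 or 4; total bound W_max = 0.85 or 0.9
# with per-synapse bound w_max = W_max / M -- the row sums must stay below 1
# for the linear network to be stable; gamma = 225 /s or 0; psi, eta, mu,
# latency per experiment), so call sites never re-transcribe them.

#' Named parameter presets for the self-organization experiments
#'
#' Returns a \code{"plasticity_config"} (plus auxiliary sweep axes as
#' attributes) for one of the named experiments:
#' \describe{
#'   \item{fig5_coeffs}{antisymmetric window + default kernel; coefficient
#'     curves vs synaptic latency (no dynamics).}
#'   \item{fig6_motif_grid}{selected-motif deterministic runs on the
#'     (f_{1,0}, f_{0,1}) / (f_{1,0}, f_{2,1}) grids; psi = 2e3,
#'     W_max = 0.85, gamma = 225, step cap 1e-4.}
#'   \item{fig7_mu_sweep}{full dynamics, chain score vs self-depression rate
#'     mu; psi = 5e4, W_max = 0.9, gamma = 225, d = 0, step cap 0.02.}
#'   \item{fig7_latency_sweep}{full dynamics, chain score vs latency;
#'     mu = 300 b.}
#'   \item{fig8_eta_sweep}{stochastic runs at d = 6 ms, mu = 300 b, over
#'     learning rates.}
#'   \item{fig9_assembly}{stochastic mexican-hat run, b = 5 Hz, psi = 1e5,
#'     eta = 2.5e-9, M = 4, gamma = 0, d = 5.25 ms.}
#'   \item{s2_second_order}{selected-motif grids over second-order
#'     coefficients.}
#'   \item{s3_wmax}{latency sweep at W_max 0.9/0.7/0.5 (M = 4).}
#'   \item{s4_asymmetric}{latency sweep with the asymmetric window,
#'     mu = 600 b, gamma = 0, M = 4.}
#'   \item{s5_high_order}{coefficient-vs-latency curves grouped by
#'     alpha - beta (no dynamics).}
#' }
#'
#' @param tag preset name.
#' @param latency_d synaptic latency override (s) where applicable.
#' @param ... further overrides passed to [plasticity_config()].
#' @return a \code{"plasticity_config"}.
#' @export
figure_preset <- function(tag = c("fig5_coeffs", "fig6_motif_grid",
                                  "fig7_mu_sweep", "fig7_latency_sweep",
                                  "fig8_eta_sweep", "fig9_assembly",
                                  "s2_second_order", "s3_wmax",
                                  "s4_asymmetric", "s5_high_order"),
                          latency_d = NULL, ...) {
  tag <- match.arg(tag)
  kd <- function(d) make_alpha_kernel(latency_d = if (is.null(latency_d)) d
                                                  else latency_d)
  args <- switch(tag,
    fig5_coeffs = ,
    s5_high_order = list(
      eta = 1e-8, psi = 5e4, mu = 0, gamma = 0, M = 5, w_max = 0.9 / 5,
      b = 15, kernel = kd(0), stdp = make_stdp("antisymmetric"),
      drift_mode = "exact"),
    fig6_motif_grid = list(
      eta = 1e-8, psi = 2e3, mu = 0, gamma = 225, M = 5, w_max = 0.85 / 5,
      b = 15, kernel = kd(0), stdp = make_stdp("antisymmetric"),
      drift_mode = "table", step_cap = 1e-4,
      coeff_table = motif_table(c("1,0" = 0, "0,1" = -30, "2,1" = 20,
                                  "1,2" = -20))),
    fig7_mu_sweep = list(
      eta = 1e-8, psi = 5e4, mu = 300 * 15, gamma = 225, M = 5,
      w_max = 0.9 / 5, b = 15, kernel = kd(0),
      stdp = make_stdp("antisymmetric"), drift_mode = "truncated",
      order = 3, step_cap = 0.02),
    fig7_latency_sweep = list(
      eta = 1e-8, psi = 5e4, mu = 300 * 15, gamma = 225, M = 5,
      w_max = 0.9 / 5, b = 15, kernel = kd(0),
      stdp = make_stdp("antisymmetric"), drift_mode = "truncated",
      order = 3, step_cap = 0.02),
    fig8_eta_sweep = list(
      eta = 4e-7, psi = 5e4, mu = 300 * 15, gamma = 225, M = 5,
      w_max = 0.9 / 5, b = 15, kernel = kd(0.006),
      stdp = make_stdp("antisymmetric"), drift_mode = "truncated",
      order = 3, step_cap = 0.002),
    fig9_assembly = list(
      eta = 2.5e-9, psi = 1e5, mu = 0, gamma = 0, M = 4, w_max = 0.9 / 4,
      b = 5, kernel = kd(0.00525), stdp = make_stdp("mexican_hat"),
      drift_mode = "exact"),
    s2_second_order = list(
      eta = 1e-8, psi = 2e3, mu = 0, gamma = 225, M = 5, w_max = 0.85 / 5,
      b = 15, kernel = kd(0), stdp = make_stdp("antisymmetric"),
      drift_mode = "table", step_cap = 1e-4,
      coeff_table = motif_table(c("1,0" = -2, "0,1" = -30, "2,1" = 20,
                                  "1,2" = -20))),
    s3_wmax = list(
      eta = 1e-8, psi = 5e4, mu = 300 * 15, gamma = 225, M = 4,
      w_max = 0.9 / 4, b = 15, kernel = kd(0),
      stdp = make_stdp("antisymmetric"), drift_mode = "truncated",
      order = 3, step_cap = 0.02),
    s4_asymmetric = list(
      eta = 1e-8, psi = 5e4, mu = 600 * 15, gamma = 0, M = 4,
      w_max = 0.9 / 4, b = 15, kernel = kd(0),
      stdp = make_stdp("asymmetric"), drift_mode = "truncated",
      order = 3, step_cap = 0.02))
  over <- list(...)
  args[names(over)] <- over
  do.call(plasticity_config, args)
}

#' Specify a sweep experiment
#'
#' @param figure_tag preset name (see [figure_preset()]).
#' @param grid data.frame of per-point overrides; recognized columns are
#'   `latency_d`, `mu`, `eta`, `w_max`, `duration`, and motif coefficients
#'   named like `f_2,1` (table mode). An empty or `NULL` grid runs the
#'   preset once.
#' @param n_inits random initial connectivities per grid point.
#' @param seeds base seeds, one per init.
#' @param init_scale initial-weight upper-bound multiplier (1 or 1.5; the
#'   full-dynamics experiments use 1.5).
#' @param N network size.
#' @param mode `"deterministic"` or `"stochastic"` engine.
#' @param score_mode `"chain"` or `"assembly"`.
#' @param out_dir optional directory for per-run artifacts.
#' @param ... further preset overrides.
#' @return an object of class \code{"experiment_spec"}.
#' @export
experiment_spec <- function(figure_tag, grid = NULL, n_inits = 3,
                            seeds = seq_len(n_inits), init_scale = 1.5,
                            N = 20, mode = c("deterministic", "stochastic"),
                            score_mode = c("chain", "assembly"),
                            out_dir = NULL, ...) {
  mode <- match.arg(mode)
  score_mode <- match.arg(score_mode)
  if (is.null(grid)) grid <- data.frame(.point = 1)
  structure(list(figure_tag = figure_tag, grid = grid, n_inits = n_inits,
                 seeds = rep_len(seeds, n_inits), init_scale = init_scale,
                 N = N, mode = mode, score_mode = score_mode,
                 out_dir = out_dir, overrides = list(...)),
            class = "experiment_spec")
}

apply_grid_point <- function(config, row) {
  for (nm in names(row)) {
    val <- row[[nm]]
    if (nm == ".point" || is.na(val)) next
    if (nm == "latency_d") {
      config$kernel <- make_alpha_kernel(config$kernel$tau1,
                                         config$kernel$tau2, val)
      if (config$drift_mode == "truncated")
        config$coeff_table <- coefficient_table(config$stdp, config$kernel,
                                                max_order = config$order)
    } else if (grepl("^f_", nm)) {
      ab <- as.integer(strsplit(sub("^f_", "", nm), ",")[[1]])
      cf <- config$coeff_table$coeffs
      hit <- cf$alpha == ab[1] & cf$beta == ab[2]
      if (any(hit)) cf$f[hit] <- val
      else cf <- rbind(cf, data.frame(alpha = ab[1], beta = ab[2], f = val))
      config$coeff_table <- motif_table(cf, f0 = config$coeff_table$f0)
      config$order <- max(config$order, config$coeff_table$max_order)
    } else if (nm == "w_max") {
      config$w_max <- val
      config$W_max <- config$M * val
    } else if (nm %in% names(config)) {
      config[[nm]] <- val
      if (nm == "mu" || nm == "eta" || nm == "duration") NULL
    }
  }
  config
}

#' Run a sweep experiment
#'
#' Executes every grid point with `n_inits` random initial connectivities,
#' scores the final weights, and returns the raw per-run table together
#' with per-point mean and standard deviation of the score. Failed points
#' are logged and marked, and the run continues.
#'
#' @param spec an \code{"experiment_spec"}.
#' @param verbose print one line per run.
#' @return list with `runs` (one row per simulation: grid point, init seed,
#'   final score, iterations, converged) and `summary` (per-point mean/sd).
#' @export
run_experiment <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  base <- do.call(figure_preset,
                  c(list(tag = spec$figure_tag), spec$overrides))
  runs <- list()
  for (p in seq_len(nrow(spec$grid))) {
    config <- apply_grid_point(base, spec$grid[p, , drop = FALSE])
    for (q in seq_len(spec$n_inits)) {
      seed <- spec$seeds[q]
      res <- tryCatch({
        W0 <- generate_initial_weights(spec$N, config$M, config$w_max,
                                       scale = spec$init_scale, seed = seed)
        config$seed <- seed
        traj <- if (spec$mode == "deterministic")
          run_deterministic(W0, config) else run_stochastic(W0, config)
        sc <- chain_score(traj$final_state, mode = spec$score_mode)
        list(score = sc$score, iterations = traj$iterations,
             converged = isTRUE(traj$converged), failed = FALSE)
      }, error = function(e) {
        warning(sprintf("point %d / seed %d failed: %s", p, seed,
                        conditionMessage(e)))
        list(score = NA_real_, iterations = NA_integer_, converged = NA,
             failed = TRUE)
      })
      if (verbose)
        message(sprintf("point %d seed %d: score %.3f (%s iters)",
                        p, seed, res$score, res$iterations))
      runs[[length(runs) + 1]] <-
        cbind(spec$grid[p, , drop = FALSE],
              data.frame(init_seed = seed, final_score = res$score,
                         iterations = res$iterations,
                         converged = res$converged, failed = res$failed))
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  agg_mean <- tapply(runs$final_score, runs[, 1], mean, na.rm = TRUE)
  agg_sd <- tapply(runs$final_score, runs[, 1], stats::sd, na.rm = TRUE)
  summary <- data.frame(point = names(agg_mean),
                        mean_score = as.numeric(agg_mean),
                        sd_score = as.numeric(agg_sd))
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(runs, file.path(spec$out_dir, "runs.txt"),
                       row.names = FALSE, quote = FALSE)
    utils::write.table(summary, file.path(spec$out_dir, "summary.txt"),
                       row.names = FALSE, quote = FALSE)
  }
  list(runs = runs, summary = summary)
}
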