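#' Sweep growth and information metrics over cell stress
#'
#' Runs the simulation for every combination of strategy, absorption
#' coefficient and seed, at fixed maintenance cost `S`, and collects the
#' metrics per run. Cell stress is `c* = S / k`, so the default grid
#' `k = 1..5` with `S = 1` spans `c*` from 1 down to 0.2. The same seeds are
#' reused across conditions, pairing the replicates.
#'
#' @param k_values absorption coefficients to sweep.
#' @param S maintenance cost held fixed (the division threshold tracks it as
#'   `D = 5 S dt`).
#' @param strategies subset of `"equal"`, `"adaptive"`, `"random_move"`.
#' @param replicates seeds per condition.
#' @param seeds explicit seed vector (defaults to `1:replicates`).
#' @param base a [sim_config()] providing everything not swept.
#' @param binning,min_group_n passed to [compute_metrics()].
#' @return `data.frame` with one row per (strategy, k, seed): `strategy`,
#'   `k`, `c_star`, `seed`, `GT`, `MI_T`, `H_X`, `H_XgY`, `SI`.
#' @seealso [aggregate_sweep()] for replicate means and standard deviations.
#' @export
run_stress_sweep <- function(k_values = c(1, 2, 3, 4, 5), S = 1,
                             strategies = c("equal", "adaptive"),
                             replicates = 5, seeds = seq_len(replicates),
                             base = sim_config(),
                             binning = binning_spec(), min_group_n = 10) {
  rows <- list()
  for (st in strategies) {
    for (k in k_values) {
      cp <- base$cell
      cell <- cell_params(k = k, S = S, Kd = cp$Kd, Rtot = cp$Rtot,
                          vmax = cp$vmax, dt = cp$dt, ell = cp$ell)
      for (s in seeds) {
        cfg <- update_config(base, cell = cell, strategy = st, seed = s)
        m <- compute_metrics(run_simulation(cfg), binning, min_group_n)
        rows[[length(rows) + 1L]] <-
          data.frame(strategy = st, k = k, c_star = m$c_star, seed = s,
                     GT = m$GT, MI_T = m$MI_T, H_X = m$H_X, H_XgY = m$H_XgY,
                     SI = m$SI)
      }
    }
  }
  do.call(rbind, rows)
}

#' Sweep growth and information metrics over sensing noise
#'
#' As [run_stress_sweep()], but varying the Gaussian sensing noise factor
#' `gamma` (the multiplier on the binomial sensing variance) at fixed cell
#' parameters.
#'
#' @param gamma_values noise factors (>= 0) to sweep.
#' @inheritParams run_stress_sweep
#' @return `data.frame` with one row per (strategy, gamma, seed): `strategy`,
#'   `gamma`, `seed`, `GT`, `MI_T`, `H_X`, `H_XgY`, `SI`.
#' @export
run_noise_sweep <- function(gamma_values = c(0.25, 0.5, 1, 2, 4),
                            strategies = c("equal", "adaptive"),
                            replicates = 5, seeds = seq_len(replicates),
                            base = sim_config(),
                            binning = binning_spec(), min_group_n = 10) {
  rows <- list()
  for (st in strategies) {
    for (g in gamma_values) {
      for (s in seeds) {
        cfg <- update_config(base, strategy = st, gamma = g, seed = s)
        m <- compute_metrics(run_simulation(cfg), binning, min_group_n)
        rows[[length(rows) + 1L]] <-
          data.frame(strategy = st, gamma = g, seed = s,
                     GT = m$GT, MI_T = m$MI_T, H_X = m$H_X, H_XgY = m$H_XgY,
                     SI = m$SI)
      }
    }
  }
  do.call(rbind, rows)
}

#' Replicate means and standard deviations of a sweep table
#'
#' @param sweep output of [run_stress_sweep()] or [run_noise_sweep()].
#' @param by grouping columns; defaults to strategy plus whichever of
#'   `c_star` / `gamma` the table carries.
#' @return `data.frame` with `<metric>_mean` and `<metric>_sd` columns per
#'   group.
#' @export
aggregate_sweep <- function(sweep, by = NULL) {
  if (is.null(by))
    by <- intersect(c("strategy", "c_star", "gamma"), names(sweep))
  metrics <- intersect(c("GT", "MI_T", "H_X", "H_XgY", "SI"), names(sweep))
  key <- interaction(sweep[by], drop = TRUE, lex.order = TRUE)
  out <- unique(sweep[by])
  out <- out[order(interaction(out, drop = TRUE, lex.order = TRUE)), ,
             drop = FALSE]
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- as.numeric(tapply(sweep[[m]], key, mean))
    out[[paste0(m, "_sd")]] <- as.numeric(tapply(sweep[[m]], key, stats::sd))
  }
  rownames(out) <- NULL
  out
}
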