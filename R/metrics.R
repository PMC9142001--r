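#' Binning specification for the plug-in estimators
#'
#' `"distinct"` treats every distinct observed value as its own bin, which is
#' exact for the simulator's variables (inputs take at most `N` static field
#' values per channel side; outputs are integer bound counts). `"width"`
#' partitions the observed range into `n_bins` equal-width bins, for use with
#' continuous-valued data.
#'
#' @param mode `"distinct"` or `"width"`.
#' @param n_bins number of equal-width bins (>= 2; `"width"` mode only).
#' @return Object of class `"binning_spec"`.
#' @export
binning_spec <- function(mode = c("distinct", "width"), n_bins = 32L) {
  mode <- match.arg(mode)
  if (mode == "width" && (!is.numeric(n_bins) || n_bins < 2))
    stop("binning_spec: 'n_bins' must be >= 2 for equal-width binning",
         call. = FALSE)
  structure(list(mode = mode, n_bins = as.integer(n_bins)),
            class = "binning_spec")
}

bin_codes <- function(x, spec) {
  if (spec$mode == "distinct") return(match(x, sort(unique(x))))
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  br <- seq(r[1], r[2], length.out = spec$n_bins + 1L)
  pmin(findInterval(x, br, rightmost.closed = TRUE), spec$n_bins)
}

entropy_codes <- function(codes) {
  p <- tabulate(codes)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}

joint_codes <- function(cx, cy) (cx - 1L) * max(cy) + cy

#' Plug-in entropy (bits)
#'
#' Empirical-frequency (plug-in) Shannon entropy of the binned sample, with
#' `0 log 0 = 0`.
#'
#' @param x sample vector (numeric or otherwise discretizable; >= 1 value).
#' @param binning a [binning_spec()].
#' @return Entropy in bits.
#' @export
entropy_bits <- function(x, binning = binning_spec()) {
  if (length(x) < 1L) stop("entropy_bits: empty sample", call. = FALSE)
  entropy_codes(bin_codes(x, binning))
}

#' Plug-in mutual information (bits)
#'
#' Estimated from the empirical joint histogram of the binned pair as
#' `H(X) + H(Y) - H(X,Y)`, clamped at zero. Bounded above by
#' `min(H(X), H(Y))`.
#'
#' @param x,y paired sample vectors of equal length.
#' @param binning a [binning_spec()] applied to each variable.
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(x, y, binning = binning_spec()) {
  if (length(x) != length(y))
    stop("mutual_information: 'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("mutual_information: empty sample", call. = FALSE)
  cx <- bin_codes(x, binning)
  cy <- bin_codes(y, binning)
  max(0, entropy_codes(cx) + entropy_codes(cy) - entropy_codes(joint_codes(cx, cy)))
}

#' Plug-in conditional entropy (bits)
#'
#' `H(X | Y) = H(X, Y) - H(Y)` on the shared empirical histograms, so the
#' identity `H(X) - H(X|Y) = MI(X, Y)` holds to floating-point precision.
#'
#' @inheritParams mutual_information
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(x, y, binning = binning_spec()) {
  if (length(x) != length(y))
    stop("conditional_entropy: 'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("conditional_entropy: empty sample", call. = FALSE)
  cx <- bin_codes(x, binning)
  cy <- bin_codes(y, binning)
  entropy_codes(joint_codes(cx, cy)) - entropy_codes(cy)
}

# Map each channel-log row to its estimation group. Samples are pooled by
# receptor-allocation key (atot); keys with fewer than min_group_n samples are
# merged into the nearest well-populated key (plug-in MI on tiny groups is
# badly biased). If no key is well populated, everything pools into the
# largest one.
channel_groups <- function(atot, min_group_n) {
  keys <- sort(unique(atot))
  cnt <- tabulate(match(atot, keys), length(keys))
  big <- keys[cnt >= min_group_n]
  if (length(big) == 0L) big <- keys[which.max(cnt)]
  map <- vapply(keys, function(k) big[which.min(abs(big - k))], numeric(1))
  map[match(atot, keys)]
}

channel_pairs <- list(AR = c("in_ar", "out_ar"), AL = c("in_al", "out_al"),
                      BR = c("in_br", "out_br"), BL = c("in_bl", "out_bl"))

#' Per-allocation-group channel information
#'
#' Pools the sensing samples of all cells sharing a receptor-allocation key
#' and estimates, per group, the four per-channel mutual informations, their
#' sum (the per-cell MI), and the summed input and conditional entropies.
#' Every cell's per-cell MI is *its group's* estimate: cells operating an
#' identical sensing channel are assigned an identical value, which is what
#' makes the across-population spread ([subjective_information()]) exactly
#' zero for the equal-allocation strategy.
#'
#' @param channels a channel log (`sim$channels` from [run_simulation()]):
#'   columns `t`, `atot`, `in_ar`, `out_ar`, ..., `in_bl`, `out_bl`.
#' @param binning a [binning_spec()].
#' @param min_group_n minimum samples per allocation key; sparser keys are
#'   merged into the nearest well-populated key.
#' @return `data.frame` with one row per group: `group` (allocation key),
#'   `n` (samples), `mi_ar`, `mi_al`, `mi_br`, `mi_bl`, `mi_cell`, `h_x`,
#'   `h_xgy`.
#' @export
channel_mi <- function(channels, binning = binning_spec(), min_group_n = 10) {
  check_channels(channels)
  grp <- channel_groups(channels$atot, min_group_n)
  keys <- sort(unique(grp))
  rows <- lapply(keys, function(g) {
    sub <- channels[grp == g, , drop = FALSE]
    mi <- hx <- ce <- numeric(4)
    for (i in seq_along(channel_pairs)) {
      x <- sub[[channel_pairs[[i]][1]]]
      y <- sub[[channel_pairs[[i]][2]]]
      mi[i] <- mutual_information(x, y, binning)
      hx[i] <- entropy_bits(x, binning)
      ce[i] <- conditional_entropy(x, y, binning)
    }
    data.frame(group = g, n = nrow(sub),
               mi_ar = mi[1], mi_al = mi[2], mi_br = mi[3], mi_bl = mi[4],
               mi_cell = sum(mi), h_x = sum(hx), h_xgy = sum(ce))
  })
  do.call(rbind, rows)
}

check_channels <- function(channels) {
  need <- c("t", "atot", unlist(channel_pairs, use.names = FALSE))
  if (is.null(channels) || nrow(channels) == 0L)
    stop("empty channel log", call. = FALSE)
  if (!all(need %in% names(channels)))
    stop("channel log is missing required columns", call. = FALSE)
  invisible(channels)
}

#' Per-cell MI for one allocation key
#'
#' @inheritParams channel_mi
#' @param allocation an allocation key (`atot` value) present in the log.
#' @return The per-cell MI (bits) of the group containing that key: the sum
#'   of the four per-channel MI estimates over the pooled samples.
#' @export
mi_cell <- function(channels, allocation, binning = binning_spec(),
                    min_group_n = 10) {
  check_channels(channels)
  if (!allocation %in% channels$atot)
    stop("mi_cell: no samples with that allocation key", call. = FALSE)
  grp <- channel_groups(channels$atot, min_group_n)
  g <- grp[match(allocation, channels$atot)]
  tab <- channel_mi(channels, binning, min_group_n)
  tab$mi_cell[tab$group == g]
}

# Per-row (cell, t) metric values: each row inherits its group's estimates.
per_row_metrics <- function(channels, binning, min_group_n) {
  grp <- channel_groups(channels$atot, min_group_n)
  tab <- channel_mi(channels, binning, min_group_n)
  i <- match(grp, tab$group)
  list(mi = tab$mi_cell[i], h_x = tab$h_x[i], h_xgy = tab$h_xgy[i],
       t = channels$t, table = tab)
}

#' Population-and-time average per-cell MI
#'
#' Averages the per-cell MI over every (cell, time-step) occurrence in the
#' log, weighting each occurrence equally.
#'
#' @inheritParams channel_mi
#' @return MI(T) in bits.
#' @export
mi_average <- function(channels, binning = binning_spec(), min_group_n = 10) {
  check_channels(channels)
  mean(per_row_metrics(channels, binning, min_group_n)$mi)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Subjective information
#'
#' At each time step, the population standard deviation (divisor `n`) of the
#' per-cell MI across the cells present; subjective information is the time
#' average of these spreads. A population in which every cell operates the
#' same sensing channel (the equal-allocation strategy: a single allocation
#' group) has subjective information exactly zero; heterogeneous channel
#' tuning across individuals makes it positive. Steps with fewer than two
#' cells contribute zero spread.
#'
#' @inheritParams channel_mi
#' @return Subjective information in bits (>= 0).
#' @export
subjective_information <- function(channels, binning = binning_spec(),
                                   min_group_n = 10) {
  check_channels(channels)
  pr <- per_row_metrics(channels, binning, min_group_n)
  sds <- vapply(split(pr$mi, pr$t),
                function(v) if (length(v) < 2L) 0 else pop_sd(v), numeric(1))
  mean(sds)
}

#' Population growth rate (log2 doublings per step)
#'
#' Mean over the retained steps of `log2(P[j+1] / P[j])`, where `P` is the
#' real population count series (environment cells times the capping
#' multiplier). Invariant to rescaling all counts by a constant, so the
#' capping bookkeeping cannot bias it.
#'
#' @param counts population series `P_0, ..., P_J` (length >= 2).
#' @param transient number of initial ratios to discard.
#' @param dt duration of one step; the default 1 reports per-step growth.
#' @return Growth rate in bits per unit time, or `NA_real_` if the population
#'   hits zero inside the evaluated window (extinction: growth undefined).
#' @export
growth_rate <- function(counts, transient = 0, dt = 1) {
  if (!is.numeric(counts) || length(counts) < 2L)
    stop("growth_rate: need a numeric series of length >= 2", call. = FALSE)
  r <- log2(counts[-1L] / counts[-length(counts)])
  if (transient < 0 || transient >= length(r))
    stop("growth_rate: 'transient' must leave at least one ratio", call. = FALSE)
  r <- r[(transient + 1L):length(r)]
  if (any(!is.finite(r))) return(NA_real_)
  mean(r) / dt
}

#' Cell stress
#'
#' The ratio `S / k` of maintenance cost to absorption coefficient: the
#' break-even ambient concentration below which a cell loses that substrate.
#'
#' @param S basal metabolic cost (molecules per step).
#' @param k absorption coefficient (> 0).
#' @return `S / k` (concentration units).
#' @export
cell_stress <- function(S, k) {
  if (!is.numeric(k) || any(k <= 0))
    stop("cell_stress: 'k' must be > 0", call. = FALSE)
  S / k
}

#' Compute all run metrics
#'
#' Assembles the metrics report for one simulation: growth rate from the
#' real-count series, and the information metrics (average per-cell MI, input
#' and conditional entropies, subjective information) from the sensing
#' channel log, all evaluated after discarding the configured initial
#' transient.
#'
#' @param sim a `forage_sim` from [run_simulation()].
#' @param binning a [binning_spec()].
#' @param min_group_n minimum samples per allocation group (see
#'   [channel_mi()]).
#' @param transient number of initial steps to discard; defaults to the
#'   run's configured transient window.
#' @return Object of class `"metrics_report"`: `GT`, `MI_T`, `H_X`, `H_XgY`,
#'   `SI`, `c_star`, `n_steps_used`, the per-step spread series
#'   (`si_series`), and the per-group information table (`groups`).
#'   Information fields are `NA` when the run recorded no channels.
#' @export
compute_metrics <- function(sim, binning = binning_spec(), min_group_n = 10,
                            transient = NULL) {
  stopifnot(inherits(sim, "forage_sim"))
  if (is.null(transient)) transient <- sim$transient_steps
  GT <- growth_rate(sim$real_counts, transient = transient, dt = sim$config$cell$dt)
  MI_T <- H_X <- H_XgY <- SI <- NA_real_
  si_series <- NULL
  groups <- NULL
  ch <- sim$channels
  if (!is.null(ch)) {
    ch <- ch[ch$t > transient, , drop = FALSE]
    if (nrow(ch) > 0L) {
      pr <- per_row_metrics(ch, binning, min_group_n)
      MI_T <- mean(pr$mi)
      H_X <- mean(pr$h_x)
      H_XgY <- mean(pr$h_xgy)
      sds <- vapply(split(pr$mi, pr$t),
                    function(v) if (length(v) < 2L) 0 else pop_sd(v), numeric(1))
      SI <- mean(sds)
      si_series <- data.frame(t = as.integer(names(sds)), si = unname(sds))
      groups <- pr$table
    }
  }
  structure(list(GT = GT, MI_T = MI_T, H_X = H_X, H_XgY = H_XgY, SI = SI,
                 c_star = cell_stress(sim$config$cell$S, sim$config$cell$k),
                 n_steps_used = sim$config$steps - transient,
                 binning = binning, min_group_n = min_group_n,
                 si_series = si_series, groups = groups),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Foraging run metrics (transient discarded):\n")
  cat(sprintf("  growth rate G_T : %s bits/step\n", format(x$GT, digits = 4)))
  cat(sprintf("  MI(T)           : %s bits\n", format(x$MI_T, digits = 4)))
  cat(sprintf("  H(X) / H(X|Y)   : %s / %s bits\n",
              format(x$H_X, digits = 4), format(x$H_XgY, digits = 4)))
  cat(sprintf("  subjective info : %s bits\n", format(x$SI, digits = 4)))
  cat(sprintf("  cell stress c*  : %s   (steps used: %d)\n",
              format(x$c_star, digits = 4), x$n_steps_used))
  invisible(x)
}
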