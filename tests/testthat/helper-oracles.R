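# Fixtures and independent oracles used across the suite.

# Flat environment with the given concentrations (kappa = 0 makes the von
# Mises density uniform, so the per-site value is Cmax / L).
uniform_env <- function(concA, concB = concA, N = 100, L = N) {
  environment_field(
    field_params(Cmax = concA * L, mu = 0, kappa = 0, L = L, N = N),
    field_params(Cmax = concB * L, mu = 0, kappa = 0, L = L, N = N))
}

make_cells <- function(site, Ain = 0, Bin = 0, Atot = 200, Btot = 400 - Atot) {
  data.frame(site = as.integer(site), Ain = Ain, Bin = Bin,
             Atot = Atot, Btot = Btot)
}

# Independent MI oracle: direct double sum over a joint probability (or
# count) matrix. Never calls the package's estimator path.
mi_from_joint <- function(P) {
  P <- P / sum(P)
  px <- rowSums(P)
  py <- colSums(P)
  s <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) s <- s + P[i, j] * log2(P[i, j] / (px[i] * py[j]))
    }
  }
  as.numeric(s)
}

# Exact joint of the analytic test channel: X ~ uniform{0,1},
# Y | X = x ~ Binomial(n, if x = 0 then p0 else p1).
binom_channel_joint <- function(n, p0, p1) {
  rbind(0.5 * dbinom(0:n, n, p0), 0.5 * dbinom(0:n, n, p1))
}

# Small default run configuration for unit tests (kept light on purpose).
small_config <- function(...) {
  args <- list(steps = 12, cell_max = 600, cell_adjusted = 450, seed = 7)
  repl <- list(...)
  args[names(repl)] <- repl
  do.call(sim_config, args)
}
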