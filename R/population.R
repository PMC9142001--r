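#' Simulation configuration
#'
#' Collects everything a run needs: cell parameters, the two substrate
#' fields, the behavioral strategy, run length, seeding, and the population
#' capping scheme. Capping keeps the number of *environment* cells tractable:
#' whenever it strictly exceeds `cell_max` after a step, cells are removed
#' uniformly at random down to `cell_adjusted` (which preserves the spatial
#' distribution in expectation) and the running multiplier `cellmulti` is
#' scaled by `count_before / cell_adjusted`, so the *real* population count
#' `n_env * cellmulti` keeps tracking the uncapped process.
#'
#' @param cell a [cell_params()].
#' @param field_A,field_B [field_params()] for the two substrates.
#' @param strategy `"equal"`, `"adaptive"`, or `"random_move"` (chemotaxis
#'   replaced by a uniform integer displacement in `[-vmax, vmax]`; receptor
#'   allocation stays equal).
#' @param gamma `NULL` for binomial sensing, or a noise factor >= 0 to use
#'   the Gaussian sensing channel ([sense_gaussian()]).
#' @param steps number of time steps (>= 1).
#' @param init_positions `"one-per-site"` (one founder cell on every lattice
#'   site) or a vector of 1-based site indices in `[1, N]` (converted to the
#'   0-based internal convention).
#' @param init_stores length-2 numeric, initial `(Ain, Bin)`.
#' @param cell_max hard cap on environment cells.
#' @param cell_adjusted post-cap target (< `cell_max`).
#' @param transient_frac fraction of the run flagged as initial transient and
#'   discarded by the metrics (default one third).
#' @param record_channels keep the per-cell sensing samples needed for the
#'   information metrics (disable for growth-only runs to save memory).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(cell = cell_params(),
                       field_A = field_params(mu = 25),
                       field_B = field_params(mu = 75),
                       strategy = c("equal", "adaptive", "random_move"),
                       gamma = NULL,
                       steps = 31,
                       init_positions = "one-per-site",
                       init_stores = c(0, 0),
                       cell_max = 10000,
                       cell_adjusted = 9000,
                       transient_frac = 1 / 3,
                       record_channels = TRUE,
                       seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cell, "cell_params"),
            inherits(field_A, "field_params"),
            inherits(field_B, "field_params"))
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1 || steps != round(steps))
    stop("sim_config: 'steps' must be a positive integer", call. = FALSE)
  if (!is.null(gamma) &&
      (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0))
    stop("sim_config: 'gamma' must be NULL or a scalar >= 0", call. = FALSE)
  if (cell_adjusted >= cell_max)
    stop("sim_config: 'cell_adjusted' must be below 'cell_max'", call. = FALSE)
  if (!is.numeric(transient_frac) || transient_frac < 0 || transient_frac >= 1)
    stop("sim_config: 'transient_frac' must be in [0, 1)", call. = FALSE)
  N <- field_A$N
  if (identical(init_positions, "one-per-site")) {
    positions <- seq_len(N)
  } else {
    positions <- init_positions
    if (!is.numeric(positions) || length(positions) < 1L ||
        any(positions < 1) || any(positions > N) || any(positions != round(positions)))
      stop("sim_config: 'init_positions' must be \"one-per-site\" or 1-based sites in [1, N]",
           call. = FALSE)
  }
  if (strategy == "random_move" && !is.finite(cell$vmax))
    stop("sim_config: random_move requires a finite vmax", call. = FALSE)
  stopifnot(length(init_stores) == 2L, all(init_stores >= 0))
  structure(list(cell = cell, field_A = field_A, field_B = field_B,
                 strategy = strategy, gamma = gamma, steps = as.integer(steps),
                 init_positions = as.integer(positions),
                 init_stores = as.numeric(init_stores),
                 cell_max = cell_max, cell_adjusted = cell_adjusted,
                 transient_frac = transient_frac,
                 record_channels = isTRUE(record_channels),
                 seed = seed),
            class = "sim_config")
}

#' Modify a simulation configuration
#'
#' Rebuilds the configuration through [sim_config()] so all validation
#' re-runs.
#'
#' @param config a `sim_config`.
#' @param ... named [sim_config()] arguments to replace.
#' @return A new `sim_config`.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  args <- list(cell = config$cell, field_A = config$field_A,
               field_B = config$field_B, strategy = config$strategy,
               gamma = config$gamma, steps = config$steps,
               init_positions = config$init_positions,
               init_stores = config$init_stores,
               cell_max = config$cell_max, cell_adjusted = config$cell_adjusted,
               transient_frac = config$transient_frac,
               record_channels = config$record_channels, seed = config$seed)
  repl <- list(...)
  args[names(repl)] <- repl
  do.call(sim_config, args)
}

#' Seed the population
#'
#' Founder cells are placed at the configured positions with the configured
#' initial stores, an equal receptor split, and capping multiplier 1.
#'
#' @param config a [sim_config()].
#' @param field the realized [environment_field()].
#' @return Object of class `"population_state"`: list of the cell table
#'   (`cells`), the real-count multiplier (`cellmulti`) and the step counter
#'   (`t`).
#' @export
initialize_population <- function(config, field) {
  cells <- cell_states(site = config$init_positions - 1L,
                       Ain = config$init_stores[1],
                       Bin = config$init_stores[2],
                       params = config$cell)
  structure(list(cells = cells, cellmulti = 1, t = 0L),
            class = "population_state")
}

#' Apply the population cap
#'
#' If the environment cell count strictly exceeds `cell_max`, cells are
#' subsampled uniformly without replacement down to `cell_adjusted` and the
#' multiplier is scaled by `count_before / cell_adjusted`, keeping the real
#' count `n * cellmulti` unchanged.
#'
#' @param pop a `population_state`.
#' @param config a [sim_config()].
#' @return The (possibly reduced) `population_state`.
#' @export
apply_cap <- function(pop, config) {
  n <- nrow(pop$cells)
  if (n > config$cell_max) {
    keep <- sample.int(n, config$cell_adjusted)
    pop$cells <- pop$cells[keep, , drop = FALSE]
    rownames(pop$cells) <- NULL
    pop$cellmulti <- pop$cellmulti * (n / config$cell_adjusted)
  }
  pop
}

#' Advance the population by one time step
#'
#' Every living cell runs the per-step state machine in fixed order:
#' absorb, sense, move (or a uniform random displacement under the
#' `random_move` strategy), reallocate, assess. Dead cells are removed,
#' daughters appended (they first act next step), then the cap is applied.
#' Because cells do not interact, the fixed update order does not change the
#' law of the process; it guarantees bit-reproducibility under a fixed seed.
#'
#' @param pop a `population_state`.
#' @param config a [sim_config()].
#' @param field the [environment_field()].
#' @param t step index (1-based), recorded in the outputs.
#' @return List: `pop` (updated state), `record` (one-row data.frame),
#'   `channels` (sensing samples, or `NULL`), `site_counts` and `div_counts`
#'   (length-`N` tallies of cell and division locations this step).
#' @export
step_population <- function(pop, config, field, t) {
  cp <- config$cell
  N <- field$N
  n0 <- nrow(pop$cells)
  empty_rec <- data.frame(t = t, n_env = 0L, cellmulti = pop$cellmulti,
                          real_count = 0, divisions = 0L, deaths = 0L,
                          capped = FALSE)
  if (n0 == 0L) {  # extinction is absorbing
    return(list(pop = pop, record = empty_rec, channels = NULL,
                site_counts = numeric(N), div_counts = numeric(N)))
  }
  cells <- absorb(pop$cells, field, cp)
  sense <- if (is.null(config$gamma)) sense_binomial(cells, field, cp)
           else sense_gaussian(cells, field, cp, config$gamma)
  channels <- NULL
  if (config$record_channels) {
    channels <- data.frame(t = t, atot = cells$Atot,
                           in_ar = sense$AR, out_ar = sense$AR_star,
                           in_al = sense$AL, out_al = sense$AL_star,
                           in_br = sense$BR, out_br = sense$BR_star,
                           in_bl = sense$BL, out_bl = sense$BL_star)
  }
  if (config$strategy == "random_move") {
    di <- sample(seq.int(-cp$vmax, cp$vmax), n0, replace = TRUE)
    cells$site <- (cells$site + di) %% N
  } else {
    cells <- move_cells(cells, sense, cp, field)
  }
  alloc <- if (config$strategy == "adaptive") "adaptive" else "equal"
  cells <- reallocate(cells, alloc, cp)
  verdict <- assess_cells(cells, cp)
  died <- verdict == "die"
  dividing <- verdict == "divide"
  div_counts <- tabulate(cells$site[dividing] + 1L, N)
  deaths <- sum(died)
  divisions <- sum(dividing)
  cells <- cells[!died, , drop = FALSE]
  cells <- divide_cells(cells, which(dividing[!died]))
  site_counts <- tabulate(cells$site + 1L, N)
  pop$cells <- cells
  n_before_cap <- nrow(cells)
  pop <- apply_cap(pop, config)
  pop$t <- t
  rec <- data.frame(t = t, n_env = nrow(pop$cells), cellmulti = pop$cellmulti,
                    real_count = nrow(pop$cells) * pop$cellmulti,
                    divisions = divisions, deaths = deaths,
                    capped = n_before_cap > config$cell_max)
  list(pop = pop, record = rec, channels = channels,
       site_counts = site_counts, div_counts = div_counts)
}

#' Run a full population simulation
#'
#' Executes `config$steps` cycles of the state machine from the configured
#' initial condition, collecting per-step records, per-site density tallies,
#' the real-count series used by [growth_rate()], and (optionally) the
#' per-cell sensing channel log consumed by the information metrics.
#'
#' @param config a [sim_config()].
#' @return Object of class `"forage_sim"`: list with `config`, `field`,
#'   `steps` (one row per step: `t`, `n_env`, `cellmulti`, `real_count`,
#'   `divisions`, `deaths`, `capped`, `transient`), `channels` (sensing log:
#'   `t`, `atot`, and input/output pairs for the four channels; `NULL` if not
#'   recorded), `density` (per-site cumulative cell and division counts),
#'   `real_counts` (length `steps + 1`, starting at the founder count),
#'   `transient_steps`, and the final cell table.
#' @examples
#' cfg <- sim_config(steps = 10, cell_max = 500, cell_adjusted = 400, seed = 1)
#' sim <- run_simulation(cfg)
#' sim$steps[1:3, c("t", "n_env", "real_count", "divisions", "deaths")]
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  field <- environment_field(config$field_A, config$field_B)
  pop <- initialize_population(config, field)
  N <- field$N
  n_steps <- config$steps
  transient_steps <- floor(n_steps * config$transient_frac)
  real_counts <- numeric(n_steps + 1)
  real_counts[1] <- nrow(pop$cells)
  cell_density <- numeric(N)
  division_density <- numeric(N)
  recs <- vector("list", n_steps)
  chans <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    out <- step_population(pop, config, field, t)
    pop <- out$pop
    recs[[t]] <- out$record
    chans[[t]] <- out$channels
    cell_density <- cell_density + out$site_counts
    division_density <- division_density + out$div_counts
    real_counts[t + 1] <- out$record$real_count
  }
  steps <- do.call(rbind, recs)
  steps$transient <- steps$t <= transient_steps
  channels <- if (config$record_channels) do.call(rbind, chans) else NULL
  structure(list(config = config, field = field, steps = steps,
                 channels = channels,
                 density = data.frame(site = seq_len(N) - 1L,
                                      cell_density = cell_density,
                                      division_density = division_density),
                 real_counts = real_counts,
                 transient_steps = transient_steps,
                 final_cells = pop$cells,
                 cellmulti = pop$cellmulti),
            class = "forage_sim")
}

#' @export
print.forage_sim <- function(x, ...) {
  n <- length(x$real_counts)
  cat(sprintf("Two-substrate foraging simulation: %d steps, strategy '%s'%s\n",
              x$config$steps, x$config$strategy,
              if (is.null(x$config$gamma)) ""
              else sprintf(" (gaussian sensing, gamma=%g)", x$config$gamma)))
  cat(sprintf("  founders: %d   final real count: %.5g (env cells %d x multiplier %.4g)\n",
              length(x$config$init_positions), x$real_counts[n],
              nrow(x$final_cells), x$cellmulti))
  cat(sprintf("  divisions: %d   deaths: %d   capped steps: %d\n",
              sum(x$steps$divisions), sum(x$steps$deaths), sum(x$steps$capped)))
  invisible(x)
}
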