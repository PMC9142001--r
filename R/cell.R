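#' Per-cell model parameters
#'
#' @param k absorption coefficient (molecules absorbed per unit concentration
#'   per time step, > 0).
#' @param S basal metabolic maintenance cost (molecules consumed per substrate
#'   per time step, > 0 unless `S = 0` for stress-free runs).
#' @param Kd receptor dissociation constant (concentration units, > 0): a
#'   receptor facing concentration `C` is bound with probability
#'   `C / (Kd + C)`.
#' @param Rtot total receptor budget per cell (even integer, > 0), split
#'   between A-specific and B-specific receptor types.
#' @param vmax maximum displacement per time step (sites; may be `Inf`).
#' @param dt time step (the model is formulated for `dt = 1`).
#' @param D division threshold (molecules): a cell divides when both internal
#'   stores strictly exceed `D`. Defaults to `5 * S * dt`, the reserve needed
#'   to survive five maintenance steps.
#' @param ell cell length (sites, even; the two ends of a cell at site `x`
#'   are `x - ell/2` and `x + ell/2`).
#' @return Object of class `"cell_params"`.
#' @export
cell_params <- function(k = 1, S = 1, Kd = 2, Rtot = 400, vmax = 10,
                        dt = 1, D = 5 * S * dt, ell = 2) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0,
            is.numeric(S), length(S) == 1L, S >= 0,
            is.numeric(Kd), length(Kd) == 1L, Kd > 0,
            is.numeric(Rtot), length(Rtot) == 1L, Rtot >= 0,
            is.numeric(vmax), length(vmax) == 1L, vmax > 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(D), length(D) == 1L, D > 0,
            is.numeric(ell), length(ell) == 1L, ell > 0)
  if (Rtot %% 2 != 0) stop("cell_params: 'Rtot' must be even", call. = FALSE)
  if (ell %% 2 != 0) stop("cell_params: 'ell' must be even", call. = FALSE)
  structure(list(k = k, S = S, Kd = Kd, Rtot = Rtot, vmax = vmax,
                 dt = dt, D = D, ell = ell),
            class = "cell_params")
}

#' Construct a table of cell states
#'
#' Cells are represented as rows of a data frame with columns `site` (0-based
#' lattice position), `Ain`, `Bin` (internal stores, real-valued, >= 0) and
#' `Atot`, `Btot` (integer receptor counts summing to `Rtot`). All per-step
#' operations ([absorb()], [sense_binomial()], [move_cells()], ...) are
#' vectorized over the rows.
#'
#' @param site 0-based site index (vector).
#' @param Ain,Bin initial internal stores (recycled).
#' @param Atot,Btot receptor allocation (recycled; default equal split).
#' @param params a [cell_params()] (used for the default allocation).
#' @return `data.frame` with one row per cell.
#' @export
cell_states <- function(site, Ain = 0, Bin = 0, params = cell_params(),
                        Atot = params$Rtot / 2, Btot = params$Rtot - Atot) {
  df <- data.frame(site = as.integer(site), Ain = Ain, Bin = Bin,
                   Atot = Atot, Btot = Btot)
  if (any(df$Atot + df$Btot != params$Rtot))
    stop("cell_states: Atot + Btot must equal Rtot", call. = FALSE)
  if (any(df$Ain < 0) || any(df$Bin < 0))
    stop("cell_states: stores must be non-negative", call. = FALSE)
  df
}

#' Absorb substrates from the environment
#'
#' Each cell gains `(k * (C(left) + C(right)) / 2 - S) * dt` molecules of each
#' substrate, where `left`/`right` are the sites at the cell's two ends
#' (`site -/+ ell/2`). A store driven negative is clamped to zero
#' independently; death is assessed later by [assess_cells()].
#'
#' @param cells cell table ([cell_states()]).
#' @param field an [environment_field()].
#' @param params a [cell_params()].
#' @return The cell table with updated `Ain`, `Bin`.
#' @export
absorb <- function(cells, field, params) {
  h <- params$ell / 2
  dA <- (params$k * (concentration_at(field, "A", cells$site - h) +
                     concentration_at(field, "A", cells$site + h)) / 2 -
           params$S) * params$dt
  dB <- (params$k * (concentration_at(field, "B", cells$site - h) +
                     concentration_at(field, "B", cells$site + h)) / 2 -
           params$S) * params$dt
  cells$Ain <- pmax(cells$Ain + dA, 0)
  cells$Bin <- pmax(cells$Bin + dB, 0)
  cells
}

# Side budgets: receptors of one type are split between the two ends of the
# cell; floor on the left, remainder on the right, so the total is conserved
# even for odd allocations.
side_budgets <- function(tot) {
  lo <- floor(tot / 2)
  list(left = lo, right = tot - lo)
}

bind_prob <- function(conc, Kd) conc / (Kd + conc)

sense_inputs <- function(cells, field, params) {
  h <- params$ell / 2
  list(AR = concentration_at(field, "A", cells$site + h),
       AL = concentration_at(field, "A", cells$site - h),
       BR = concentration_at(field, "B", cells$site + h),
       BL = concentration_at(field, "B", cells$site - h))
}

#' Sense concentrations through binomial receptor binding
#'
#' The bound-receptor count on each end of the cell is a binomial sample: the
#' number of trials is the side's receptor budget (half the cell's receptors
#' of that type) and the success probability is the Hill-type occupancy
#' `C / (Kd + C)` at that end. The four channels (A-right, A-left, B-right,
#' B-left) are drawn independently.
#'
#' @inheritParams absorb
#' @return `data.frame` with the bound counts `AR_star`, `AL_star`, `BR_star`,
#'   `BL_star` and the input concentrations `AR`, `AL`, `BR`, `BL` used.
#' @export
sense_binomial <- function(cells, field, params) {
  n <- nrow(cells)
  inp <- sense_inputs(cells, field, params)
  a <- side_budgets(cells$Atot)
  b <- side_budgets(cells$Btot)
  data.frame(
    AR_star = stats::rbinom(n, a$right, bind_prob(inp$AR, params$Kd)),
    AL_star = stats::rbinom(n, a$left,  bind_prob(inp$AL, params$Kd)),
    BR_star = stats::rbinom(n, b$right, bind_prob(inp$BR, params$Kd)),
    BL_star = stats::rbinom(n, b$left,  bind_prob(inp$BL, params$Kd)),
    AR = inp$AR, AL = inp$AL, BR = inp$BR, BL = inp$BL)
}

#' Sense with Gaussian receptor noise of tunable magnitude
#'
#' Variant sensing channel used for noise sweeps: each bound count is drawn
#' from a normal distribution with the binomial mean `n p` and variance
#' `n p (1 - p) * gamma`, then rounded to the nearest integer and clipped to
#' `[0, n]`. `gamma = 1` reproduces the binomial's first two moments;
#' `gamma = 0` is a deterministic channel.
#'
#' @inheritParams absorb
#' @param gamma noise factor (>= 0), the ratio of the Gaussian variance to
#'   the matching binomial variance.
#' @return As [sense_binomial()].
#' @export
sense_gaussian <- function(cells, field, params, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop("sense_gaussian: 'gamma' must be a finite scalar >= 0", call. = FALSE)
  n <- nrow(cells)
  inp <- sense_inputs(cells, field, params)
  a <- side_budgets(cells$Atot)
  b <- side_budgets(cells$Btot)
  draw <- function(size, p) {
    m <- size * p
    sd <- sqrt(size * p * (1 - p) * gamma)
    pmin(pmax(round(stats::rnorm(n, m, sd)), 0), size)
  }
  data.frame(
    AR_star = draw(a$right, bind_prob(inp$AR, params$Kd)),
    AL_star = draw(a$left,  bind_prob(inp$AL, params$Kd)),
    BR_star = draw(b$right, bind_prob(inp$BR, params$Kd)),
    BL_star = draw(b$left,  bind_prob(inp$BL, params$Kd)),
    AR = inp$AR, AL = inp$AL, BR = inp$BR, BL = inp$BL)
}

#' Move cells along the estimated gradient
#'
#' The displacement is the right-minus-left excess of bound receptors,
#' `psi = AR* + BR* - AL* - BL*`, clipped to `[-vmax, vmax]`; positions wrap
#' around the ring. With `vmax = Inf` the displacement is `psi` itself.
#'
#' @inheritParams absorb
#' @param sense result of [sense_binomial()] or [sense_gaussian()].
#' @return The cell table with updated `site`.
#' @export
move_cells <- function(cells, sense, params, field) {
  psi <- sense$AR_star + sense$BR_star - sense$AL_star - sense$BL_star
  di <- pmin(pmax(psi, -params$vmax), params$vmax)
  cells$site <- (cells$site + di) %% field$N
  cells
}

#' Re-apportion the receptor budget between substrate types
#'
#' Under the `"equal"` strategy every cell keeps `Atot = Btot = Rtot / 2`.
#' Under the `"adaptive"` strategy a cell shifts receptors toward its scarcer
#' resource: `Btot = round(Rtot * Ain / (Ain + Bin))` (a relative surplus of A
#' inside means B is the bottleneck, so B receptors grow), `Atot = Rtot -
#' Btot`. A cell with both stores empty splits equally, the unbiased choice
#' for an uninformative state.
#'
#' @inheritParams absorb
#' @param strategy `"equal"` or `"adaptive"`.
#' @return The cell table with updated `Atot`, `Btot` (integers summing to
#'   `Rtot`).
#' @export
reallocate <- function(cells, strategy = c("equal", "adaptive"), params) {
  strategy <- match.arg(strategy)
  half <- params$Rtot / 2
  if (strategy == "equal") {
    cells$Atot <- rep(half, nrow(cells))
    cells$Btot <- rep(half, nrow(cells))
  } else {
    tot <- cells$Ain + cells$Bin
    btot <- ifelse(tot > 0, round(params$Rtot * cells$Ain / tot), half)
    cells$Btot <- btot
    cells$Atot <- params$Rtot - btot
  }
  cells
}

#' Assess division and death
#'
#' A cell dies when either internal store has hit zero; otherwise it divides
#' when both stores strictly exceed the threshold `D`; otherwise it continues.
#' Death takes precedence over division (vacuously, since `D > 0`).
#'
#' @inheritParams absorb
#' @return Character vector of verdicts: `"die"`, `"divide"` or `"continue"`.
#' @export
assess_cells <- function(cells, params) {
  ifelse(cells$Ain == 0 | cells$Bin == 0, "die",
         ifelse(cells$Ain > params$D & cells$Bin > params$D, "divide",
                "continue"))
}

#' Divide cells
#'
#' Each dividing mother is replaced by two daughters at the same site, each
#' holding half of the mother's (real-valued) stores and a copy of her
#' receptor allocation. Daughter rows are appended at the end of the table and
#' first act in the next time step.
#'
#' @param cells cell table.
#' @param idx row indices of the dividing cells.
#' @return The enlarged cell table.
#' @export
divide_cells <- function(cells, idx) {
  if (length(idx) == 0L) return(cells)
  cells$Ain[idx] <- cells$Ain[idx] / 2
  cells$Bin[idx] <- cells$Bin[idx] / 2
  out <- rbind(cells, cells[idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}
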