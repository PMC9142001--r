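#' Parameters of a von Mises substrate field
#'
#' The environment is a one-dimensional ring of circumference `L` sampled at
#' `N` equally spaced lattice sites (spacing `L/N`; the defaults use spacing
#' 1). A substrate is laid out as a von Mises density scaled by `Cmax`: the
#' concentration at the site with coordinate \eqn{x_i = iL/N} (0-based) is
#' \deqn{C_i = \frac{C_{max}\,\exp\{\kappa \cos(2\pi (x_i - \mu)/L)\}}
#'             {L\, I_0(\kappa)},}
#' where \eqn{I_0} is the modified Bessel function of the first kind of order
#' zero. The density integrates to 1 around the ring, so the field sums to
#' approximately `Cmax` over the sites; the peak sits at the site closest to
#' `mu`. With `kappa = 0` the field is flat at `Cmax / L`. The von Mises form
#' is the maximum-entropy distribution on a periodic support for a given
#' circular mean and variance, which makes it the least-committal way to give
#' the cells a gradient to climb.
#'
#' @param Cmax peak-scaling concentration (molecules per site, > 0). The
#'   field's ring total is ~`Cmax`.
#' @param mu circular mean (lattice units, in `[0, L)`): location of the peak.
#' @param kappa von Mises concentration parameter (dimensionless, >= 0);
#'   larger values sharpen the peak.
#' @param L ring circumference (lattice units, > 0).
#' @param N number of lattice sites (integer >= 2).
#' @return An object of class `"field_params"`.
#' @seealso [build_field()], [environment_field()]
#' @examples
#' p <- field_params(Cmax = 500, mu = 25, kappa = 0.1)
#' f <- build_field(p)
#' which.max(f) - 1  # 0-based site of the peak: 25
#' @export
field_params <- function(Cmax = 500, mu = 25, kappa = 0.1, L = 100, N = 100) {
  check_scalar(Cmax, "Cmax")
  check_scalar(mu, "mu")
  check_scalar(kappa, "kappa")
  check_scalar(L, "L")
  check_scalar(N, "N")
  if (Cmax <= 0) stop("field_params: 'Cmax' must be > 0", call. = FALSE)
  if (kappa < 0) stop("field_params: 'kappa' must be >= 0", call. = FALSE)
  if (L <= 0) stop("field_params: 'L' must be > 0", call. = FALSE)
  if (mu < 0 || mu >= L) stop("field_params: 'mu' must be in [0, L)", call. = FALSE)
  if (N < 2 || N != round(N)) stop("field_params: 'N' must be an integer >= 2", call. = FALSE)
  structure(list(Cmax = Cmax, mu = mu, kappa = kappa, L = L, N = as.integer(N)),
            class = "field_params")
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("field_params: '%s' must be a finite numeric scalar", name),
         call. = FALSE)
  invisible(x)
}

#' Evaluate a von Mises substrate field on the lattice
#'
#' @param params a [field_params()] object.
#' @return Numeric vector of `N` strictly positive concentrations, indexed by
#'   0-based site (element `i + 1` is site `i`).
#' @export
build_field <- function(params) {
  if (!inherits(params, "field_params"))
    stop("build_field: 'params' must be a field_params object", call. = FALSE)
  x <- (seq_len(params$N) - 1) * params$L / params$N
  params$Cmax * exp(params$kappa * cos(2 * pi * (x - params$mu) / params$L)) /
    (params$L * besselI(params$kappa, 0))
}

#' Static two-substrate environment
#'
#' Bundles the realized concentration fields of substrates A and B. The fields
#' are immutable for the whole simulation: absorption by cells does not
#' deplete them.
#'
#' @param params_A,params_B [field_params()] for substrates A and B. The two
#'   fields must share the same lattice (`L`, `N`). Defaults place the peaks
#'   at opposite ends of a ring of 100 sites (`mu` 25 and 75).
#' @return Object of class `"environment_field"` with elements `conc_A`,
#'   `conc_B` (length-`N` vectors), `N`, and the two parameter sets.
#' @export
environment_field <- function(params_A = field_params(mu = 25),
                              params_B = field_params(mu = 75)) {
  if (!inherits(params_A, "field_params") || !inherits(params_B, "field_params"))
    stop("environment_field: both arguments must be field_params objects",
         call. = FALSE)
  if (params_A$N != params_B$N || params_A$L != params_B$L)
    stop("environment_field: A and B fields must share the same lattice (L, N)",
         call. = FALSE)
  structure(list(params_A = params_A, params_B = params_B,
                 conc_A = build_field(params_A), conc_B = build_field(params_B),
                 N = params_A$N),
            class = "environment_field")
}

#' Periodic concentration lookup
#'
#' Site indices are 0-based and wrap modulo `N`, so any integer (negative or
#' beyond `N - 1`) addresses a valid location on the ring.
#'
#' @param field an [environment_field()].
#' @param substrate `"A"` or `"B"`.
#' @param site integer site index (vectorized; any integer).
#' @return Concentration(s) at `site %% N`.
#' @export
concentration_at <- function(field, substrate = c("A", "B"), site) {
  substrate <- match.arg(substrate)
  conc <- if (substrate == "A") field$conc_A else field$conc_B
  conc[(site %% field$N) + 1L]
}

#' @export
as.data.frame.environment_field <- function(x, ...) {
  data.frame(site = seq_len(x$N) - 1L, conc_A = x$conc_A, conc_B = x$conc_B)
}

#' @export
print.environment_field <- function(x, ...) {
  cat(sprintf("Two-substrate periodic field: %d sites\n", x$N))
  cat(sprintf("  A: Cmax=%g mu=%g kappa=%g (peak %.3f)\n",
              x$params_A$Cmax, x$params_A$mu, x$params_A$kappa, max(x$conc_A)))
  cat(sprintf("  B: Cmax=%g mu=%g kappa=%g (peak %.3f)\n",
              x$params_B$Cmax, x$params_B$mu, x$params_B$kappa, max(x$conc_B)))
  invisible(x)
}
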