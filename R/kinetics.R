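# Three-state irreversible unfolding kinetics: N -> I -> D.
#
# Each step i has a first-order rate constant
#   k_i(T) = exp[(Ea_i / R) (1/Tstar_i - 1/T)]   (min^-1),
# where Tstar_i is the temperature at which k_i = 1 min^-1. The model is
# parametrized by the two activation energies, the two Tstar temperatures
# and the calorimetric enthalpies dHcal_1, dHcal_2 released in each step.

#' Kinetic parameters of the three-state irreversible unfolding model
#'
#' @param ea1,ea2 Activation energies of the N->I and I->D steps, kJ/mol.
#' @param tstar1,tstar2 Temperatures (K) at which the respective rate
#'   constant equals 1 min^-1. `tstar2 = Inf` encodes a frozen second step
#'   (k2 identically zero), the two-state limit.
#' @param dh1,dh2 Calorimetric enthalpies of the two steps, kJ/mol. Either
#'   may be fixed to exactly zero by a fit constraint.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(ea1, tstar1, ea2, tstar2, dh1 = 0, dh2 = 0) {
  stopifnot(is.numeric(ea1), is.numeric(ea2), ea1 >= 0, ea2 >= 0)
  if (!(tstar1 >= 273 && tstar1 <= 400))
    stop("tstar1 must lie within 273-400 K")
  if (!is.infinite(tstar2) && !(tstar2 >= 273 && tstar2 <= 400))
    stop("tstar2 must lie within 273-400 K (or Inf for a frozen step)")
  if (dh1 < 0 || dh2 < 0) stop("calorimetric enthalpies must be >= 0")
  structure(list(ea1 = ea1, tstar1 = tstar1, ea2 = ea2, tstar2 = tstar2,
                 dh1 = dh1, dh2 = dh2),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Three-state irreversible unfolding parameters\n")
  cat(sprintf("  step 1 (N->I): Ea = %.1f kJ/mol, T* = %.2f K, dHcal = %.1f kJ/mol\n",
              x$ea1, x$tstar1, x$dh1))
  cat(sprintf("  step 2 (I->D): Ea = %.1f kJ/mol, T* = %s K, dHcal = %.1f kJ/mol\n",
              x$ea2, format(x$tstar2), x$dh2))
  invisible(x)
}

#' Unfolding rate constant at a temperature
#'
#' `k_i(T) = exp[(Ea_i/R)(1/Tstar_i - 1/T)]` in min^-1, so `k = 1` at
#' `T = Tstar_i` by construction and k increases with T for positive Ea.
#'
#' @param params A [kinetic_params()] object.
#' @param step Which unfolding step, 1 (N->I) or 2 (I->D).
#' @param temp Temperature(s), K. Must be positive.
#' @return Rate constant(s), min^-1 (vectorized over `temp`).
#' @export
rate_constant <- function(params, step, temp) {
  stopifnot(inherits(params, "kinetic_params"), step %in% c(1, 2))
  if (any(temp <= 0)) stop("temperature must be positive (Kelvin)")
  ea <- if (step == 1) params$ea1 else params$ea2
  tstar <- if (step == 1) params$tstar1 else params$tstar2
  if (is.infinite(tstar)) return(rep(0, length(temp)))
  exp((ea * 1000 / R_GAS) * (1 / tstar - 1 / temp))
}

new_state_fractions <- function(grid, xn, xi, xd, axis = c("temperature", "time"),
                                scan_rate = NULL, hold_temperature = NULL) {
  axis <- match.arg(axis)
  structure(
    data.frame(grid = grid, xN = xn, xI = xi, xD = xd),
    axis = axis, scan_rate = scan_rate, hold_temperature = hold_temperature,
    class = c("state_fractions", "data.frame"))
}

#' Propagate state fractions along a temperature scan
#'
#' Integrates `dxN/dT = -k1 xN / v`, `dxI/dT = (k1 xN - k2 xI)/v` from the
#' all-native initial condition, on a temperature grid scanned at `v` K/min.
#' The integrator is an exponentially fitted scheme on a refined internal
#' grid (no step larger than `max_step` K); it conserves `xN + xI + xD = 1`
#' to machine precision and is stable for arbitrarily large post-transition
#' rate constants.
#'
#' @param params A [kinetic_params()] object.
#' @param t0,t1 Scan start and end temperatures, K (`t1 > t0`).
#' @param v Scan rate, K/min (> 0).
#' @param n_grid Number of output grid points.
#' @param grid Optional explicit (strictly increasing) output temperature
#'   grid overriding `t0`/`t1`/`n_grid` — used to evaluate the model exactly
#'   at experimental temperatures.
#' @param max_step Maximum internal integration step, K.
#' @return A `state_fractions` data frame with columns `grid` (K), `xN`,
#'   `xI`, `xD`.
#' @export
propagate_scan <- function(params, t0, t1, v, n_grid = 501, grid = NULL,
                           max_step = 0.01) {
  stopifnot(inherits(params, "kinetic_params"), v > 0)
  if (is.null(grid)) {
    stopifnot(t1 > t0)
    grid <- seq(t0, t1, length.out = n_grid)
  }
  if (any(diff(grid) <= 0)) stop("temperature grid must be strictly increasing")
  m <- propagate_scan_cpp(params$ea1 * 1000, params$tstar1,
                          params$ea2 * 1000, params$tstar2,
                          grid, v, max_step)
  new_state_fractions(grid, m[, 1], m[, 2], m[, 3],
                      axis = "temperature", scan_rate = v)
}

#' Propagate state fractions at constant temperature (analytic)
#'
#' Closed-form solution of the sequential irreversible scheme at a fixed
#' temperature: `xN = exp(-k1 t)` and
#' `xI = k1/(k2-k1) (exp(-k1 t) - exp(-k2 t))`, with the degenerate
#' `k1 = k2` branch `xI = k1 t exp(-k1 t)` evaluated through a numerically
#' stable `expm1` form.
#'
#' @param params A [kinetic_params()] object.
#' @param temp Hold temperature, K.
#' @param times Non-negative, ascending time points, min.
#' @return A `state_fractions` data frame with `grid` in minutes.
#' @export
propagate_isothermal <- function(params, temp, times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(times < 0) || any(diff(times) < 0))
    stop("times must be non-negative and ascending")
  k1 <- rate_constant(params, 1, temp)
  k2 <- rate_constant(params, 2, temp)
  xn <- exp(-k1 * times)
  d <- k2 - k1
  # xI = k1 (e^{-k1 t} - e^{-k2 t}) / (k2 - k1); series branch near k1 = k2
  u <- d * times
  xi <- ifelse(abs(u) > 1e-6,
               k1 * (xn - exp(-k2 * times)) / d,
               k1 * times * xn * (1 - u / 2 + u^2 / 6))
  xi[times == 0] <- 0
  xi <- pmax(xi, 0)
  xd <- pmin(1, pmax(0, 1 - xn - xi))
  new_state_fractions(times, xn, xi, 1 - xn - xi,
                      axis = "time", hold_temperature = temp)
}

#' Excess heat capacity predicted by the kinetic model
#'
#' `Cp_exc(T) = [dHcal1 k1(T) xN(T) + dHcal2 k2(T) xI(T)] / v`. No delta-Cp
#' term is included: the contract is baseline-subtracted DSC data, so the
#' whole area under the curve equals `dHcal1 + dHcal2`.
#'
#' @param params A [kinetic_params()] object (its `dh1`, `dh2` are used).
#' @param fractions `state_fractions` from [propagate_scan()] at scan rate `v`.
#' @param v Scan rate, K/min; must match the one used for `fractions`.
#' @return Numeric vector of excess heat capacity, kJ mol^-1 K^-1.
#' @export
dsc_signal <- function(params, fractions, v) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(fractions, "state_fractions"))
  if (attr(fractions, "axis") != "temperature")
    stop("dsc_signal needs temperature-scan fractions")
  fv <- attr(fractions, "scan_rate")
  if (!is.null(fv) && abs(fv - v) > 1e-12)
    stop("scan rate mismatch between fractions (", fv, ") and v (", v, ")")
  temps <- fractions$grid
  (params$dh1 * rate_constant(params, 1, temps) * fractions$xN +
   params$dh2 * rate_constant(params, 2, temps) * fractions$xI) / v
}

#' Spectroscopic signal from state fractions and per-state linear baselines
#'
#' `y = sum_s (a_s + b_s (T - Tref)) x_s` over s in N, I, D. For isothermal
#' fractions the baseline argument is the time axis instead of `T - Tref`.
#'
#' @param fractions A `state_fractions` object.
#' @param baselines 3 x 2 numeric matrix, rows N, I, D, columns (a, b).
#' @param tref Reference temperature, K (ignored for time-axis fractions).
#' @return Numeric signal vector.
#' @export
spectro_signal <- function(fractions, baselines, tref = 298.15) {
  stopifnot(inherits(fractions, "state_fractions"))
  baselines <- matrix(as.numeric(baselines), nrow = 3, ncol = 2)
  dx <- if (attr(fractions, "axis") == "temperature")
    fractions$grid - tref else fractions$grid
  lin <- function(s) baselines[s, 1] + baselines[s, 2] * dx
  lin(1) * fractions$xN + lin(2) * fractions$xI + lin(3) * fractions$xD
}

#' Gibbs activation energies of the two unfolding steps
#'
#' Eyring inversion of the rate constants:
#' `dG_i(T) = -R T ln[k_i(T) h / (kB T)]` with `k_i` converted to s^-1.
#' The default grid is 40, 60 and 80 degrees Celsius.
#'
#' @param params A [kinetic_params()] object.
#' @param temperatures Temperatures, K.
#' @return A data frame of class `barrier_report` with columns
#'   `temperature` (K), `dG1`, `dG2` (kJ/mol).
#' @export
barrier_at <- function(params, temperatures = c(313.15, 333.15, 353.15)) {
  stopifnot(inherits(params, "kinetic_params"), all(temperatures > 0))
  dg <- function(step) {
    k_s <- rate_constant(params, step, temperatures) / 60
    -R_GAS * temperatures * log(k_s * PLANCK / (BOLTZMANN * temperatures)) / 1000
  }
  structure(data.frame(temperature = temperatures, dG1 = dg(1), dG2 = dg(2)),
            class = c("barrier_report", "data.frame"))
}

# Inverse of barrier_at for one step: k (min^-1) back from dG (kJ/mol).
rate_from_barrier <- function(dg, temperatures) {
  60 * (BOLTZMANN * temperatures / PLANCK) *
    exp(-dg * 1000 / (R_GAS * temperatures))
}
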