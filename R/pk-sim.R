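#' Build a dosing regimen
#'
#' A regimen is a tibble of intravenous infusion events. All times are in
#' hours from the start of the first dose.
#'
#' @param amt Dose amount(s), mg.
#' @param time Infusion start time(s), h.
#' @param tinf Infusion duration(s), h.
#' @param ii Scheduled dosing interval(s), h (used by steady-state formulas
#'   and daily-dose accounting, not by the simulator itself).
#' @param n_doses If given with scalar `amt`/`tinf`/`ii`, replicates the dose
#'   every `ii` hours starting at `time`.
#' @return A tibble with columns `time`, `amt`, `tinf`, `ii`.
#' @examples
#' pk_regimen(amt = 600, tinf = 0.5, ii = 24, n_doses = 3)
#' @export
pk_regimen <- function(amt, time = 0, tinf = 0.5, ii = 24, n_doses = NULL) {
  if (!is.null(n_doses)) {
    stopifnot(length(amt) == 1, length(tinf) == 1, length(ii) == 1)
    time <- time[1] + ii * (seq_len(n_doses) - 1)
    amt <- rep(amt, n_doses)
  }
  reg <- tibble::tibble(
    time = as.numeric(time),
    amt = as.numeric(amt),
    tinf = rep_len(as.numeric(tinf), length(time)),
    ii = rep_len(as.numeric(ii), length(time))
  )
  if (any(reg$amt < 0)) abort("Dose amounts must be non-negative.")
  if (any(reg$tinf <= 0)) abort("Infusion durations must be positive.")
  if (is.unsorted(reg$time)) abort("Dose times must be non-decreasing.")
  reg
}

# Disposition macro-constants: exponents lambda and unit-sum coefficients of
# the central-compartment impulse response. For one compartment this is the
# trivial (k, 1) pair; for two, the usual alpha/beta decomposition.
.macro <- function(params) {
  CL <- params$CL; V1 <- params$V1
  has_q <- all(c("Q", "V2") %in% names(params)) &&
    !is.na(params[["Q"]]) && !is.na(params[["V2"]])
  if (identical(as.integer(params$n_compartments), 2L)) {
    if (!has_q) {
      abort("Two-compartment simulation needs `Q` and `V2`.")
    }
    k10 <- CL / V1; k12 <- params$Q / V1; k21 <- params$Q / params$V2
    s <- k10 + k12 + k21
    disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    list(lambda = c(alpha, beta),
         coef = c((alpha - k21) / (alpha - beta),
                  (k21 - beta) / (alpha - beta)),
         V1 = V1)
  } else {
    if (has_q) {
      abort("One-compartment parameter set must not carry `Q`/`V2`.")
    }
    list(lambda = CL / V1, coef = 1, V1 = V1)
  }
}

# Central concentration after a single infusion (dose D over tinf) at times
# t >= 0 from dose start; exact piecewise-analytic evaluation.
.conc_single <- function(t, D, tinf, mac) {
  out <- numeric(length(t))
  pos <- t > 0
  if (!any(pos) || D == 0) return(out)
  tp <- t[pos]
  acc <- 0
  for (j in seq_along(mac$lambda)) {
    lam <- mac$lambda[j]
    acc <- acc + (mac$coef[j] / lam) *
      (1 - exp(-lam * pmin(tp, tinf))) * exp(-lam * pmax(tp - tinf, 0))
  }
  out[pos] <- (D / (tinf * mac$V1)) * acc
  out
}

#' Simulate central-compartment concentrations
#'
#' Exact analytic superposition of intravenous-infusion solutions for one- or
#' two-compartment disposition — no ODE integration, so the result is
#' deterministic to machine precision.
#'
#' @param params Parameter tibble from [individual_parameters()] or
#'   [pk_params()].
#' @param regimen A [pk_regimen()].
#' @param times Numeric vector of times (h, from first dose start); must be
#'   non-negative.
#' @return A tibble with columns `time` and `conc` (mg/L), sorted by time.
#' @examples
#' p <- pk_params(CL = 6, V1 = 30)
#' simulate_concentrations(p, pk_regimen(600, tinf = 0.5), times = c(0.5, 9.5))
#' @export
simulate_concentrations <- function(params, regimen, times) {
  if (any(times < 0)) abort("Simulation times must be non-negative.")
  mac <- .macro(params)
  times <- sort(times)
  conc <- numeric(length(times))
  for (d in seq_len(nrow(regimen))) {
    conc <- conc + .conc_single(times - regimen$time[d], regimen$amt[d],
                                regimen$tinf[d], mac)
  }
  tibble::tibble(time = times, conc = conc)
}

#' Exposure: area under the concentration-time curve
#'
#' For a parameter set plus regimen the curve is evaluated analytically on a
#' fine grid and integrated by the trapezoid rule; the `[0, Inf)` window uses
#' the mass-balance identity `AUC = sum(doses) / CL` exactly (linear
#' kinetics), with any `[0, t_start)` head subtracted by quadrature. A
#' pre-computed curve (data frame with `time`, `conc`) is integrated as-is
#' over the window.
#'
#' @param x Parameter tibble, or a concentration curve data frame.
#' @param regimen A [pk_regimen()] (required when `x` is a parameter set).
#' @param window Length-2 numeric `[t_start, t_end]`, h; `t_end` may be `Inf`
#'   for a parameter set.
#' @param dt Trapezoid grid resolution, h.
#' @return AUC in mg*h/L.
#' @examples
#' p <- pk_params(CL = 6, V1 = 30)
#' reg <- pk_regimen(600, tinf = 0.5)
#' compute_auc(p, reg, window = c(0, Inf))  # 600/6 = 100 exactly
#' @export
compute_auc <- function(x, regimen = NULL, window = c(0, 24), dt = 0.01) {
  if (window[2] <= window[1]) abort("AUC window must have t_end > t_start.")
  if (is.data.frame(x) && all(c("time", "conc") %in% names(x))) {
    keep <- x$time >= window[1] & x$time <= window[2]
    if (sum(keep) < 2) abort("Curve grid does not cover the AUC window.")
    return(.trapz(x$time[keep], x$conc[keep]))
  }
  if (is.null(regimen)) abort("`regimen` is required for a parameter set.")
  if (is.infinite(window[2])) {
    total <- sum(regimen$amt) / x$CL
    if (window[1] > 0) {
      total <- total - compute_auc(x, regimen, c(0, window[1]), dt)
    }
    return(total)
  }
  grid <- seq(window[1], window[2], by = dt)
  if (tail(grid, 1) < window[2]) grid <- c(grid, window[2])
  curve <- simulate_concentrations(x, regimen, grid)
  .trapz(curve$time, curve$conc)
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Steady-state peak and trough of a fitted individual
#'
#' Evaluates the steady-state concentration at given offsets within a dosing
#' interval by superposing enough preceding doses for the accumulation to
#' converge.
#'
#' @param params Parameter tibble.
#' @param amt Dose per administration, mg. @param tinf Infusion length, h.
#' @param ii Dosing interval, h.
#' @param offsets Times after dose start (h) at which to evaluate.
#' @param n_doses Number of preceding doses superposed (default 200, ample
#'   for convergence at therapeutic half-lives).
#' @return Tibble with `offset` and `conc`.
#' @export
steady_state_conc <- function(params, amt, tinf, ii, offsets, n_doses = 200) {
  reg <- pk_regimen(amt, tinf = tinf, ii = ii, n_doses = n_doses)
  t_last <- reg$time[n_doses]
  sim <- simulate_concentrations(params, reg, t_last + offsets)
  tibble::tibble(offset = sort(offsets), conc = sim$conc)
}
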