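# Sea-level trajectories for IPCC emission scenarios: a semi-empirical
# temperature-driven model and a parametric power-law curve, plus the shared
# fixed-step classical Runge-Kutta integrator used by the reef model.

.TRAJECTORY_KINDS <- c("temperature", "sea_level", "reef_elevation")

#' Time-series trajectory
#'
#' A (year, value) series for temperature (degrees C above baseline),
#' sea level (mm above baseline) or reef elevation (mm of accreted
#' framework).
#'
#' @param years Strictly increasing numeric years.
#' @param values Numeric values, same length, finite.
#' @param kind One of `"temperature"`, `"sea_level"`, `"reef_elevation"`.
#' @return An object of class `trajectory` (a data.frame with columns
#'   `year` and `value` and a `kind` attribute).
#' @export
trajectory <- function(years, values, kind) {
  kind <- match.arg(kind, .TRAJECTORY_KINDS)
  stopifnot(is.numeric(years), is.numeric(values),
            length(years) == length(values))
  if (length(years) < 1) stop("invalid_trajectory: empty", call. = FALSE)
  if (any(diff(years) <= 0)) {
    stop("invalid_trajectory: years must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("invalid_trajectory: values must be finite", call. = FALSE)
  }
  structure(data.frame(year = years, value = values),
            kind = kind, class = c("trajectory", "data.frame"))
}

#' Kind of a trajectory
#' @param traj A [trajectory()].
#' @return The kind tag.
#' @export
trajectory_kind <- function(traj) attr(traj, "kind")

#' Interpolate a trajectory at arbitrary years
#' @param traj A [trajectory()].
#' @param years Years within the trajectory span.
#' @return Linearly interpolated values.
#' @export
trajectory_at <- function(traj, years) {
  stopifnot(inherits(traj, "trajectory"))
  if (any(years < min(traj$year)) || any(years > max(traj$year))) {
    stop("span_error: requested years outside the trajectory span",
         call. = FALSE)
  }
  stats::approx(traj$year, traj$value, xout = years)$y
}

# Classical fixed-step 4th-order Runge-Kutta for a scalar ODE y' = f(t, y).
# Used identically for sea-level and reef-elevation integration. Returns the
# solution at t0 + 0:n_steps * step.
.rk4 <- function(f, y0, t0, t1, step) {
  stopifnot(step > 0, t1 > t0)
  n <- round((t1 - t0) / step)
  if (abs(n * step - (t1 - t0)) > 1e-8 * (t1 - t0)) {
    stop("invalid_step: (t1 - t0) must be an integer multiple of step",
         call. = FALSE)
  }
  tt <- t0 + (0:n) * step
  y <- numeric(n + 1)
  y[1] <- y0
  for (i in seq_len(n)) {
    t <- tt[i]; h <- step; yi <- y[i]
    k1 <- f(t, yi)
    k2 <- f(t + h / 2, yi + h / 2 * k1)
    k3 <- f(t + h / 2, yi + h / 2 * k2)
    k4 <- f(t + h, yi + h * k3)
    y[i + 1] <- yi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(t = tt, y = y)
}

# Restrict an RK4 solution to (approximately) annual output years.
.annual <- function(sol, t0, t1) {
  years <- seq(ceiling(t0), floor(t1))
  if (years[1] != t0) years <- c(t0, years)
  idx <- vapply(years, function(yr) which.min(abs(sol$t - yr)), integer(1))
  list(t = sol$t[idx], y = sol$y[idx])
}

#' Default emission-scenario set
#'
#' The three IPCC SRES scenarios used for the 1990-2100 projections: B1
#' (+1.8 degrees C by 2100), A2 (+3.4), A1FI (+4.0), with default parametric
#' sea-level endpoints of 750, 850 and 900 mm spanning the 75-90 cm range.
#'
#' @return A data.frame with columns `name`, `delta_T_2100` (degrees C) and
#'   `rise_2100_mm`.
#' @export
emission_scenarios <- function() {
  data.frame(name = c("B1", "A2", "A1FI"),
             delta_T_2100 = c(1.8, 3.4, 4.0),
             rise_2100_mm = c(750, 850, 900),
             stringsAsFactors = FALSE)
}

.get_scenario <- function(scenario) {
  if (is.character(scenario)) {
    scen <- emission_scenarios()
    # the label is sometimes printed with a trailing digit one
    name <- toupper(scenario)
    name[name == "A1F1"] <- "A1FI"
    idx <- match(name, scen$name)
    if (any(is.na(idx))) {
      stop("unknown_scenario: ", paste(scenario[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    return(scen[idx, , drop = FALSE])
  }
  stopifnot(is.data.frame(scenario), "delta_T_2100" %in% names(scenario))
  scenario
}

#' Temperature trajectory for an emission scenario
#'
#' Anchored at zero anomaly at `t0` and at the scenario's 2100 warming at
#' `t1`. The `"linear"` shape is a straight ramp; `"smooth"` is the monotone
#' cubic `delta_T * (3x^2 - 2x^3)` with zero initial slope.
#'
#' @param scenario Scenario name (`"B1"`, `"A2"`, `"A1FI"`) or a one-row
#'   data.frame with `delta_T_2100`.
#' @param t0,t1 Start and end years (default 1990, 2100).
#' @param step Grid step in years (default 1).
#' @param shape `"linear"` or `"smooth"`.
#' @return A temperature [trajectory()] in degrees C above the `t0` baseline.
#' @export
temperature_trajectory <- function(scenario, t0 = 1990, t1 = 2100, step = 1,
                                   shape = c("linear", "smooth")) {
  shape <- match.arg(shape)
  stopifnot(t0 < t1, step > 0)
  scen <- .get_scenario(scenario)
  if (nrow(scen) != 1) stop("one scenario at a time", call. = FALSE)
  dT <- scen$delta_T_2100
  years <- seq(t0, t1, by = step)
  if (years[length(years)] != t1) years <- c(years, t1)
  x <- (years - t0) / (t1 - t0)
  values <- switch(shape, linear = dT * x, smooth = dT * (3 * x^2 - 2 * x^3))
  trajectory(years, values, "temperature")
}

#' Semi-empirical sea-level model parameters
#'
#' Rise rate dH/dt = a_sl * (T - T0) + b_sl * dT/dt. Defaults follow the
#' dual-term semi-empirical calibration of Vermeer & Rahmstorf (2009):
#' a_sl = 5.6 mm y^-1 K^-1, b_sl = -49 mm K^-1, T0 = -0.41 degrees C
#' (anomaly relative to the 1990 baseline used here).
#'
#' @param a_sl Sensitivity of the rise rate to temperature, mm y^-1 K^-1.
#' @param b_sl Instantaneous-response term, mm K^-1.
#' @param T0 Equilibrium temperature anomaly, degrees C.
#' @return An object of class `sealevel_params`.
#' @export
sealevel_params <- function(a_sl = 5.6, b_sl = -49, T0 = -0.41) {
  stopifnot(is.finite(a_sl), is.finite(b_sl), is.finite(T0))
  structure(list(a_sl = a_sl, b_sl = b_sl, T0 = T0),
            class = "sealevel_params")
}

#' Instantaneous semi-empirical sea-level rise rate
#'
#' @param temperature Temperature anomaly, degrees C.
#' @param dTdt Rate of temperature change, degrees C y^-1.
#' @param params A [sealevel_params()] object.
#' @return Rise rate in mm y^-1.
#' @export
semi_empirical_rate <- function(temperature, dTdt, params = sealevel_params()) {
  stopifnot(inherits(params, "sealevel_params"))
  params$a_sl * (temperature - params$T0) + params$b_sl * dTdt
}

#' Integrate sea level from a temperature trajectory
#'
#' Integrates the semi-empirical rate with the same fixed-step classical
#' Runge-Kutta scheme as the reef model; H = 0 at the start of the
#' trajectory. dT/dt is evaluated from finite differences on the
#' temperature grid (centered in the interior, one-sided at the ends).
#'
#' @param temp A temperature [trajectory()] with at least two points.
#' @param params A [sealevel_params()] object.
#' @param step Integration step in years (default 0.1).
#' @return A sea-level [trajectory()] in mm, reported annually.
#' @export
integrate_sea_level <- function(temp, params = sealevel_params(), step = 0.1) {
  stopifnot(inherits(temp, "trajectory"))
  if (nrow(temp) < 2) {
    stop("invalid_trajectory: need at least two temperature points",
         call. = FALSE)
  }
  yrs <- temp$year; Tv <- temp$value
  n <- length(yrs)
  dT <- numeric(n)
  dT[1] <- (Tv[2] - Tv[1]) / (yrs[2] - yrs[1])
  dT[n] <- (Tv[n] - Tv[n - 1]) / (yrs[n] - yrs[n - 1])
  if (n > 2) {
    dT[2:(n - 1)] <- (Tv[3:n] - Tv[1:(n - 2)]) / (yrs[3:n] - yrs[1:(n - 2)])
  }
  Tfun <- stats::approxfun(yrs, Tv, rule = 2)
  dTfun <- stats::approxfun(yrs, dT, rule = 2)
  t0 <- yrs[1]; t1 <- yrs[n]
  sol <- .rk4(function(t, H) semi_empirical_rate(Tfun(t), dTfun(t), params),
              0, t0, t1, step)
  out <- .annual(sol, t0, t1)
  trajectory(out$t, out$y, "sea_level")
}

#' Parametric sea-level trajectory from a 2100 endpoint
#'
#' H(t) = rise_2100 * ((t - t0)/(t1 - t0))^p: an accelerating power law
#' anchored at 0 at `t0` and exactly at `rise_2100` at `t1`. Used when only
#' the end-of-century rise is known.
#'
#' @param rise_2100 Total rise over the span, mm (>= 0).
#' @param exponent Power p >= 1 (p = 1 is a constant rate; default 2).
#' @param t0,t1 Span (default 1990-2100).
#' @param step Grid step in years (default 1).
#' @return A sea-level [trajectory()] in mm.
#' @export
parametric_sea_level <- function(rise_2100, exponent = 2, t0 = 1990,
                                 t1 = 2100, step = 1) {
  stopifnot(t0 < t1, step > 0)
  if (!is.finite(rise_2100) || rise_2100 < 0) {
    stop("invalid_rise: rise_2100 must be >= 0", call. = FALSE)
  }
  if (!is.finite(exponent) || exponent < 1) {
    stop("invalid_exponent: exponent must be >= 1 ",
         "(decelerating curves out of scope)", call. = FALSE)
  }
  years <- seq(t0, t1, by = step)
  if (years[length(years)] != t1) years <- c(years, t1)
  x <- (years - t0) / (t1 - t0)
  trajectory(years, rise_2100 * x^exponent, "sea_level")
}

#' Average rate of change over a trajectory window
#'
#' (H(tb) - H(ta)) / (tb - ta), with linear interpolation at non-grid years.
#'
#' @param traj A [trajectory()].
#' @param ta,tb Window bounds (ta < tb, both within the span).
#' @return Average rate in the trajectory's value units per year.
#' @export
average_rate <- function(traj, ta, tb) {
  stopifnot(inherits(traj, "trajectory"), ta < tb)
  vals <- trajectory_at(traj, c(ta, tb))
  (vals[2] - vals[1]) / (tb - ta)
}
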