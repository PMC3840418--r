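# Accretion-dissolution reef-growth model and keep-up diagnostics against
# sea-level rise.
#
# The governing equation is dA/dt = (a*A)/A + b*S - (c*D)/A, where A is the
# accreted framework (mm), a the net accretion coefficient (mm y^-1, coral
# plus coralline-algal growth minus bioerosion), b*S sedimentation (mm y^-1)
# and c*D dissolution (mm y^-1). The first term reduces algebraically to a.
# Two readings of the dissolution term are supported: "constant" treats c*D
# as a plain rate (dA/dt = a + b*S - c*D, the default, which reproduces the
# narrative magnitudes); "literal" keeps the division by A, i.e. dissolution
# damped by accumulated framework, with A floored at a small epsilon.

#' Reef accretion-dissolution model parameters
#'
#' @param a Accretion coefficient, mm y^-1: 7 for reefs producing
#'   10 kg CaCO3 m^-2 y^-1, 3 for 4 kg, 0.75 for 1 kg (50% framework
#'   porosity).
#' @param b Sedimentation coefficient (dimensionless, default 1).
#' @param S Sedimentation rate, mm y^-1 (default 1, so b*S = 1 mm y^-1).
#' @param c Dissolution coefficient (dimensionless in constant mode; carries
#'   units of mm in literal mode). Default 1.
#' @param D Dissolution rate, mm y^-1, >= 0, subtracted. Default 0
#'   (imperforate framework); the perforate default elsewhere in the package
#'   is derived from the measured mass loss via
#'   [mass_rate_to_vertical_rate()].
#' @param A0 Initial accreted framework, mm; must be > 0 in literal mode
#'   (default 100).
#' @param mode `"constant"` (default) or `"literal"` (see Details above).
#' @param floor_mm Lower bound applied to A in literal mode (default 1 mm).
#' @return An object of class `reef_model_params`.
#' @export
reef_model_params <- function(a, b = 1, S = 1, c = 1, D = 0, A0 = 100,
                              mode = c("constant", "literal"), floor_mm = 1) {
  mode <- match.arg(mode)
  stopifnot(is.finite(a), is.finite(b), is.finite(S), is.finite(c),
            is.finite(A0), is.finite(floor_mm), floor_mm > 0)
  if (!is.finite(D) || D < 0) {
    stop("invalid_params: D must be finite and >= 0", call. = FALSE)
  }
  if (mode == "literal" && A0 <= 0) {
    stop("invalid_params: A0 must be > 0 in literal mode", call. = FALSE)
  }
  structure(list(a = a, b = b, S = S, c = c, D = D, A0 = A0, mode = mode,
                 floor_mm = floor_mm),
            class = "reef_model_params")
}

#' Right-hand side of the reef accretion-dissolution equation
#'
#' @param A Current accreted framework, mm.
#' @param params A [reef_model_params()] object.
#' @return dA/dt in mm y^-1.
#' @export
reef_rhs <- function(A, params) {
  stopifnot(inherits(params, "reef_model_params"))
  if (params$mode == "constant") {
    return(params$a + params$b * params$S - params$c * params$D)
  }
  if (any(A <= 0)) {
    stop("invalid_state: A must be > 0 in literal mode", call. = FALSE)
  }
  params$a + params$b * params$S -
    params$c * params$D / pmax(A, params$floor_mm)
}

#' Integrate the reef accretion-dissolution model
#'
#' Classical fixed-step 4th-order Runge-Kutta from A(t0) = A0, reported
#' annually. In literal mode the state is floored at `floor_mm`; if the
#' floor is reached the returned trajectory carries the attribute
#' `framework_exhausted = TRUE` (a flagged, non-fatal condition).
#'
#' @param params A [reef_model_params()] object.
#' @param t0,t1 Simulation span in years (default 1990-2100).
#' @param step Integration step in years (default 0.1).
#' @return A reef-elevation [trajectory()] (accreted framework, mm) with
#'   attribute `framework_exhausted`.
#' @export
integrate_reef <- function(params, t0 = 1990, t1 = 2100, step = 0.1) {
  stopifnot(inherits(params, "reef_model_params"), step > 0, t0 < t1)
  exhausted <- FALSE
  f <- if (params$mode == "constant") {
    function(t, A) params$a + params$b * params$S - params$c * params$D
  } else {
    function(t, A) {
      if (A <= params$floor_mm) exhausted <<- TRUE
      params$a + params$b * params$S -
        params$c * params$D / max(A, params$floor_mm)
    }
  }
  sol <- .rk4(f, params$A0, t0, t1, step)
  if (params$mode == "literal" && any(sol$y <= params$floor_mm)) {
    exhausted <- TRUE
    sol$y <- pmax(sol$y, params$floor_mm)
  }
  out <- .annual(sol, t0, t1)
  traj <- trajectory(out$t, out$y, "reef_elevation")
  attr(traj, "framework_exhausted") <- exhausted
  traj
}

#' Keep-up diagnostics of a reef against sea-level rise
#'
#' Compares a reef-elevation trajectory with a sea-level trajectory on
#' their common annual grid. Both are rebased to zero at the first common
#' year; the gap is sea level minus accumulated reef growth. Rates are
#' estimated by centered finite differences (one-sided at the ends).
#'
#' @param reef A reef-elevation [trajectory()].
#' @param sea A sea-level [trajectory()].
#' @param threshold Gap (mm) above which the reef is considered submerged
#'   relative to its start (default 0).
#' @return A list of class `keep_up_report`: `gap` (a trajectory, mm),
#'   `rate_crossover_year` (first year the sea-level rise rate exceeds the
#'   net reef accretion rate, or `NA`), `submergence_year` (first year the
#'   gap exceeds `threshold`, or `NA`), and `keeps_up` (TRUE iff the gap
#'   never exceeds `threshold`).
#' @export
keep_up_report <- function(reef, sea, threshold = 0) {
  stopifnot(inherits(reef, "trajectory"), inherits(sea, "trajectory"))
  years <- intersect(round(reef$year, 6), round(sea$year, 6))
  if (length(years) < 2) {
    stop("span_error: reef and sea-level trajectories do not overlap",
         call. = FALSE)
  }
  years <- sort(years)
  A <- trajectory_at(reef, years)
  H <- trajectory_at(sea, years)
  gap <- (H - H[1]) - (A - A[1])
  rate <- function(v) {
    n <- length(v)
    r <- numeric(n)
    r[1] <- (v[2] - v[1]) / (years[2] - years[1])
    r[n] <- (v[n] - v[n - 1]) / (years[n] - years[n - 1])
    if (n > 2) {
      r[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (years[3:n] - years[1:(n - 2)])
    }
    r
  }
  sea_rate <- rate(H); reef_rate <- rate(A)
  cross <- which(sea_rate > reef_rate)
  submerge <- which(gap > threshold)
  structure(
    list(gap = trajectory(years, gap, "sea_level"),
         rate_crossover_year = if (length(cross)) years[cross[1]] else NA_real_,
         submergence_year = if (length(submerge)) years[submerge[1]] else NA_real_,
         keeps_up = length(submerge) == 0),
    class = "keep_up_report")
}

#' @export
print.keep_up_report <- function(x, ...) {
  cat("Keep-up report:\n")
  cat("  keeps up:            ", x$keeps_up, "\n")
  cat("  rate crossover year: ", x$rate_crossover_year, "\n")
  cat("  submergence year:    ", x$submergence_year, "\n")
  invisible(x)
}

#' Default reef configurations for the scenario matrix
#'
#' Three carbonate-production densities (low/medium/high = 1, 4 and
#' 10 kg CaCO3 m^-2 y^-1, i.e. a = 0.75, 3 and 7 mm y^-1) crossed with the
#' two porosity classes. The perforate dissolution rate defaults to the
#' vertical-rate equivalent of `perforate_loss_kg_m2_y` (15.3 kg m^-2 y^-1,
#' about 10.55 mm y^-1 at aragonite density and 50% framework porosity);
#' imperforate skeletons showed no consistent passive dissolution, so D = 0.
#'
#' @param perforate_loss_kg_m2_y Perforate mass-loss input, kg m^-2 y^-1.
#' @param props [framework_properties()] used for the conversion.
#' @param mode Model mode passed to [reef_model_params()].
#' @return A data.frame with columns `density`, `porosity`, `a`, `D`, `mode`.
#' @export
default_reef_configs <- function(perforate_loss_kg_m2_y = 15.3,
                                 props = framework_properties(),
                                 mode = "constant") {
  D_perf <- mass_rate_to_vertical_rate(perforate_loss_kg_m2_y, props)
  dens <- data.frame(density = c("low", "medium", "high"),
                     a = c(0.75, 3, 7), stringsAsFactors = FALSE)
  out <- merge(dens,
               data.frame(porosity = c("perforate", "imperforate"),
                          D = c(D_perf, 0), stringsAsFactors = FALSE))
  out <- out[order(match(out$density, dens$density), out$porosity), ]
  out$mode <- mode
  rownames(out) <- NULL
  out[, c("density", "porosity", "a", "D", "mode")]
}

#' Default sea-level configurations for the scenario matrix
#'
#' One parametric curve per emission scenario, anchored at the scenario's
#' 2100 rise with the accelerating default exponent.
#'
#' @param scenarios A scenario table as from [emission_scenarios()].
#' @param exponent Power-law exponent (default 2).
#' @param t0,t1,step Span and grid.
#' @return A named list of sea-level [trajectory()] objects.
#' @export
default_sea_configs <- function(scenarios = emission_scenarios(),
                                exponent = 2, t0 = 1990, t1 = 2100, step = 1) {
  out <- lapply(seq_len(nrow(scenarios)), function(i) {
    parametric_sea_level(scenarios$rise_2100_mm[i], exponent, t0, t1, step)
  })
  names(out) <- scenarios$name
  out
}

#' Run the full reef-density x porosity x scenario matrix
#'
#' Integrates the reef model for every reef configuration and compares each
#' run against every sea-level trajectory, emitting one row per combination
#' (18 under the defaults: 3 densities x 2 porosity classes x 3 scenarios).
#'
#' @param reef_configs A data.frame as from [default_reef_configs()].
#' @param sea_configs A named list of sea-level trajectories as from
#'   [default_sea_configs()].
#' @param t0,t1 Simulation span.
#' @param step Reef-model integration step (years).
#' @param threshold Keep-up gap threshold, mm.
#' @param ... Further arguments passed to [reef_model_params()].
#' @return A data.frame with one row per combination: `density`, `porosity`,
#'   `scenario`, `a`, `D`, `net_rate` (a + b*S - c*D, mm y^-1), `keeps_up`,
#'   `rate_crossover_year`, `submergence_year`, `final_gap_mm`. The reef and
#'   gap trajectories are attached as the `trajectories` attribute (a named
#'   list keyed `density.porosity.scenario`).
#' @export
scenario_matrix <- function(reef_configs = default_reef_configs(),
                            sea_configs = default_sea_configs(),
                            t0 = 1990, t1 = 2100, step = 0.1, threshold = 0,
                            ...) {
  stopifnot(nrow(reef_configs) > 0, length(sea_configs) > 0)
  rows <- list(); trajs <- list()
  for (i in seq_len(nrow(reef_configs))) {
    rc <- reef_configs[i, ]
    params <- reef_model_params(a = rc$a, D = rc$D, mode = rc$mode, ...)
    reef <- integrate_reef(params, t0, t1, step)
    for (scen in names(sea_configs)) {
      rep <- keep_up_report(reef, sea_configs[[scen]], threshold)
      key <- paste(rc$density, rc$porosity, scen, sep = ".")
      trajs[[key]] <- list(reef = reef, sea = sea_configs[[scen]],
                           gap = rep$gap)
      rows[[key]] <- data.frame(
        density = rc$density, porosity = rc$porosity, scenario = scen,
        a = rc$a, D = rc$D,
        net_rate = params$a + params$b * params$S - params$c * params$D,
        keeps_up = rep$keeps_up,
        rate_crossover_year = rep$rate_crossover_year,
        submergence_year = rep$submergence_year,
        final_gap_mm = rep$gap$value[nrow(rep$gap)],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trajectories") <- trajs
  out
}
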