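# Seeded synthetic inputs emulating the dissolution experiment: 15 perforate
# Montipora colonies (four growth forms) and 15 imperforate Pectinia colonies
# (foliose), split between an acidified (pH 7.8) treatment and a pH 8.2
# control over a 7-day exposure. Acidified perforate losses follow the
# exponential surface-area model plus Gaussian noise; imperforate and control
# losses are centered on zero.

#' Design of a synthetic dissolution experiment
#'
#' @param n_montipora Number of perforate *Montipora* colonies (default 15),
#'   assigned round-robin to the four growth forms.
#' @param n_pectinia Number of imperforate *Pectinia* colonies (default 15),
#'   all foliose.
#' @param duration Exposure duration in days (default 7).
#' @param sa_range Surface-area interval (cm^2) sampled uniformly
#'   (default c(20, 250)).
#' @param w0_range Initial dry-weight interval (g) sampled uniformly
#'   (default c(5, 50)).
#' @param treatment_assignment `"split"` (default): colonies alternate
#'   between acidified and control within each genus, one row per colony;
#'   `"paired-control"`: every colony yields an acidified and a control row.
#' @param noise_sd_loss Gaussian sd of the acidified perforate loss, g
#'   (default 0.01).
#' @param control_sd Gaussian sd of control and imperforate losses, g
#'   (default 0.01).
#' @param seed Integer seed; the same seed yields an identical table.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_montipora = 15, n_pectinia = 15, duration = 7,
                              sa_range = c(20, 250), w0_range = c(5, 50),
                              treatment_assignment = c("split", "paired-control"),
                              noise_sd_loss = 0.01, control_sd = 0.01,
                              seed = 1) {
  treatment_assignment <- match.arg(treatment_assignment)
  stopifnot(n_montipora > 0, n_pectinia > 0, duration > 0,
            length(sa_range) == 2, all(sa_range > 0), diff(sa_range) > 0,
            length(w0_range) == 2, all(w0_range > 0), diff(w0_range) > 0,
            noise_sd_loss >= 0, control_sd >= 0)
  structure(list(n_montipora = n_montipora, n_pectinia = n_pectinia,
                 duration = duration, sa_range = sa_range,
                 w0_range = w0_range,
                 treatment_assignment = treatment_assignment,
                 noise_sd_loss = noise_sd_loss, control_sd = control_sd,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Exponential loss model coefficients for the generator
#'
#' Defaults are the fitted surface-area-dissolution coefficients:
#' loss = -0.005 * exp(0.017 * SA).
#'
#' @param k_amp Amplitude, g (> 0).
#' @param k_exp Exponent coefficient, cm^-2 (> 0).
#' @return A list with `k_amp` and `k_exp`.
#' @export
loss_model <- function(k_amp = 0.005, k_exp = 0.017) {
  stopifnot(k_amp > 0, k_exp > 0)
  list(k_amp = k_amp, k_exp = k_exp)
}

#' Simulate a dissolution-experiment table
#'
#' Generates a [validate_coral_samples()]-conformant table. Surface areas
#' are uniform on `sa_range`; acidified perforate losses are
#' `-k_amp * exp(k_exp * SA)` plus Gaussian noise; acidified imperforate and
#' all control losses are Gaussian around zero (no consistent dissolution,
#' no surface-area dependence). Final weights are clipped to stay positive;
#' if more than 5% of samples hit the clip the design is flagged as too
#' noisy with a warning.
#'
#' @param design An [experiment_design()].
#' @param model A [loss_model()].
#' @return A coral-sample data.frame, deterministic given `design$seed`.
#' @export
simulate_dissolution_experiment <- function(design = experiment_design(),
                                            model = loss_model()) {
  stopifnot(inherits(design, "experiment_design"))
  stopifnot(model$k_amp > 0, model$k_exp > 0)
  set.seed(design$seed)
  forms <- rep(c("submassive", "branching", "encrusting", "foliose"),
               length.out = design$n_montipora)
  colonies <- data.frame(
    genus = c(rep("Montipora", design$n_montipora),
              rep("Pectinia", design$n_pectinia)),
    growth_form = c(forms, rep("foliose", design$n_pectinia)),
    porosity_class = c(rep("perforate", design$n_montipora),
                       rep("imperforate", design$n_pectinia)),
    stringsAsFactors = FALSE)
  n <- nrow(colonies)
  # Perforate growth forms occupy size strata (submassive < encrusting <
  # branching < foliose quarter-bands of sa_range, so the pooled draw stays
  # uniform over sa_range); foliose colonies therefore expose the most
  # surface and dissolve the most, the pattern the analysis expects.
  # Imperforate foliose colonies span the whole range.
  band <- match(colonies$growth_form,
                c("submassive", "encrusting", "branching", "foliose"))
  band[colonies$porosity_class == "imperforate"] <- NA
  lo <- design$sa_range[1]; wid <- diff(design$sa_range)
  sa_lo <- ifelse(is.na(band), lo, lo + (band - 1) / 4 * wid)
  sa_hi <- ifelse(is.na(band), design$sa_range[2], lo + band / 4 * wid)
  colonies$surface_area <- stats::runif(n, sa_lo, sa_hi)
  # dry weight scales with colony surface area (same fragment gets both
  # measurements): areal skeletal density ~0.15-0.25 g cm^-2, clipped to
  # the design's weight interval
  colonies$w0 <- pmin(pmax(colonies$surface_area * stats::runif(n, 0.15, 0.25),
                           design$w0_range[1]), design$w0_range[2])
  # displacement volume loosely tied to weight (bulk skeletal density ~1.7
  # g/mL with scatter); carried through but used in no model
  colonies$volume <- colonies$w0 / stats::runif(n, 1.4, 2.0)

  if (design$treatment_assignment == "split") {
    # alternate within each genus x growth-form stratum so every stratum
    # contributes to both arms
    treat <- character(n)
    strata <- split(seq_len(n),
                    interaction(colonies$genus, colonies$growth_form,
                                drop = TRUE))
    for (idx in strata) {
      treat[idx] <- rep(c("acidified", "control"), length.out = length(idx))
    }
    colonies$treatment <- treat
  } else {
    colonies <- rbind(transform(colonies, treatment = "acidified"),
                      transform(colonies, treatment = "control"))
    n <- nrow(colonies)
  }

  dissolving <- colonies$treatment == "acidified" &
    colonies$porosity_class == "perforate"
  loss <- stats::rnorm(n, mean = 0,
                       sd = ifelse(dissolving, design$noise_sd_loss,
                                   design$control_sd))
  loss[dissolving] <- loss[dissolving] -
    model$k_amp * exp(model$k_exp * colonies$surface_area[dissolving])

  w1 <- colonies$w0 + loss
  clip <- w1 <= 0
  if (any(clip)) {
    w1[clip] <- 0.01 * colonies$w0[clip]
    if (mean(clip) > 0.05) {
      warning("design_too_noisy: ", sum(clip), " of ", n,
              " final weights clipped to stay positive", call. = FALSE)
    }
  }
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    genus = colonies$genus,
                    growth_form = colonies$growth_form,
                    porosity_class = colonies$porosity_class,
                    treatment = colonies$treatment,
                    w0 = colonies$w0, w1 = w1,
                    surface_area = colonies$surface_area,
                    volume = colonies$volume,
                    duration = design$duration,
                    stringsAsFactors = FALSE)
  validate_coral_samples(out)
}

#' Simulate jittered temperature paths
#'
#' Scenario temperature ramps plus seeded AR(1) jitter, for stress-testing
#' the sea-level integration. With `jitter_sd = 0` the output equals
#' [temperature_trajectory()] exactly.
#'
#' @param scenarios Scenario names or a scenario table
#'   (default [emission_scenarios()]).
#' @param jitter_sd Marginal sd of the AR(1) jitter, degrees C (>= 0).
#' @param seed Integer seed.
#' @param phi AR(1) coefficient (default 0.7).
#' @param t0,t1,step Grid passed to [temperature_trajectory()].
#' @param shape Ramp shape.
#' @return A named list of temperature [trajectory()] objects.
#' @export
simulate_temperature_paths <- function(scenarios = emission_scenarios(),
                                       jitter_sd = 0, seed = 1, phi = 0.7,
                                       t0 = 1990, t1 = 2100, step = 1,
                                       shape = "linear") {
  stopifnot(jitter_sd >= 0, abs(phi) < 1)
  scen <- .get_scenario(if (is.character(scenarios)) scenarios else
    scenarios$name)
  set.seed(seed)
  out <- lapply(seq_len(nrow(scen)), function(i) {
    base <- temperature_trajectory(scen[i, , drop = FALSE], t0, t1, step, shape)
    if (jitter_sd > 0) {
      m <- nrow(base)
      innov_sd <- jitter_sd * sqrt(1 - phi^2)
      eps <- as.numeric(stats::arima.sim(list(ar = phi), n = m,
                                         sd = innov_sd))
      base$value <- base$value + eps
    }
    base
  })
  names(out) <- scen$name
  out
}
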