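# File formats, configuration and the end-to-end pipeline. All tables are
# plain CSV with units named in column headers where relevant; trajectories
# are two-column CSV (year, value) with a '# kind:' header comment.

#' Read a coral-sample table from CSV
#'
#' @param path Path to a CSV with exactly the [coral_sample_columns()]
#'   header.
#' @return A validated coral-sample data.frame.
#' @export
read_samples <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_coral_samples(tab)
}

#' Write a coral-sample table to CSV
#'
#' @param samples A validated coral-sample table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_coral_samples(samples)
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' @param traj A [trajectory()].
#' @param path Output path. The kind is recorded as a `# kind:` comment line.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind: ", trajectory_kind(traj)), con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' @param path Path written by [write_trajectory()].
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub("^# kind:\\s*", "", first)
  if (identical(kind, first)) {
    stop("schema_error: missing '# kind:' header in ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, comment.char = "#")
  trajectory(tab$year, tab$value, kind)
}

#' Default pipeline configuration
#'
#' A flat, fully-defaulted configuration covering every stage: the synthetic
#' experiment design, the nonlinear fit, the unit conversion, the sea-level
#' projection and the reef model. Every field can be overridden; unknown
#' keys are rejected.
#'
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    design = list(n_montipora = 15L, n_pectinia = 15L, duration = 7,
                  sa_range = c(20, 250), w0_range = c(5, 50),
                  treatment_assignment = "split",
                  noise_sd_loss = 0.01, control_sd = 0.01),
    loss_model = list(k_amp = 0.005, k_exp = 0.017),
    fit = list(max_iter = 200L, tol = 1e-10),
    units = list(mineral_density = 2.9, framework_porosity = 0.5,
                 perforate_loss_kg_m2_y = 15.3),
    sealevel = list(mode = "parametric", exponent = 2,
                    a_sl = 5.6, b_sl = -49, T0 = -0.41,
                    t0 = 1990, t1 = 2100, step = 1),
    reef = list(mode = "constant", b = 1, S = 1, c = 1, A0 = 100,
                step = 0.1, threshold = 0)
  ), class = "pipeline_config")
}

# Recursively overlay user values onto defaults, rejecting unknown keys.
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  stopifnot(is.list(user))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("config_error: unknown key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       paste0(path, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Build a pipeline configuration from overrides
#'
#' @param overrides A (possibly nested) list of values to overlay onto
#'   [default_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  structure(.merge_config(unclass(default_config()), overrides),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror [default_config()].
#' @return A `pipeline_config` with file values overlaid on the defaults.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

# Stable hash of the effective configuration (md5 of its deparsed form).
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a dissolution-experiment table, analyzes it
#' (group summary, five-group ANOVA among acidified samples, Tukey post-hoc,
#' exponential surface-area fit on the acidified perforate subset, mean
#' areal rate), converts the configured perforate mass-loss rate to a
#' vertical dissolution rate, builds the sea-level trajectories and runs the
#' reef scenario matrix with keep-up reports. Deterministic given the seed.
#'
#' @param config A `pipeline_config` (default [default_config()]).
#' @param samples Optional pre-existing coral-sample table; when `NULL`
#'   (default) a synthetic table is generated from the config's design block.
#' @param out_dir Optional output directory; when given, all tables,
#'   trajectories and the run manifest are written there as CSV/YAML.
#' @return A list: `samples`, `summary`, `anova`, `tukey`, `fit`,
#'   `mean_areal_rate_g_cm2_d`, `sea_levels`, `matrix`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), samples = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  design <- experiment_design(
    n_montipora = config$design$n_montipora,
    n_pectinia = config$design$n_pectinia,
    duration = config$design$duration,
    sa_range = config$design$sa_range,
    w0_range = config$design$w0_range,
    treatment_assignment = config$design$treatment_assignment,
    noise_sd_loss = config$design$noise_sd_loss,
    control_sd = config$design$control_sd,
    seed = config$seed)
  model <- loss_model(config$loss_model$k_amp, config$loss_model$k_exp)
  if (is.null(samples)) {
    samples <- simulate_dissolution_experiment(design, model)
  } else {
    samples <- validate_coral_samples(samples)
  }

  summary_tab <- group_summary(samples,
                               by = c("porosity_class", "treatment"))
  groups <- analysis_groups(samples)
  loss_norm <- normalized_loss(samples)
  acid <- samples$treatment == "acidified"
  anova_res <- one_way_anova(loss_norm[acid], groups[acid])
  tukey_res <- tukey_hsd(loss_norm[acid], groups[acid])

  perf_acid <- acid & samples$porosity_class == "perforate"
  fit <- fit_exponential_loss(samples$surface_area[perf_acid],
                              samples$w1[perf_acid] - samples$w0[perf_acid],
                              max_iter = config$fit$max_iter,
                              tol = config$fit$tol)
  mean_rate <- mean(areal_dissolution_rate(samples[perf_acid, ])$value)

  props <- framework_properties(config$units$mineral_density,
                                config$units$framework_porosity)
  perf_vertical <- mass_rate_to_vertical_rate(
    -config$units$perforate_loss_kg_m2_y, props)

  sl <- config$sealevel
  scen <- emission_scenarios()
  sea_levels <- if (identical(sl$mode, "parametric")) {
    default_sea_configs(scen, sl$exponent, sl$t0, sl$t1, sl$step)
  } else if (identical(sl$mode, "semi-empirical")) {
    params <- sealevel_params(sl$a_sl, sl$b_sl, sl$T0)
    out <- lapply(scen$name, function(nm) {
      integrate_sea_level(
        temperature_trajectory(nm, sl$t0, sl$t1, sl$step), params,
        step = config$reef$step)
    })
    names(out) <- scen$name
    out
  } else {
    stop("config_error: sealevel.mode must be 'parametric' or ",
         "'semi-empirical'", call. = FALSE)
  }

  reef_configs <- default_reef_configs(config$units$perforate_loss_kg_m2_y,
                                       props, mode = config$reef$mode)
  mat <- scenario_matrix(reef_configs, sea_levels,
                         t0 = sl$t0, t1 = sl$t1, step = config$reef$step,
                         threshold = config$reef$threshold,
                         b = config$reef$b, S = config$reef$S,
                         c = config$reef$c, A0 = config$reef$A0)

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefdiss")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = .config_hash(config),
    config = unclass(config),
    n_samples = nrow(samples),
    fitted_k_amp = fit$k_amp,
    fitted_k_exp = fit$k_exp,
    mean_areal_rate_g_cm2_d = mean_rate,
    perforate_vertical_rate_mm_y = perf_vertical)

  result <- list(samples = samples, summary = summary_tab,
                 anova = anova_res, tukey = tukey_res, fit = fit,
                 mean_areal_rate_g_cm2_d = mean_rate,
                 sea_levels = sea_levels, matrix = mat, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_samples(samples, file.path(out_dir, "samples.csv"))
    utils::write.csv(summary_tab, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(tukey_res, file.path(out_dir, "tukey.csv"),
                     row.names = FALSE)
    mat_out <- mat
    names(mat_out)[names(mat_out) == "net_rate"] <- "net_rate_mm_per_y"
    utils::write.csv(mat_out, file.path(out_dir, "scenario_matrix.csv"),
                     row.names = FALSE)
    for (nm in names(sea_levels)) {
      write_trajectory(sea_levels[[nm]],
                       file.path(out_dir, paste0("sealevel_", nm, ".csv")))
    }
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  result
}
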