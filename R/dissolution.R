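# Dissolution-experiment analysis: normalized weight loss, areal rates,
# group comparisons (ANOVA + Tukey HSD), the exponential surface-area
# dissolution fit, and the packaged family-porosity reference table.

.GROWTH_FORMS <- c("submassive", "branching", "encrusting", "foliose")
.POROSITY_CLASSES <- c("perforate", "imperforate")
.TREATMENTS <- c("acidified", "control")

#' Required columns of a coral-sample table
#'
#' @return Character vector of column names in canonical order.
#' @export
coral_sample_columns <- function() {
  c("sample_id", "genus", "growth_form", "porosity_class", "treatment",
    "w0", "w1", "surface_area", "volume", "duration")
}

#' Validate a coral-sample table
#'
#' Checks the schema of a dissolution-experiment table: one row per colony
#' with initial/final dry weight (g), wax-dip surface area (cm^2),
#' displacement volume (mL) and exposure duration (d). Errors are
#' row-addressed.
#'
#' @param samples A data.frame with the columns of [coral_sample_columns()].
#' @return The validated data.frame (invisibly unchanged apart from
#'   canonical column order and factor-to-character coercion).
#' @export
validate_coral_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  cols <- coral_sample_columns()
  missing <- setdiff(cols, names(samples))
  if (length(missing) > 0) {
    stop("schema_error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[, cols]
  for (ch in c("sample_id", "genus", "growth_form", "porosity_class", "treatment"))
    samples[[ch]] <- as.character(samples[[ch]])
  for (nm in c("w0", "w1", "surface_area", "volume", "duration")) {
    if (!is.numeric(samples[[nm]])) {
      stop("schema_error: column '", nm, "' must be numeric", call. = FALSE)
    }
  }
  bad_row <- function(ok, why) {
    if (any(!ok)) {
      stop("schema_error: row(s) ", paste(which(!ok), collapse = ", "),
           ": ", why, call. = FALSE)
    }
  }
  bad_row(samples$growth_form %in% .GROWTH_FORMS,
          paste("growth_form must be one of",
                paste(.GROWTH_FORMS, collapse = "/")))
  bad_row(samples$porosity_class %in% .POROSITY_CLASSES,
          "porosity_class must be perforate or imperforate")
  bad_row(samples$treatment %in% .TREATMENTS,
          "treatment must be acidified or control")
  bad_row(is.finite(samples$w0) & samples$w0 > 0, "w0 must be > 0")
  bad_row(is.finite(samples$w1) & samples$w1 >= 0, "w1 must be >= 0")
  bad_row(is.finite(samples$surface_area) & samples$surface_area > 0,
          "surface_area must be > 0")
  bad_row(is.finite(samples$volume) & samples$volume > 0, "volume must be > 0")
  bad_row(is.finite(samples$duration) & samples$duration > 0,
          "duration must be > 0")
  samples
}

#' Weight loss normalized by initial weight
#'
#' Returns (w1 - w0) / w0 per sample: negative for dissolution. Dividing by
#' the initial dry weight corrects for differences in colony size.
#'
#' @param samples A validated coral-sample table.
#' @return Numeric vector of dimensionless fractional changes.
#' @export
normalized_loss <- function(samples) {
  samples <- validate_coral_samples(samples)
  (samples$w1 - samples$w0) / samples$w0
}

#' Areal dissolution rate per sample
#'
#' (w1 - w0) / (surface_area * duration) in g cm^-2 d^-1; negative while
#' dissolving.
#'
#' @param samples A validated coral-sample table.
#' @return An [areal_mass_rate()] in g cm^-2 d^-1 (vector-valued).
#' @export
areal_dissolution_rate <- function(samples) {
  samples <- validate_coral_samples(samples)
  areal_mass_rate((samples$w1 - samples$w0) /
                    (samples$surface_area * samples$duration),
                  "g", "cm2", "d")
}

#' Group summary of normalized weight loss
#'
#' @param samples A validated coral-sample table.
#' @param by Character vector of grouping columns (default porosity class
#'   and treatment).
#' @return A data.frame with one row per group: the grouping columns, `n`,
#'   `mean_loss` and `sd_loss` of the normalized loss (sd is `NA` for n = 1).
#' @export
group_summary <- function(samples, by = c("porosity_class", "treatment")) {
  samples <- validate_coral_samples(samples)
  if (nrow(samples) == 0) stop("empty_input: no samples", call. = FALSE)
  stopifnot(all(by %in% names(samples)))
  loss <- normalized_loss(samples)
  key <- interaction(samples[by], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(seq_along(loss), key), function(idx) {
    row <- samples[idx[1], by, drop = FALSE]
    row$n <- length(idx)
    row$mean_loss <- mean(loss[idx])
    row$sd_loss <- stats::sd(loss[idx])
    row
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Add the five-group labelling used for the headline comparison
#'
#' Acidified samples are labelled by growth form for the perforate genus and
#' by genus for the imperforate one (four perforate growth forms plus the
#' imperforate group); controls are labelled `control_<porosity_class>`.
#'
#' @param samples A validated coral-sample table.
#' @return Character vector of group labels, one per row.
#' @export
analysis_groups <- function(samples) {
  samples <- validate_coral_samples(samples)
  ifelse(samples$treatment == "control",
         paste0("control_", samples$porosity_class),
         ifelse(samples$porosity_class == "perforate",
                samples$growth_form, "imperforate"))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of `values` on `groups`, fitted with
#' [stats::lm()]. When the within-group sum of squares is exactly zero but
#' groups differ, the test is degenerate: F is infinite and p is reported
#' as 0 with `degenerate = TRUE`.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @return List with `F`, `df_between`, `df_within`, `p`, `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2) stop("invalid_groups: need at least 2 groups", call. = FALSE)
  n <- length(values)
  if (n - k < 2) {
    stop("invalid_groups: need >= 2 residual degrees of freedom", call. = FALSE)
  }
  # degenerate (perfect-fit) layouts are handled explicitly below, so the
  # perfect-fit warning from anova.lm is redundant here
  tab <- suppressWarnings(stats::anova(stats::lm(values ~ g)))
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  df1 <- tab$Df[1]; df2 <- tab$Df[2]
  tol <- 1e-12 * max(1, sum(values^2))
  if (ssw <= tol) {
    if (ssb <= tol) {
      return(list(F = 0, df_between = df1, df_within = df2, p = 1,
                  degenerate = TRUE))
    }
    return(list(F = Inf, df_between = df1, df_within = df2, p = 0,
                degenerate = TRUE))
  }
  list(F = tab$`F value`[1], df_between = df1, df_within = df2,
       p = tab$`Pr(>F)`[1], degenerate = FALSE)
}

#' Tukey honest-significant-difference post-hoc test
#'
#' Pairwise comparisons after a one-way ANOVA via [stats::TukeyHSD()]
#' (studentized-range distribution on the pooled within-group variance).
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A data.frame with columns `group1`, `group2`, `diff` (mean of
#'   group2 minus mean of group1), `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  stopifnot(is.numeric(values), length(values) == length(groups),
            alpha > 0, alpha < 1)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("invalid_groups: need at least 2 groups", call. = FALSE)
  if (length(values) - nlevels(g) < 2) {
    stop("invalid_groups: need >= 2 residual degrees of freedom", call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  ssw <- sum(stats::residuals(fit)^2)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- do.call(rbind, strsplit(rownames(hsd), "-", fixed = TRUE))
  out <- data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                    diff = hsd[, "diff"], lwr = hsd[, "lwr"],
                    upr = hsd[, "upr"], p_adj = hsd[, "p adj"],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (ssw <= 1e-12 * max(1, sum(values^2))) {
    # zero pooled variance: any real difference is infinitely significant;
    # differences at rounding-noise scale are no difference at all
    tiny <- abs(out$diff) <= 1e-8 * max(1, max(abs(values)))
    out$diff[tiny] <- 0
    out$p_adj <- ifelse(tiny, 1, 0)
  }
  out$significant <- out$p_adj < alpha
  out
}

#' Fit the exponential surface-area-dissolution model
#'
#' Least-squares fit of `loss = -k_amp * exp(k_exp * surface_area)` by
#' Gauss-Newton iteration with step halving. Starting values come from an
#' ordinary regression of `log(-loss)` on surface area over the strictly
#' negative losses; the refinement then uses all points, so samples that
#' gained weight still inform the fit.
#'
#' @param surface_area Surface areas in cm^2, strictly positive, not all equal.
#' @param loss Weight change in g (negative while dissolving), same length.
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance on the relative parameter change
#'   (default 1e-10).
#' @return An object of class `exp_loss_fit`: `k_amp`, `k_exp`, standard
#'   errors `se_k_amp` and `se_k_exp`, `rss`, `n`, `converged`, `iterations`.
#' @examples
#' sa <- seq(40, 240, by = 40)
#' fit_exponential_loss(sa, -0.005 * exp(0.017 * sa))
#' @export
fit_exponential_loss <- function(surface_area, loss, max_iter = 200,
                                 tol = 1e-10) {
  stopifnot(is.numeric(surface_area), is.numeric(loss),
            length(surface_area) == length(loss))
  n <- length(loss)
  if (n < 3) stop("invalid_fit_input: need at least 3 points", call. = FALSE)
  if (any(surface_area <= 0)) {
    stop("invalid_fit_input: surface areas must be strictly positive",
         call. = FALSE)
  }
  if (length(unique(surface_area)) < 2) {
    stop("invalid_fit_input: surface areas must not all be equal",
         call. = FALSE)
  }
  neg <- loss < 0
  if (sum(neg) < 2) {
    stop("degenerate_losses: need at least 2 strictly negative losses ",
         "for log-initialization", call. = FALSE)
  }
  init <- stats::lm(log(-loss[neg]) ~ surface_area[neg])
  theta <- c(k_amp = exp(unname(stats::coef(init)[1])),
             k_exp = unname(stats::coef(init)[2]))

  model <- function(th) -th[1] * exp(th[2] * surface_area)
  rss_of <- function(th) sum((loss - model(th))^2)
  rss <- rss_of(theta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    e <- exp(theta[2] * surface_area)
    r <- loss - (-theta[1] * e)
    J <- cbind(-e, -theta[1] * surface_area * e)  # d(model)/d(theta)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(err) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    repeat {
      cand <- theta + lambda * as.numeric(step)
      if (cand[1] > 0 && rss_of(cand) <= rss) break
      lambda <- lambda / 2
      if (lambda < 1e-12) { cand <- theta; break }
    }
    rel <- max(abs(cand - theta) / pmax(abs(theta), 1e-12))
    theta <- cand
    rss <- rss_of(theta)
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      class = c("fit_no_convergence", "error", "condition"),
      list(message = paste0("fit_no_convergence: Gauss-Newton did not ",
                            "converge within ", max_iter, " iterations"),
           call = sys.call(-1),
           last_iterate = list(k_amp = unname(theta[1]),
                               k_exp = unname(theta[2]), rss = rss)))
    stop(cond)
  }
  e <- exp(theta[2] * surface_area)
  J <- cbind(-e, -theta[1] * surface_area * e)
  sigma2 <- rss / (n - 2)
  covm <- tryCatch(sigma2 * solve(crossprod(J)),
                   error = function(err) matrix(NA_real_, 2, 2))
  structure(
    list(k_amp = unname(theta[1]), k_exp = unname(theta[2]),
         se_k_amp = sqrt(covm[1, 1]), se_k_exp = sqrt(covm[2, 2]),
         rss = rss, n = n, converged = converged, iterations = iter),
    class = "exp_loss_fit")
}

#' @export
print.exp_loss_fit <- function(x, ...) {
  cat("Exponential dissolution model: loss = -k_amp * exp(k_exp * SA)\n")
  cat(sprintf("  k_amp = %.6g g (se %.3g)\n", x$k_amp, x$se_k_amp))
  cat(sprintf("  k_exp = %.6g cm^-2 (se %.3g)\n", x$k_exp, x$se_k_exp))
  cat(sprintf("  RSS = %.4g on n = %d (%d iterations)\n", x$rss, x$n,
              x$iterations))
  invisible(x)
}

#' Predicted loss from an exponential dissolution fit
#'
#' @param object An `exp_loss_fit`.
#' @param surface_area Surface areas (cm^2) at which to predict.
#' @param ... Unused.
#' @return Predicted losses in g (<= 0).
#' @export
predict.exp_loss_fit <- function(object, surface_area, ...) {
  -object$k_amp * exp(object$k_exp * surface_area)
}

#' Family-level porosity reference table
#'
#' The packaged classification of scleractinian coral families into
#' perforate and imperforate skeletons, with species counts per family.
#'
#' @return A data.frame with columns `family`, `n_species`, `porosity`.
#' @export
porosity_reference <- function() {
  path <- system.file("extdata", "coral_family_porosity.csv",
                      package = "reefdiss", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_porosity_table(tab)
}

#' Validate a porosity reference table
#'
#' @param table A data.frame with `family`, `n_species`, `porosity`.
#' @return The validated table.
#' @export
validate_porosity_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("family", "n_species", "porosity") %in% names(table)))
  if (anyDuplicated(tolower(table$family))) {
    stop("invalid_table: duplicate family names", call. = FALSE)
  }
  if (any(table$n_species < 0) || any(table$n_species != round(table$n_species))) {
    stop("invalid_table: species counts must be non-negative integers",
         call. = FALSE)
  }
  if (!all(tolower(table$porosity) %in% .POROSITY_CLASSES)) {
    stop("invalid_table: porosity must be perforate or imperforate",
         call. = FALSE)
  }
  table$porosity <- tolower(table$porosity)
  table
}

#' Species counts per porosity class
#'
#' @param table A porosity reference table (default the packaged one).
#' @return Named numeric vector with elements `perforate` and `imperforate`.
#' @export
species_porosity_counts <- function(table = porosity_reference()) {
  table <- validate_porosity_table(table)
  out <- c(perforate = 0, imperforate = 0)
  for (cls in names(out)) {
    out[cls] <- sum(table$n_species[table$porosity == cls])
  }
  out
}

#' Porosity class of a coral family
#'
#' Case-insensitive exact lookup in the reference table.
#'
#' @param family Family name(s).
#' @param table A porosity reference table (default the packaged one).
#' @return `"perforate"`, `"imperforate"`, or `"unknown"` per family.
#' @export
porosity_class <- function(family, table = porosity_reference()) {
  table <- validate_porosity_table(table)
  idx <- match(tolower(family), tolower(table$family))
  ifelse(is.na(idx), "unknown", table$porosity[idx])
}
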