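test_that("normalized loss and areal rate follow their definitions", {
  s <- make_samples(n = 3, w0 = c(10, 5, 8.40), w1 = c(9.9, 5, 8.3706),
                    surface_area = c(100, 50, 70))
  expect_equal(normalized_loss(s), c(-0.01, 0, -0.0035))
  r <- areal_dissolution_rate(make_samples(
    n = 3, w0 = c(10, 10, 10), w1 = c(10 - 0.0294, 10, 10 - 0.147),
    surface_area = c(100, 100, 50), duration = 7))
  expect_s3_class(r, "areal_mass_rate")
  expect_equal(r$value, c(-4.2e-5, 0, -4.2e-4))
  expect_identical(c(r$mass_unit, r$area_unit, r$time_unit), c("g", "cm2", "d"))
})

test_that("loss measures are order-invariant and linear in the weight change", {
  tab <- simulate_dissolution_experiment(experiment_design(seed = 3))
  perm <- sample(nrow(tab))
  expect_equal(normalized_loss(tab)[perm], normalized_loss(tab[perm, ]))
  expect_equal(areal_dissolution_rate(tab)$value[perm],
               areal_dissolution_rate(tab[perm, ])$value)
  tab2 <- tab
  tab2$w1 <- tab$w0 + 3 * (tab$w1 - tab$w0)
  expect_equal(normalized_loss(tab2), 3 * normalized_loss(tab))
  expect_equal(areal_dissolution_rate(tab2)$value,
               3 * areal_dissolution_rate(tab)$value)
})

test_that("sample validation rejects bad rows with addressed messages", {
  s <- make_samples(n = 2)
  expect_silent(validate_coral_samples(s))
  s_bad <- s; s_bad$w0[2] <- 0
  expect_error(validate_coral_samples(s_bad), "row\\(s\\) 2.*w0")
  s_bad <- s; s_bad$surface_area <- NULL
  expect_error(validate_coral_samples(s_bad), "schema_error.*surface_area")
  s_bad <- s; s_bad$growth_form[1] <- "massive"
  expect_error(validate_coral_samples(s_bad), "growth_form")
})

test_that("group summary reports exact means and sds per group", {
  s <- rbind(make_samples(n = 3, w0 = 10, w1 = 10 + c(-0.1, -0.2, -0.3)),
             make_samples(n = 3, w0 = 10, w1 = 10,
                          porosity_class = "imperforate", genus = "Pectinia"))
  out <- group_summary(s, by = "porosity_class")
  out <- out[order(out$porosity_class), ]
  expect_equal(out$mean_loss, c(0, -0.02))  # imperforate, perforate
  expect_equal(out$n, c(3L, 3L))
  one <- group_summary(make_samples(n = 2, w0 = 10, w1 = 9), by = "treatment")
  expect_equal(one$mean_loss, -0.1)
  expect_equal(one$sd_loss, 0)
  expect_error(group_summary(make_samples(n = 0)), "empty_input|row")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5, SSW = 4, F = 1.5 on (1, 4)
  res <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 1.5)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  # oracle: p from the t^2 = F relation with 4 df
  expect_equal(res$p, 2 * (1 - stats::pt(sqrt(1.5), 4)), tolerance = 1e-10)
  expect_false(res$degenerate)
  # identical means, equal spread: F small, p large
  res2 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res2$F, 0)
  expect_gt(res2$p, 0.9)
  # all observations equal: SSB = 0 -> F = 0, p = 1
  res3 <- one_way_anova(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res3$F, 0)
  expect_equal(res3$p, 1)
  expect_true(res3$degenerate)
  # groups differ but zero within variance: degenerate, p = 0
  res4 <- one_way_anova(rep(c(0, 1), each = 3), rep(c("a", "b"), each = 3))
  expect_equal(res4$p, 0)
  expect_true(res4$degenerate)
  expect_error(one_way_anova(1:5, rep("a", 5)), "invalid_groups")
})

test_that("ANOVA F is invariant under affine response transformations", {
  set.seed(11)
  for (i in seq_len(5)) {
    v <- stats::rnorm(15)
    g <- sample(letters[1:3], 15, replace = TRUE)
    if (length(unique(g)) < 2) next
    f0 <- one_way_anova(v, g)$F
    expect_equal(one_way_anova(v + 7.3, g)$F, f0, tolerance = 1e-9)
    expect_equal(one_way_anova(v * 2.5, g)$F, f0, tolerance = 1e-9)
  }
})

test_that("Tukey HSD agrees with a studentized-range integration oracle", {
  v <- c(1, 2, 3, 2, 3, 4, 1, 2, 3)
  g <- rep(c("a", "b", "c"), each = 3)
  out <- tukey_hsd(v, g)
  expect_equal(nrow(out), 3)
  msw <- 1  # each group has variance 1
  for (i in seq_len(nrow(out))) {
    d <- abs(out$diff[i])
    p_oracle <- if (d == 0) 1 else 1 - ptukey_oracle(d / sqrt(msw / 3), 3, 6)
    expect_equal(out$p_adj[i], p_oracle, tolerance = 1e-3)
  }
})

test_that("Tukey HSD handles separation and degenerate spread", {
  # wide separation with tiny jitter: significant at alpha = 0.05
  set.seed(2)
  v <- c(rnorm(4, 0, 1e-3), rnorm(4, 10, 1e-3))
  out <- tukey_hsd(v, rep(c("a", "b"), each = 4))
  expect_true(all(out$significant))
  # identical values within groups, equal means: nothing significant
  out2 <- tukey_hsd(rep(2, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(all(out2$p_adj == 1))
  expect_false(any(out2$significant))
  # identical within groups, different means: infinitely significant
  out3 <- tukey_hsd(rep(c(0, 1, 1), each = 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(out3$p_adj[out3$diff != 0], c(0, 0))
})

test_that("Tukey adjusted p is never below the unadjusted pairwise-t p", {
  set.seed(13)
  for (rep_i in seq_len(10)) {
    k <- sample(3:5, 1)
    ns <- sample(3:6, k, replace = TRUE)
    g <- rep(letters[1:k], ns)
    v <- stats::rnorm(length(g), mean = as.integer(factor(g)) * 0.5)
    out <- tukey_hsd(v, g)
    fit <- stats::aov(v ~ factor(g))
    msw <- sum(stats::residuals(fit)^2) / fit$df.residual
    means <- tapply(v, g, mean)
    nn <- tapply(v, g, length)
    for (i in seq_len(nrow(out))) {
      se <- sqrt(msw * (1 / nn[out$group1[i]] + 1 / nn[out$group2[i]]))
      p_t <- 2 * (1 - stats::pt(abs(out$diff[i]) / se, fit$df.residual))
      expect_gte(out$p_adj[i] + 1e-10, p_t)
    }
  }
})

test_that("exponential fit recovers coefficients exactly on noiseless data", {
  sa <- seq(40, 240, by = 40)
  fit <- fit_exponential_loss(sa, -0.005 * exp(0.017 * sa))
  expect_equal(fit$k_amp, 0.005, tolerance = 1e-6)
  expect_equal(fit$k_exp, 0.017, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # property: recovery for random coefficients over k_exp in [0.001, 0.05]
  set.seed(21)
  for (i in seq_len(20)) {
    ka <- 10^stats::runif(1, -3, -1.5)
    ke <- stats::runif(1, 0.001, 0.05)
    sa_i <- sort(stats::runif(12, 20, 250))
    fit_i <- fit_exponential_loss(sa_i, -ka * exp(ke * sa_i))
    expect_equal(fit_i$k_amp, ka, tolerance = 1e-6)
    expect_equal(fit_i$k_exp, ke, tolerance = 1e-6)
  }
})

test_that("exponential fit matches an independent nonlinear least-squares oracle", {
  skip_if_not_installed("minpack.lm")
  set.seed(5)
  sa <- stats::runif(40, 20, 250)
  loss <- -0.005 * exp(0.017 * sa) + stats::rnorm(40, 0, 0.01)
  fit <- fit_exponential_loss(sa, loss)
  ref <- minpack.lm::nlsLM(loss ~ -ka * exp(ke * sa),
                           start = list(ka = 0.01, ke = 0.01))
  expect_equal(fit$k_amp, unname(stats::coef(ref)["ka"]), tolerance = 1e-6)
  expect_equal(fit$k_exp, unname(stats::coef(ref)["ke"]), tolerance = 1e-6)
})

test_that("noisy parameter recovery stays within 10% for the exponent", {
  set.seed(1)
  sa <- stats::runif(50, 20, 250)
  loss <- -0.005 * exp(0.017 * sa) + stats::rnorm(50, 0, 0.01)
  fit <- fit_exponential_loss(sa, loss)
  expect_lt(abs(fit$k_exp / 0.017 - 1), 0.10)
})

test_that("exponential fit rejects degenerate inputs", {
  expect_error(fit_exponential_loss(c(10, 20, 30), c(0, 0, 0)),
               "degenerate_losses")
  expect_error(fit_exponential_loss(c(10, 20, 30), c(-1, 0, 0)),
               "degenerate_losses")
  expect_error(fit_exponential_loss(c(10, 20), c(-1, -2)), "invalid_fit_input")
  expect_error(fit_exponential_loss(c(10, 10, 10), c(-1, -2, -3)),
               "invalid_fit_input")
  expect_error(fit_exponential_loss(c(-1, 20, 30), c(-1, -2, -3)),
               "invalid_fit_input")
  # samples that gained weight are retained (fit still succeeds)
  sa <- seq(40, 240, by = 40)
  loss <- -0.005 * exp(0.017 * sa)
  loss[1] <- 0.002
  expect_s3_class(fit_exponential_loss(sa, loss), "exp_loss_fit")
})

test_that("packaged porosity table reproduces the global species counts", {
  counts <- species_porosity_counts()
  expect_equal(unname(counts["perforate"]), 404)
  expect_equal(unname(counts["imperforate"]), 432)
  empty <- data.frame(family = character(), n_species = integer(),
                      porosity = character())
  expect_equal(unname(species_porosity_counts(empty)), c(0, 0))
})

test_that("family porosity lookup is case-insensitive with unknown fallback", {
  expect_equal(porosity_class("Acroporidae"), "perforate")
  expect_equal(porosity_class("faviidae"), "imperforate")
  expect_equal(porosity_class("Pectiniidae"), "imperforate")
  expect_equal(porosity_class("NotAFamily"), "unknown")
  expect_equal(porosity_class(c("Poritidae", "Mussidae", "x")),
               c("perforate", "imperforate", "unknown"))
  bad <- data.frame(family = c("A", "a"), n_species = c(1, 2),
                    porosity = c("perforate", "perforate"))
  expect_error(validate_porosity_table(bad), "duplicate")
})
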