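test_that("reef model right-hand side follows the two readings", {
  # constant mode with the perforate inputs: 7 + 1 - 10.5 = -2.5 mm/y
  p <- reef_model_params(a = 7, D = 10.5, mode = "constant")
  expect_equal(reef_rhs(50, p), -2.5)
  # no-dissolution limit: a + b*S in either mode
  expect_equal(reef_rhs(1, reef_model_params(a = 3, D = 0)), 4)
  expect_equal(reef_rhs(5, reef_model_params(a = 3, D = 0, mode = "literal")), 4)
  # literal mode: dissolution damped by accumulated framework
  pl <- reef_model_params(a = 7, D = 10.5, mode = "literal")
  expect_equal(reef_rhs(10.5, pl), 7 + 1 - 1)
  expect_equal(reef_rhs(1e9, pl), 8, tolerance = 1e-6)
  expect_error(reef_rhs(-1, pl), "invalid_state")
  expect_error(reef_model_params(a = 7, D = -1), "invalid_params")
  expect_error(reef_model_params(a = 7, A0 = 0, mode = "literal"),
               "invalid_params")
})

test_that("constant-mode trajectories are exactly linear under RK4", {
  # a = 7, b*S = 1, no dissolution, 10 years: +80 mm exactly
  tr <- integrate_reef(reef_model_params(a = 7, D = 0), 1990, 2000, 0.1)
  expect_equal(tr$value[nrow(tr)] - tr$value[1], 80)
  expect_equal(unique(round(diff(tr$value), 9)), 8)
  # net -2.5 mm/y over 110 years: -275 mm
  tr2 <- integrate_reef(reef_model_params(a = 7, D = 10.5), 1990, 2100, 0.1)
  expect_equal(tr2$value[nrow(tr2)] - tr2$value[1], -275, tolerance = 1e-9)
})

test_that("literal-mode RK4 converges at fourth order", {
  p <- reef_model_params(a = 0.5, D = 40, A0 = 60, mode = "literal")
  final <- function(h) {
    tr <- integrate_reef(p, 1990, 2010, h)
    tr$value[nrow(tr)]
  }
  d1 <- final(1) - final(0.5)
  d2 <- final(0.5) - final(0.25)
  expect_gt(abs(d1 / d2), 12)
  expect_lt(abs(d1 / d2), 20)
})

test_that("framework exhaustion is flagged, not fatal", {
  p <- reef_model_params(a = 0, b = 0, S = 0, D = 50, A0 = 20,
                         mode = "literal")
  tr <- integrate_reef(p, 1990, 2010, 0.1)
  expect_true(attr(tr, "framework_exhausted"))
  expect_true(all(tr$value >= p$floor_mm))
  ok <- integrate_reef(reef_model_params(a = 7, D = 0, mode = "literal"),
                       1990, 2000, 0.1)
  expect_false(attr(ok, "framework_exhausted"))
})

test_that("keep-up reports classify reefs against sea level", {
  yrs <- 1990:2100
  reef8 <- trajectory(yrs, 100 + 8 * (yrs - 1990), "reef_elevation")
  flat <- trajectory(yrs, rep(0, length(yrs)), "sea_level")
  rep1 <- keep_up_report(reef8, flat)
  expect_true(rep1$keeps_up)
  expect_true(is.na(rep1$rate_crossover_year))
  expect_true(is.na(rep1$submergence_year))
  # stalled reef under rising seas: crossover at the first year
  reef0 <- trajectory(yrs, rep(100, length(yrs)), "reef_elevation")
  rising <- parametric_sea_level(900, 1)
  rep2 <- keep_up_report(reef0, rising)
  expect_false(rep2$keeps_up)
  expect_equal(rep2$rate_crossover_year, 1990)
  expect_equal(rep2$submergence_year, 1991)
  expect_error(keep_up_report(
    trajectory(1900:1910, rep(0, 11), "reef_elevation"), rising),
    "span_error")
})

test_that("imperforate high-cover reefs lose the rate race mid-century", {
  # net 8 mm/y (7 + 1 - 0) against the accelerating highest-emission curve;
  # closed form: rate crossing at 1990 + 8 * 110^2 / (2 * 900) ~ 2043.8
  reef <- integrate_reef(reef_model_params(a = 7, D = 0), 1990, 2100, 0.1)
  sea <- parametric_sea_level(900, 2)
  rep <- keep_up_report(reef, sea)
  expect_equal(rep$rate_crossover_year, 2044)
  expect_gte(rep$rate_crossover_year, 2040)
  expect_lte(rep$rate_crossover_year, 2060)
})

test_that("crossover year grows with the net accretion rate", {
  sea <- parametric_sea_level(900, 2)
  years <- sapply(c(1, 2, 4, 6, 8, 10), function(net) {
    reef <- integrate_reef(reef_model_params(a = net, b = 0, S = 0, D = 0),
                           1990, 2100, 0.1)
    keep_up_report(reef, sea)$rate_crossover_year
  })
  expect_true(all(diff(years) >= 0))
})

test_that("reefs outpacing the fastest sea-level rise always keep up", {
  sea <- parametric_sea_level(500, 1)  # constant ~4.5 mm/y
  max_rate <- max(diff(sea$value))
  reef <- integrate_reef(reef_model_params(a = max_rate + 2, b = 1, S = 1,
                                           D = 0), 1990, 2100, 0.1)
  rep <- keep_up_report(reef, sea)
  expect_true(rep$keeps_up)
})

test_that("the default scenario matrix covers 18 combinations", {
  mat <- scenario_matrix()
  expect_equal(nrow(mat), 18)
  expect_equal(nrow(unique(mat[c("density", "porosity", "scenario")])), 18)
  # perforate rows: net rate 7 + 1 - 10.55 < 0 at best, never keep up
  perf <- mat[mat$porosity == "perforate", ]
  expect_true(all(perf$net_rate < 0))
  expect_false(any(perf$keeps_up))
  trajs <- attr(mat, "trajectories")
  expect_equal(length(trajs), 18)
  for (key in grep("perforate", names(trajs), value = TRUE)) {
    if (grepl("imperforate", key)) next
    expect_true(all(diff(trajs[[key]]$reef$value) < 0))
  }
  # imperforate high density crosses over mid-century; lower density earlier
  imp <- mat[mat$porosity == "imperforate" & mat$scenario == "A1FI", ]
  imp <- imp[order(imp$a), ]
  expect_true(all(diff(imp$rate_crossover_year) > 0))
  hi <- imp[imp$density == "high", ]
  expect_gte(hi$rate_crossover_year, 2040)
  expect_lte(hi$rate_crossover_year, 2060)
})
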