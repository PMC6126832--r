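test_that("closed-form expected efficiency matches Monte Carlo and is monotone", {
  expect_equal(te_closed_form(0), 1)
  expect_equal(te_closed_form(1), 2 * exp(0.5) * pnorm(-1), tolerance = 1e-12)
  expect_equal(te_closed_form(1), 0.5232, tolerance = 1e-4)
  set.seed(21)
  u <- abs(rnorm(1e5))
  mc <- mean(exp(-u))
  se <- sd(exp(-u)) / sqrt(1e5)
  expect_lt(abs(mc - te_closed_form(1)), 3 * se)
  # strictly decreasing on a grid, bounded in (0, 1]
  grid <- seq(0, 5, by = 0.1)
  v <- te_closed_form(grid)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 1))
  # large scales stay finite through the log-scale evaluation
  expect_true(is.finite(te_closed_form(40)))
})

test_that("the variance ratio reproduces the published values", {
  expect_equal(round(variance_ratio_gamma(2.301, 0.142), 4), 0.9419)
  expect_equal(round(variance_ratio_gamma(0.439, 0.141), 4), 0.7569)
  expect_equal(variance_ratio_gamma(1, 1), 0.5)
  expect_equal(variance_ratio_gamma(c(1, 2), c(1, 2)), c(0.5, 0.5))
  expect_error(variance_ratio_gamma(-1, 1), "positive")
  expect_error(variance_ratio_gamma(1, 0), "positive")
})

test_that("single-input slack follows the contraction formula", {
  expect_equal(slack_amount(10, 0, 0.4), 0)
  expect_equal(slack_amount(10, 0.3, 0.397), 10 * (1 - exp(-0.3 / 0.397)),
               tolerance = 1e-12)
  expect_equal(slack_amount(10, 0.3, 0.397), 5.304, tolerance = 1e-3)
  # increasing in u, decreasing in beta, never exceeding the input level
  us <- seq(0, 3, by = 0.2)
  s_u <- slack_amount(10, us, 0.4)
  expect_true(all(diff(s_u) > 0))
  bs <- seq(0.1, 2, by = 0.1)
  s_b <- slack_amount(10, 0.5, bs)
  expect_true(all(diff(s_b) < 0))
  expect_true(all(slack_amount(10, c(us, 1e6), 0.4) <= 10))
  expect_error(slack_amount(10, 0.3, -0.1), "elasticities")
  expect_error(slack_amount(10, -0.3, 0.1), "non-negative")
})

test_that("technical efficiency and slack invariants hold on a fitted model", {
  fit <- get_small_fit()
  te <- technical_efficiency(fit)
  expect_true(all(te$te > 0 & te$te <= 1))
  expect_equal(attr(te, "te_overall"), mean(te$te))
  # draw-averaged and closed-form TE agree within Monte-Carlo error
  te_cf <- technical_efficiency(fit, method = "closed_form")
  expect_equal(attr(te, "te_overall"), attr(te_cf, "te_overall"),
               tolerance = 0.03)
  # per-observation values differ by construction (conditional vs
  # unconditional inefficiency) but must agree in ordering tendency
  expect_gt(cor(te$te, te_cf$te), 0.5)
  # gamma strictly inside (0, 1)
  g <- posterior_gamma(fit)
  expect_true(all(g > 0 & g < 1))
  # slack draws stay inside [0, x]
  s <- suppressWarnings(slack_resources(fit, "mort30d"))
  expect_true(all(s$slack >= 0 & s$slack <= attr(s, "x_level")))
  sp <- suppressWarnings(slack_resources(fit, "mort30d",
                                         at = "per_observation"))
  expect_true(all(sp$slack >= 0 & sp$slack <= sp$x))
  # national totals are exact sums of per-observation slacks
  tot <- attr(sp, "totals")
  manual <- tapply(sp$slack, sp$year, sum)
  expect_equal(tot$total_slack, as.numeric(manual[as.character(tot$year)]))
})

test_that("marginal TE effects: zero at zero, derivative matches finite differences, signs oppose delta", {
  fit <- get_small_fit()
  # zero coefficient implies exactly zero effect
  fit0 <- fit
  fit0$draws$delta[, "SUCert"] <- 0
  expect_equal(marginal_effect_te(fit0, "SUCert", mode = "derivative")$effect, 0)
  expect_equal(marginal_effect_te(fit0, "SUCert", mode = "discrete")$effect, 0)
  expect_equal(marginal_effect_slack(fit0, "SUCert", "mort30d",
                                     mode = "derivative")$effect, 0)
  # derivative mode equals a central finite difference of E[TE](z_j)
  ev_te <- function(fit, name, z) {
    d <- fit$draws$delta[, name]
    s <- sqrt(fit$draws$variances[, "sigma_ustar2"])
    zb <- fit$design$zbar[name]
    mean(te_closed_form(s * exp(d * (z - zb))))
  }
  h <- 1e-5
  for (nm in c("MedDepCon", "log_HosBed")) {
    zb <- fit$design$zbar[nm]
    fd <- (ev_te(fit, nm, zb + h) - ev_te(fit, nm, zb - h)) / (2 * h) * 100
    an <- marginal_effect_te(fit, nm, mode = "derivative")$effect
    expect_equal(an, fd, tolerance = 1e-6)
  }
  # sign(marginal TE effect) = -sign(posterior mean delta), all covariates
  me <- marginal_effects(fit)
  dm <- colMeans(fit$draws$delta)
  expect_equal(sign(me$te_x100), -sign(dm[me$covariate]),
               ignore_attr = TRUE)
  # slack effects carry the opposite sign of the TE effect
  for (inp in c("mort30d", "readm30d")) {
    expect_equal(sign(me[[inp]]), -sign(me$te_x100), ignore_attr = TRUE)
  }
  expect_error(marginal_effect_te(fit, "NotACovariate"), "not in the")
})

test_that("slack marginal effects match finite differences", {
  fit <- get_small_fit()
  ev_slack <- function(name, z, input = "mort30d") {
    map <- geosfa:::input_coef_map()
    row <- map[map$input == input, ]
    bk <- fit$draws$beta[, row$coef]
    ok <- bk > 0
    d <- fit$draws$delta[ok, name]
    s <- sqrt(fit$draws$variances[ok, "sigma_ustar2"])
    zb <- fit$design$zbar[name]
    xbar <- mean(fit$panel[[row$level]])
    mean(slack_amount(xbar, s * exp(d * (z - zb)) * sqrt(2 / pi), bk[ok]))
  }
  h <- 1e-5
  nm <- "MedDepCon"
  zb <- fit$design$zbar[nm]
  fd <- (ev_slack(nm, zb + h) - ev_slack(nm, zb - h)) / (2 * h)
  an <- marginal_effect_slack(fit, nm, "mort30d", mode = "derivative")$effect
  expect_equal(an, fd, tolerance = 1e-6)
})

test_that("scenario extrapolation reports raw, rounded and truncated totals", {
  s1 <- scenario_savings(0.401, 937)
  expect_equal(s1$raw, 375.737)
  expect_equal(s1$rounded, 376)
  s2 <- scenario_savings(0.927, 937)
  expect_equal(s2$raw, 868.599)
  expect_equal(s2$truncated, 868)
  expect_equal(scenario_savings(0, 1000)$raw, 0)
  expect_error(scenario_savings(-1, 10), "non-negative")
})

test_that("an effects report bundles the post-estimation layer", {
  fit <- get_small_fit()
  eff <- suppressWarnings(compute_effects(fit))
  expect_s3_class(eff, "effects_report")
  expect_true(eff$te_overall > 0 && eff$te_overall <= 1)
  expect_true(eff$gamma > 0 && eff$gamma < 1)
  expect_equal(nrow(eff$marginal), ncol(fit$draws$delta))
  expect_true(all(c("te_x100", "mort30d") %in% names(eff$marginal)))
})
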