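test_that("stored-draw bookkeeping follows the protocol arithmetic", {
  expect_equal(n_stored_draws(120000, 20000, 100), 1000)
  expect_equal(n_stored_draws(12000, 2000, 10), 1000)
  expect_error(mcmc_control(iterations = 100, burnin = 200), "smaller")
  expect_warning(mcmc_control(iterations = 1000, burnin = 100, thin = 7),
                 "multiple")
})

test_that("identical seeds give bitwise-identical stored draws", {
  sim <- get_small_sim()
  pp <- prepare_panel(sim$panel)
  ctrl <- mcmc_control(iterations = 220, burnin = 20, thin = 2, seed = 77)
  f1 <- suppressWarnings(fit_sfa(pp, sim$graph,
                                 sfa_preset("model2", mcmc = ctrl)))
  f2 <- suppressWarnings(fit_sfa(pp, sim$graph,
                                 sfa_preset("model2", mcmc = ctrl)))
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$delta, f2$draws$delta)
  expect_identical(f1$draws$u_star, f2$draws$u_star)
  expect_identical(f1$draws$variances, f2$draws$variances)
  f3 <- suppressWarnings(
    fit_sfa(pp, sim$graph,
            sfa_preset("model2", mcmc = mcmc_control(
              iterations = 220, burnin = 20, thin = 2, seed = 78))))
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("with known variances and no inefficiency the coefficient posterior is the conjugate Gaussian", {
  set.seed(9)
  n <- 2
  y <- c(0.8, -0.3)
  p <- y_only_panel(y)
  sv2 <- 0.25
  spec <- plain_spec(mcmc_control(iterations = 4200, burnin = 200, thin = 1,
                                  seed = 5,
                                  fixed = list(sigma_v2 = sv2,
                                               sigma_ustar2 = 1e-12,
                                               u_star = rep(0, n))))
  fit <- fit_sfa(p, NULL, spec)
  b <- fit$draws$beta[, "const"]
  # closed form with a flat prior: N(mean(y), sv2 / n)
  expect_lt(abs(mean(b) - mean(y)), 3 * sqrt(sv2 / n) / sqrt(4000))
  expect_lt(abs(sd(b) - sqrt(sv2 / n)), 0.02)
})

test_that("a plain half-normal frontier is recovered within posterior uncertainty", {
  set.seed(31)
  n <- 500
  b0 <- 1.5
  sv <- 0.3
  su <- 1.0
  y <- b0 + rnorm(n, 0, sv) - abs(rnorm(n, 0, su))
  p <- y_only_panel(y)
  spec <- plain_spec(mcmc_control(iterations = 4000, burnin = 1000,
                                  thin = 10, seed = 6))
  fit <- fit_sfa(p, NULL, spec)
  tb <- tidy(fit, "beta")
  tv <- tidy(fit, "variances")
  expect_gt(tb$conf.high[tb$term == "const"], b0 - 0.2)
  expect_lt(tb$conf.low[tb$term == "const"], b0 + 0.2)
  sv2_row <- tv[tv$term == "sigma_v2", ]
  su2_row <- tv[tv$term == "sigma_ustar2", ]
  expect_true(sv2_row$conf.low < sv^2 && sv^2 < sv2_row$conf.high + 0.05)
  expect_true(su2_row$conf.low - 0.1 < su^2 && su^2 < su2_row$conf.high + 0.3)
  # posterior means land in a sensible neighbourhood of the truth
  expect_equal(tb$estimate[tb$term == "const"], b0, tolerance = 0.15,
               ignore_attr = TRUE)
  expect_equal(su2_row$estimate, su^2, tolerance = 0.35, ignore_attr = TRUE)
})

test_that("DIC and WAIC match brute-force two-pass computations", {
  # hand-built miniature fit: 100 distinct draws, 3 observations
  set.seed(8)
  y <- c(0.2, -0.5, 1.0)
  p <- y_only_panel(y)
  spec <- plain_spec(mcmc_control(iterations = 10, burnin = 1, thin = 1))
  S <- 100
  beta <- matrix(rnorm(S, 0, 0.2), S, 1, dimnames = list(NULL, "const"))
  variances <- cbind(sigma_v2 = runif(S, 0.2, 0.3),
                     sigma_ustar2 = runif(S, 0.4, 0.6),
                     tau2_struct = 1, tau2_unstruct = 1, tau2_hospital = 1)
  fit <- structure(list(
    draws = list(beta = beta,
                 delta = matrix(numeric(0), S, 0),
                 f_struct = NULL, f_unstruct = NULL, h = NULL,
                 u_star = matrix(0.3, S, 3),
                 variances = variances),
    spec = spec, n_obs = 3, panel = p,
    design = list(X = matrix(1, 3, 1, dimnames = list(NULL, "const")),
                  Z = matrix(numeric(0), 3, 0), zbar = numeric(0)),
    fingerprint = "toy", seed = 1), class = "sfa_fit")
  # brute force with the density written out by hand
  logdens <- function(e, sv2, su) {
    sc <- sqrt(sv2 + su^2)
    log(2 / sc * dnorm(e / sc) * pnorm(-e * (su / sqrt(sv2)) / sc))
  }
  lp <- matrix(NA_real_, S, 3)
  for (s in 1:S) for (i in 1:3) {
    lp[s, i] <- logdens(y[i] - beta[s, 1], variances[s, "sigma_v2"],
                        sqrt(variances[s, "sigma_ustar2"]))
  }
  lppd <- sum(log(colMeans(exp(lp))))
  p_waic <- sum(apply(lp, 2, var))
  waic_manual <- -2 * (lppd - p_waic)
  dev <- -2 * rowSums(lp)
  dbar <- mean(dev)
  theta_bar_ll <- sum(vapply(1:3, function(i) {
    logdens(y[i] - mean(beta), mean(variances[, "sigma_v2"]),
            sqrt(mean(variances[, "sigma_ustar2"])))
  }, numeric(1)))
  pd_manual <- dbar - (-2 * theta_bar_ll)
  w <- compute_waic(fit)
  d <- compute_dic(fit)
  expect_equal(w$WAIC, waic_manual, tolerance = 1e-10)
  expect_equal(w$p_waic, p_waic, tolerance = 1e-10)
  expect_equal(d$Dbar, dbar, tolerance = 1e-10)
  expect_equal(d$p_D, pd_manual, tolerance = 1e-10)
  expect_equal(d$DIC, dbar + pd_manual, tolerance = 1e-10)
  # the draw-count guard rejects degenerate short chains
  fit5 <- fit
  fit5$draws$beta <- beta[1:5, , drop = FALSE]
  expect_error(compute_waic(fit5), "100")
})

test_that("a point-mass posterior has zero effective parameters", {
  y <- c(0.2, -0.5, 1.0)
  p <- y_only_panel(y)
  spec <- plain_spec(mcmc_control(iterations = 10, burnin = 1, thin = 1))
  fit <- structure(list(
    draws = list(beta = matrix(0.1, 120, 1, dimnames = list(NULL, "const")),
                 delta = matrix(numeric(0), 120, 0),
                 f_struct = NULL, f_unstruct = NULL, h = NULL,
                 u_star = matrix(0.3, 120, 3),
                 variances = cbind(sigma_v2 = rep(0.25, 120),
                                   sigma_ustar2 = 0.5, tau2_struct = 1,
                                   tau2_unstruct = 1, tau2_hospital = 1)),
    spec = spec, n_obs = 3, panel = p,
    design = list(X = matrix(1, 3, 1, dimnames = list(NULL, "const")),
                  Z = matrix(numeric(0), 3, 0), zbar = numeric(0)),
    fingerprint = "toy", seed = 1), class = "sfa_fit")
  d <- compute_dic(fit)
  w <- compute_waic(fit)
  expect_equal(d$p_D, 0, tolerance = 1e-10)
  expect_equal(d$DIC, d$Dbar, tolerance = 1e-10)
  expect_equal(w$p_waic, 0, tolerance = 1e-10)
})

test_that("chain diagnostics flag healthy and degenerate chains sensibly", {
  set.seed(4)
  x <- rnorm(1000)
  expect_lt(abs(geosfa:::split_rhat(x) - 1), 0.02)
  expect_gt(geosfa:::ess_imse(x), 500)
  # strongly autocorrelated chain: far fewer effective draws
  ar <- as.numeric(stats::filter(rnorm(1000), 0.98, method = "recursive"))
  expect_lt(geosfa:::ess_imse(ar), 200)
  fit <- get_small_fit()
  dg <- mcmc_diagnostics(fit, ess_warn = 0)
  expect_true(all(is.finite(dg$rhat)))
  expect_true(all(dg$ess >= 1))
  expect_true(any(grepl("^delta", dg$parameter)))
})
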