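model2_state <- function(panel, spec, graph = NULL) {
  X <- frontier_design(panel, spec)
  Z <- inefficiency_design(panel, spec)
  list(beta = setNames(rep(0, ncol(X)), colnames(X)),
       delta = setNames(rep(0, ncol(Z)), colnames(Z)),
       sigma_v2 = 1, sigma_ustar2 = 1)
}

test_that("frontier predictor reproduces published point arithmetic", {
  p <- hospital_panel(tiny_panel_df())
  p <- encode_zero_inputs(p)
  # center continuous inputs so that a mean-level record contributes zero
  p <- center_variables(p, c("log_mort_star", "log_readm_star",
                             "log_phys", "log_nurse"))
  spec <- sfa_model_spec(inefficiency_terms = c("SUCert", "MedDepCon"),
                         label = "t")
  st <- model2_state(p, spec)
  # intercept and zero-mortality dummy from the reported qual&res model
  st$beta["const"] <- 0.470
  st$beta["d_mort"] <- -0.329
  rec <- p[1, ]
  rec$d_mort <- 1
  for (v in c("d_readm", "log_mort_star", "log_readm_star", "log_phys",
              "log_nurse")) rec[[v]] <- 0
  rec$year <- 2006L
  attr(rec, "reference_wave") <- 2006L
  expect_equal(eta_y(st, rec, spec), 0.470 - 0.329)
  # with everything at means in the reference wave: eta_y = const
  rec$d_mort <- 0
  expect_equal(eta_y(st, rec, spec), 0.470)
  expect_error(eta_y(list(beta = c(const = 1)), p, spec), "missing")
})

test_that("translog with zero second-order terms nests Cobb-Douglas", {
  sim <- get_small_sim()
  pp <- prepare_panel(sim$panel)
  cd <- sfa_model_spec(functional_form = "cobb_douglas")
  tl <- sfa_model_spec(functional_form = "translog")
  Xcd <- frontier_design(pp, cd)
  Xtl <- frontier_design(pp, tl)
  expect_true(all(colnames(Xcd) %in% colnames(Xtl)))
  expect_equal(ncol(Xtl) - ncol(Xcd), 10)  # 4 squares + 6 cross products
  st <- list(beta = setNames(rep(0.3, ncol(Xtl)), colnames(Xtl)))
  st$beta[grep("^tl_", names(st$beta))] <- 0
  st_cd <- list(beta = st$beta[colnames(Xcd)])
  expect_equal(eta_y(st, pp, tl), eta_y(st_cd, pp, cd))
  expect_error(sfa_model_spec(frontier_inputs = character(0),
                              functional_form = "translog"),
               "translog")
})

test_that("inefficiency predictor is additive with multiplicative alpha", {
  p <- hospital_panel(tiny_panel_df())
  p <- encode_zero_inputs(p)
  spec <- sfa_model_spec(inefficiency_terms = c("SUCert", "MedDepCon"),
                         spatial = "none",
                         wave_effects_inefficiency = FALSE)
  st <- model2_state(p, spec)
  # all coefficients zero: alpha = 1 everywhere
  expect_equal(exp(eta_u(st, p, spec)), rep(1, nrow(p)))
  # flipping certification multiplies alpha by exp(delta)
  st$delta["SUCert"] <- -1.167
  a0 <- exp(eta_u(st, p, spec))
  p1 <- p
  p1$SUCert <- 1 - p1$SUCert
  a1 <- exp(eta_u(st, p1, spec))
  flip <- ifelse(p$SUCert == 0, exp(-1.167), exp(1.167))
  expect_equal(a1 / a0, flip, tolerance = 1e-12)
  expect_equal(a1[1] / a0[1], 0.3113, tolerance = 1e-3)
  # additivity: joint change equals the sum of single-covariate changes
  st$delta["MedDepCon"] <- 0.4
  pj <- p1
  pj$MedDepCon <- pj$MedDepCon + 0.25
  d_joint <- eta_u(st, pj, spec) - eta_u(st, p, spec)
  pm <- p
  pm$MedDepCon <- pm$MedDepCon + 0.25
  d_sep <- (eta_u(st, p1, spec) - eta_u(st, p, spec)) +
    (eta_u(st, pm, spec) - eta_u(st, p, spec))
  expect_equal(d_joint, d_sep, tolerance = 1e-12)
  # alpha equals the product of per-term exponentials
  Z <- inefficiency_design(p, spec)
  alpha <- exp(eta_u(st, p, spec))
  prod_terms <- exp(Z[, "SUCert"] * st$delta["SUCert"]) *
    exp(Z[, "MedDepCon"] * st$delta["MedDepCon"])
  expect_equal(alpha, unname(prod_terms), tolerance = 1e-12)
})

test_that("conditional likelihood matches hand arithmetic and ignores order", {
  p <- y_only_panel(c(0.5, -0.2, 1.1))
  spec <- plain_spec(mcmc_control(iterations = 10, burnin = 1, thin = 1))
  st <- list(beta = c(const = 0), sigma_v2 = 0.25, sigma_ustar2 = 1,
             u_star = c(0.3, 0.1, 0.2), delta = numeric(0))
  # y set exactly to eta_y - alpha u*: every term is the Gaussian mode
  p0 <- p
  p0$y <- -st$u_star
  expect_equal(loglik_conditional(st, p0, spec),
               3 * (-0.5 * log(2 * pi * 0.25)))
  # one observation with residual 0.5 and sigma_v2 = 0.25
  p1 <- y_only_panel(0.5)
  st1 <- list(beta = c(const = 0), sigma_v2 = 0.25, sigma_ustar2 = 1,
              u_star = 0, delta = numeric(0))
  expect_equal(loglik_conditional(st1, p1, spec),
               -0.5 * log(2 * pi * 0.25) - 0.5)
  # permutation invariance
  perm <- c(3, 1, 2)
  pperm <- p[perm, ]
  stp <- st
  stp$u_star <- st$u_star[perm]
  expect_equal(loglik_conditional(stp, pperm, spec),
               loglik_conditional(st, p, spec))
  expect_error(loglik_conditional(st[-4], p, spec), "u_star")
})

test_that("marginal likelihood agrees with quadrature and normalizes", {
  spec <- plain_spec(mcmc_control(iterations = 10, burnin = 1, thin = 1))
  # quadrature oracle: integrate the conditional density over u* >= 0
  marg_quad <- function(eps, sv2, su) {
    integrate(function(u) {
      dnorm(eps + u * su, 0, sqrt(sv2)) * 2 * dnorm(u)
    }, 0, Inf, rel.tol = 1e-12)$value
  }
  set.seed(7)
  for (k in 1:10) {
    eps <- rnorm(1, 0, 1.5)
    sv2 <- runif(1, 0.05, 1.5)
    su <- runif(1, 0.1, 2.5)
    p <- y_only_panel(eps)
    st <- list(beta = c(const = 0), sigma_v2 = sv2,
               sigma_ustar2 = su^2, delta = numeric(0))
    expect_equal(loglik_marginal(st, p, spec), log(marg_quad(eps, sv2, su)),
                 tolerance = 1e-8)
  }
  # vanishing inefficiency scale reduces to the Gaussian likelihood
  st0 <- list(beta = c(const = 0), sigma_v2 = 0.3, sigma_ustar2 = 1e-18,
              delta = numeric(0))
  p <- y_only_panel(c(0.4, -0.6))
  expect_equal(loglik_marginal(st0, p, spec),
               sum(dnorm(c(0.4, -0.6), 0, sqrt(0.3), log = TRUE)),
               tolerance = 1e-6)
  # the composed-error density integrates to one over the residual
  for (pars in list(c(0.2, 0.5), c(1, 1), c(0.1, 2))) {
    total <- integrate(function(e) {
      exp(geosfa:::marginal_logdens(e, pars[1], pars[2]))
    }, -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # extreme residuals stay finite through the log-cdf tail expansion
  expect_true(is.finite(geosfa:::marginal_logdens(50, 0.1, 3)))
})

test_that("Monte-Carlo averaging of the conditional likelihood converges to the marginal", {
  spec <- plain_spec(mcmc_control(iterations = 10, burnin = 1, thin = 1))
  p <- y_only_panel(c(0.3, -0.8))
  st <- list(beta = c(const = 0), sigma_v2 = 0.4, sigma_ustar2 = 0.81,
             delta = numeric(0))
  set.seed(11)
  S <- 40000
  lik <- matrix(NA_real_, S, 2)
  for (s in seq_len(S)) {
    u <- abs(rnorm(2, 0, 0.9))
    lik[s, ] <- dnorm(p$y + u, 0, sqrt(0.4))
  }
  mc <- log(colMeans(lik))
  exact <- loglik_marginal(st, p, spec, pointwise = TRUE)
  se <- apply(lik, 2, sd) / sqrt(S) / colMeans(lik)
  expect_lt(max(abs(mc - exact) / (3 * se + 1e-12)), 1)
})

test_that("the preset suite expresses the model family by configuration", {
  for (nm in c(paste0("model", 1:9), "model10_translog", "model11_rescale",
               "model16_mixed", "model17_mixed")) {
    spec <- sfa_preset(nm)
    expect_s3_class(spec, "sfa_model_spec")
  }
  m2 <- sfa_preset("model2")
  m8 <- sfa_preset("model8")
  m9 <- sfa_preset("model9")
  expect_equal(m8$frontier_inputs, "quality")
  expect_equal(m9$frontier_inputs, "resource")
  expect_equal(m2$frontier_inputs, c("quality", "resource"))
  sim <- get_small_sim()
  pp <- prepare_panel(sim$panel)
  X2 <- frontier_design(pp, m2)
  X8 <- frontier_design(pp, m8)
  X9 <- frontier_design(pp, m9)
  expect_true(all(colnames(X8) %in% colnames(X2)))
  expect_true(all(colnames(X9) %in% colnames(X2)))
  expect_equal(sfa_preset("model10_translog")$functional_form, "translog")
  expect_equal(attr(sfa_preset("model11_rescale"), "zero_mode"),
               "rescale_half")
  expect_equal(sfa_preset("model16_mixed")$unstruct_level, "coarse")
  expect_error(sfa_preset("modelx"), "Unknown preset")
})
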