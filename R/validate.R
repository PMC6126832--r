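gir_panel <- function(n_obs, graph) {
  nd <- length(graph$regions)
  tibble::tibble(
    hospital_id = sprintf("h%03d", seq_len(n_obs)),
    year = 2006L,
    district_id = rep(graph$regions, length.out = n_obs),
    exp_mortality = 1, obs_mortality = 5, obs_readmissions = 5,
    physicians = exp(rnorm(n_obs)), nurses = exp(rnorm(n_obs)),
    SUCert = rbinom(n_obs, 1, 0.5),
    MedDepCon = runif(n_obs))
}

#' Joint validation of the MCMC kernel (getting-it-right check)
#'
#' Successive-conditional simulation: starting from a prior draw of all
#' parameters, alternate (a) simulating data from the observation model
#' given the current parameters and (b) applying the exact MCMC kernel
#' used by [fit_sfa()] to those data.  If every full-conditional update
#' is correct, the marginal distribution of the parameter chain is the
#' prior, so sample moments of the inefficiency coefficients and all
#' variances must match their prior moments within Monte-Carlo error.
#' Requires proper priors; run with Gaussian coefficient priors and
#' inverse-gamma shapes above 2 so the compared moments exist.
#'
#' @param n_obs,n_regions Size of the toy model (small by design).
#' @param n_cycles Number of simulate/update cycles.
#' @param sweeps_per_cycle MCMC sweeps applied per cycle.
#' @param priors Proper [sfa_priors()]; the default uses
#'   `IG(3, 2)` variances (mean 1) and unit-variance Gaussian
#'   coefficient priors.
#' @param seed Integer seed.
#' @return A tibble with prior and empirical moments and z-scores
#'   (empirical minus prior mean over a batch-means Monte-Carlo standard
#'   error) for each checked parameter.  Variances are compared on the
#'   log scale, where the inverse-gamma prior has closed-form
#'   light-tailed moments.
#' @export
successive_conditional_check <- function(n_obs = 20, n_regions = 4,
                                         n_cycles = 4000,
                                         sweeps_per_cycle = 2,
                                         priors = sfa_priors(
                                           a = 3, b = 2,
                                           beta_var = 1, delta_var = 1,
                                           shapes = list(), scales = list()),
                                         seed = 1L) {
  if (!is.finite(priors$delta_var) || !is.finite(priors$beta_var)) {
    abort("The check needs proper coefficient priors.")
  }
  set.seed(seed)
  g <- max(2L, ceiling(sqrt(n_regions)))
  graph <- make_lattice_graph(g)
  graph <- region_graph(graph$regions[seq_len(n_regions)],
                        graph$edges[graph$edges$from %in%
                                      graph$regions[seq_len(n_regions)] &
                                      graph$edges$to %in%
                                      graph$regions[seq_len(n_regions)], ])
  panel <- hospital_panel(gir_panel(n_obs, graph))
  panel$y <- 0
  panel$frontier_excluded <- FALSE
  panel <- encode_zero_inputs(panel)
  spec <- sfa_model_spec(
    frontier_inputs = "resource",
    inefficiency_terms = c("SUCert", "MedDepCon"),
    wave_effects_frontier = FALSE, wave_effects_inefficiency = FALSE,
    spatial = "unstruct", hospital_effect = FALSE,
    priors = priors,
    mcmc = mcmc_control(iterations = 10, burnin = 1, thin = 1, seed = seed,
                        adapt = 0),
    label = "getting-it-right toy")
  e <- engine_init(panel, graph, spec)
  a <- e$a; b <- e$b
  draw_prior <- function() {
    e$beta <- rnorm(e$p, 0, sqrt(priors$beta_var))
    e$delta <- rnorm(e$q, 0, sqrt(priors$delta_var))
    e$sigma_v2 <- 1 / rgamma(1, a[["sigma_v2"]], rate = b[["sigma_v2"]])
    e$sigma_ustar2 <- 1 / rgamma(1, a[["sigma_ustar2"]],
                                 rate = b[["sigma_ustar2"]])
    e$tau2_unstruct <- 1 / rgamma(1, a[["tau2_unstruct"]],
                                  rate = b[["tau2_unstruct"]])
    e$f_u <- rep(0, length(e$un$graph$regions))
    e$f_u[e$un$observed] <- rnorm(length(e$un$observed), 0,
                                  sqrt(e$tau2_unstruct))
    e$u_star <- rtnorm_lower0(e$n, 0, sqrt(e$sigma_ustar2))
    refresh_caches(e)
  }
  draw_data <- function() {
    e$y <- as.numeric(e$X %*% e$beta) +
      rnorm(e$n, 0, sqrt(e$sigma_v2)) - e$alpha * e$u_star
    refresh_caches(e)
  }
  draw_prior()
  keep <- matrix(NA_real_, n_cycles, e$q + 3)
  colnames(keep) <- c(paste0("delta.", colnames(e$Z)),
                      "sigma_v2", "sigma_ustar2", "tau2_unstruct")
  for (cy in seq_len(n_cycles)) {
    draw_data()
    for (s in seq_len(sweeps_per_cycle)) engine_sweep(e)
    keep[cy, ] <- c(e$delta, e$sigma_v2, e$sigma_ustar2, e$tau2_unstruct)
  }
  # variances are compared on the log scale: log of an inverse-gamma
  # variate has closed-form moments (log b - digamma(a), trigamma(a))
  # and light tails, so the Monte-Carlo comparison is far better
  # conditioned than on the raw scale
  vs <- c("sigma_v2", "sigma_ustar2", "tau2_unstruct")
  for (nm in vs) keep[, nm] <- log(keep[, nm])
  prior_mean <- c(rep(0, e$q),
                  vapply(vs, function(nm) log(b[[nm]]) - digamma(a[[nm]]), 1))
  prior_sd <- c(rep(sqrt(priors$delta_var), e$q),
                vapply(vs, function(nm) sqrt(trigamma(a[[nm]])), 1))
  emp_mean <- colMeans(keep)
  # batch-means Monte-Carlo standard errors (robust to long-range
  # autocorrelation of the cycle chain)
  nb <- 50L
  bsize <- floor(n_cycles / nb)
  bmeans <- apply(keep[seq_len(nb * bsize), , drop = FALSE], 2, function(x) {
    colMeans(matrix(x, nrow = bsize))
  })
  mcse <- apply(bmeans, 2, sd) / sqrt(nb)
  tibble::tibble(parameter = c(colnames(keep)[seq_len(e$q)],
                               paste0("log_", vs)),
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 sample_mean = emp_mean, mcse = mcse,
                 z = (emp_mean - prior_mean) / mcse)
}
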