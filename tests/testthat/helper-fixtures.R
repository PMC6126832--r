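# Shared fixtures, generated in code and cached for the test run.

fixture_env <- new.env()

# a small hand-built two-wave panel with two districts
tiny_panel_df <- function() {
  tibble::tibble(
    hospital_id = rep(c("a", "b", "c"), each = 2),
    year = rep(c(2006L, 2008L), 3),
    district_id = rep(c("d1", "d1", "d2"), each = 2),
    exp_mortality = c(2.0, 1.5, 3.0, 2.5, 0.8, 1.2),
    obs_mortality = c(5, 0, 10, 8, 2, 3),
    obs_readmissions = c(4, 3, 0, 6, 1, 2),
    physicians = c(2, 2.2, 8, 8.5, 1, 1.1),
    nurses = c(6, 6.5, 20, 21, 3, 3.2),
    SUCert = c(0, 0, 1, 1, 0, 0),
    MedDepCon = c(0.9, 0.9, 0.7, 0.7, 1, 1))
}

tiny_graph <- function() {
  region_graph(c("d1", "d2"), data.frame(from = "d1", to = "d2"))
}

get_small_sim <- function() {
  if (is.null(fixture_env$sim)) {
    fixture_env$sim <- simulate_panel(
      sim_config(g = 4, coarse_block = 2, mean_hospitals = 6, seed = 5))
  }
  fixture_env$sim
}

get_small_fit <- function() {
  if (is.null(fixture_env$fit)) {
    sim <- get_small_sim()
    pp <- prepare_panel(sim$panel)
    fixture_env$fit <- fit_sfa(
      pp, sim$graph,
      sfa_preset("model2", mcmc = mcmc_control(iterations = 1500,
                                               burnin = 500, thin = 10,
                                               seed = 11)))
  }
  fixture_env$fit
}

# spec used for models without covariates/spatial terms (plain half-normal
# frontier), handy for conjugacy and recovery checks
plain_spec <- function(mcmc, priors = sfa_priors()) {
  sfa_model_spec(frontier_inputs = character(0),
                 inefficiency_terms = character(0),
                 wave_effects_frontier = FALSE,
                 wave_effects_inefficiency = FALSE,
                 spatial = "none", priors = priors, mcmc = mcmc,
                 label = "plain half-normal")
}

# minimal prepared panel wrapping given y values (no inputs, no covariates)
y_only_panel <- function(y) {
  n <- length(y)
  df <- tibble::tibble(
    hospital_id = sprintf("h%04d", seq_len(n)), year = 2006L,
    district_id = "d1",
    exp_mortality = 1, obs_mortality = 1, obs_readmissions = 1,
    physicians = 1, nurses = 1)
  p <- hospital_panel(df)
  p$y <- y
  p$frontier_excluded <- FALSE
  encode_zero_inputs(p)
}
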