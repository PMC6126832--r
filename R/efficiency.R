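input_coef_map <- function() {
  tibble::tibble(
    input = c("mort30d", "readm30d", "phys", "nurses"),
    coef = c("log_mort_star", "log_readm_star", "log_phys", "log_nurse"),
    level = c("obs_mortality_star", "obs_readmissions_star",
              "physicians", "nurses"))
}

#' Closed-form expected technical efficiency under half-normal
#' inefficiency
#'
#' `E[exp(-u)] = 2 exp(sigma_u^2 / 2) Phi(-sigma_u)` for
#' `u ~ N+(0, sigma_u^2)`; evaluated on the log scale so large
#' inefficiency scales do not overflow.  Strictly decreasing in
#' `sigma_u`.
#'
#' @param sigma_u Non-negative inefficiency standard deviation
#'   (vectorized).
#' @return Expected efficiency in `(0, 1]`.
#' @export
te_closed_form <- function(sigma_u) {
  if (any(sigma_u < 0)) abort("`sigma_u` must be non-negative.")
  exp(log(2) + sigma_u^2 / 2 + pnorm(-sigma_u, log.p = TRUE))
}

# derivative of the closed form with respect to sigma_u (always negative)
te_closed_form_deriv <- function(sigma_u) {
  2 * exp(sigma_u^2 / 2) *
    (sigma_u * pnorm(-sigma_u) - dnorm(sigma_u))
}

#' Single-input slack formula
#'
#' Input in excess of the full-efficiency requirement when only input
#' `k` is contracted, holding output and the other inputs fixed:
#' `x * (1 - exp(-u / beta))` for inefficiency `u` and input elasticity
#' `beta > 0`.  Increasing in `u`, decreasing in `beta`, capped at the
#' input level `x` (full contraction) when `u / beta` overflows.
#'
#' @param x Input level (vectorized).
#' @param u Non-negative inefficiency.
#' @param beta Positive output elasticity of the input.
#' @return Slack in input units, in `[0, x]`.
#' @export
slack_amount <- function(x, u, beta) {
  if (any(beta <= 0)) abort("Slack is undefined for non-positive elasticities.")
  if (any(u < 0)) abort("`u` must be non-negative.")
  x * (1 - exp(-pmin(u / beta, 700)))
}

alpha_draws <- function(fit) {
  d <- fit$draws
  eta <- if (ncol(d$delta)) tcrossprod(d$delta, fit$design$Z)
         else matrix(0, nrow(d$beta), fit$n_obs)
  if (!is.null(d$f_struct)) {
    eta <- eta + d$f_struct[, fit$design$struct_idx, drop = FALSE]
  }
  if (!is.null(d$f_unstruct)) {
    eta <- eta + d$f_unstruct[, fit$design$unstruct_idx, drop = FALSE]
  }
  if (!is.null(d$h)) eta <- eta + d$h[, fit$design$hospital_idx, drop = FALSE]
  exp(eta)
}

#' Posterior technical efficiency
#'
#' Per hospital-year, the posterior mean of `exp(-u)` with
#' `u = u_star * alpha`: either averaging the stored latent draws
#' (`method = "draws"`, the default) or averaging the closed-form
#' conditional expectation `E[exp(-u) | sigma_u]` per draw
#' (`method = "closed_form"`, used as an oracle).
#'
#' @param fit An `sfa_fit`.
#' @param method `"draws"` or `"closed_form"`.
#' @return A tibble with `hospital_id`, `year`, `district_id`, `te`;
#'   the grand mean is in `attr(, "te_overall")`.
#' @export
technical_efficiency <- function(fit, method = c("draws", "closed_form")) {
  method <- match.arg(method)
  d <- fit$draws
  if (is.null(d$u_star)) abort("Fit has no stored inefficiency draws.")
  alpha <- alpha_draws(fit)
  te <- if (method == "draws") {
    colMeans(exp(-d$u_star * alpha))
  } else {
    sig_u <- sqrt(d$variances[, "sigma_ustar2"]) * alpha
    colMeans(te_closed_form(sig_u))
  }
  out <- tibble::tibble(hospital_id = fit$panel$hospital_id,
                        year = fit$panel$year,
                        district_id = fit$panel$district_id,
                        te = te)
  attr(out, "te_overall") <- mean(te)
  out
}

#' Inefficiency share of composed-error variation
#'
#' `gamma = sigma_u^2 / (sigma_v^2 + sigma_u^2)`, the share of the
#' composed error attributable to inefficiency.  The reported
#' inefficiency variance is evaluated at the sample-mean covariate
#' vector (where the scaled variance equals the base innovation
#' variance, by the internal centering of the inefficiency design).
#'
#' @param sigma_u2,sigma_v2 Positive variances (vectorized).
#' @return `gamma` in (0, 1).
#' @export
variance_ratio_gamma <- function(sigma_u2, sigma_v2) {
  if (any(sigma_u2 <= 0) || any(sigma_v2 <= 0)) {
    abort("Variances must be positive.")
  }
  sigma_u2 / (sigma_v2 + sigma_u2)
}

#' @rdname variance_ratio_gamma
#' @param fit An `sfa_fit`; returns the posterior draws of gamma.
#' @export
posterior_gamma <- function(fit) {
  v <- fit$draws$variances
  variance_ratio_gamma(v[, "sigma_ustar2"], v[, "sigma_v2"])
}

#' Slack resources
#'
#' Resources in excess of those needed under full efficiency,
#' operationalized as a single-input contraction holding output and the
#' other inputs fixed: `slack_k = x_k * (1 - exp(-u / beta_k))`, where
#' `beta_k` is the input's frontier elasticity.  `at =
#' "average_hospital"` evaluates per posterior draw at the sample-mean
#' input level and covariate vector (expected inefficiency
#' `sigma_u sqrt(2/pi)`), giving the posterior slack distribution; `at =
#' "per_observation"` evaluates each observation at its posterior-mean
#' inefficiency and aggregates national totals by wave.
#'
#' @param fit An `sfa_fit`.
#' @param input One of `"mort30d"`, `"readm30d"`, `"phys"`, `"nurses"`.
#' @param at `"average_hospital"` or `"per_observation"`.
#' @return For the average hospital, a tibble of posterior slack draws
#'   (column `slack`, in input units); per observation, a tibble with
#'   one row per hospital-year and wave totals in `attr(, "totals")`.
#' @export
slack_resources <- function(fit, input = "mort30d",
                            at = c("average_hospital", "per_observation")) {
  at <- match.arg(at)
  map <- input_coef_map()
  if (!input %in% map$input) {
    abort(paste0("`input` must be one of: ", paste(map$input, collapse = ", ")))
  }
  row <- map[map$input == input, ]
  if (!row$coef %in% colnames(fit$draws$beta)) {
    abort(sprintf("Input `%s` is not part of the fitted frontier.", input))
  }
  beta_k <- fit$draws$beta[, row$coef]
  if (mean(beta_k) <= 0) {
    abort(sprintf(
      "Posterior mean elasticity of `%s` is not positive (%.3f); slack is undefined for non-positive elasticities.",
      input, mean(beta_k)))
  }
  x_lev <- fit$panel[[row$level]]
  if (at == "average_hospital") {
    xbar <- mean(x_lev)
    ok <- beta_k > 0
    if (any(!ok)) {
      warn(sprintf("%d draws with non-positive elasticity dropped.", sum(!ok)))
    }
    sig_u <- sqrt(fit$draws$variances[ok, "sigma_ustar2"])
    u_mean <- sig_u * sqrt(2 / pi)
    slack <- slack_amount(xbar, u_mean, beta_k[ok])
    out <- tibble::tibble(draw = which(ok), input = input, slack = slack,
                          share = slack / xbar)
    attr(out, "x_level") <- xbar
    out
  } else {
    u_post <- colMeans(fit$draws$u_star * alpha_draws(fit))
    bk <- mean(beta_k)
    slack <- slack_amount(x_lev, u_post, bk)
    out <- tibble::tibble(hospital_id = fit$panel$hospital_id,
                          year = fit$panel$year, input = input,
                          x = x_lev, slack = slack)
    totals <- dplyr::summarise(dplyr::group_by(out, .data$year),
                               total_slack = sum(.data$slack),
                               total_x = sum(.data$x), .groups = "drop")
    attr(out, "totals") <- totals
    out
  }
}

resolve_covariate <- function(fit, covariate) {
  zn <- colnames(fit$draws$delta)
  if (covariate %in% zn) return(covariate)
  lg <- paste0("log_", covariate)
  if (lg %in% zn) return(lg)
  abort(paste0("Covariate `", covariate,
               "` is not in the inefficiency predictor (",
               paste(zn, collapse = ", "), ")"))
}

covariate_is_binary <- function(fit, name) {
  zbar <- fit$design$zbar[name]
  raw <- fit$design$Z[, name] + zbar
  is_binary01(raw)
}

# per-draw evaluation pieces at the sample-mean covariate vector
effect_eval_point <- function(fit, name) {
  list(delta = fit$draws$delta[, name],
       sig_star = sqrt(fit$draws$variances[, "sigma_ustar2"]),
       zbar = unname(fit$design$zbar[name]))
}

#' Marginal effect of an inefficiency determinant on expected technical
#' efficiency
#'
#' Evaluated at the sample means of all variables, where the
#' inefficiency scale is `sigma_u = sigma_ustar`.  In derivative mode
#' the effect is `delta_j * sigma_u * dE[TE]/dsigma_u`; in discrete mode
#' (default for binary determinants) it is
#' `E[TE | z_j = 1] - E[TE | z_j = 0]` holding the rest at their means.
#' Reported times 100, averaged over the posterior draws.
#'
#' @param fit An `sfa_fit`.
#' @param covariate Covariate name (raw panel name or design column).
#' @param mode `"auto"`, `"derivative"` or `"discrete"`.
#' @return One-row tibble with posterior mean `effect` (x100), 95%
#'   credible bounds and the mode used.
#' @export
marginal_effect_te <- function(fit, covariate,
                               mode = c("auto", "derivative", "discrete")) {
  mode <- match.arg(mode)
  name <- resolve_covariate(fit, covariate)
  if (mode == "auto") {
    mode <- if (covariate_is_binary(fit, name)) "discrete" else "derivative"
  }
  ev <- effect_eval_point(fit, name)
  eff <- if (mode == "derivative") {
    ev$delta * ev$sig_star * te_closed_form_deriv(ev$sig_star)
  } else {
    s1 <- ev$sig_star * exp(ev$delta * (1 - ev$zbar))
    s0 <- ev$sig_star * exp(ev$delta * (0 - ev$zbar))
    te_closed_form(s1) - te_closed_form(s0)
  }
  eff <- 100 * eff
  tibble::tibble(covariate = covariate, term = name, mode = mode,
                 effect = mean(eff),
                 lower = unname(quantile(eff, 0.025)),
                 upper = unname(quantile(eff, 0.975)))
}

#' Marginal effect of an inefficiency determinant on slack resources
#'
#' Derivative (or discrete difference) of the average-hospital slack of
#' one input with respect to one determinant, at sample means.  Signs
#' are opposite to the effect on technical efficiency:
#' inefficiency-reducing covariates reduce slack.
#'
#' @inheritParams marginal_effect_te
#' @param input One of `"mort30d"`, `"readm30d"`, `"phys"`, `"nurses"`.
#' @return One-row tibble with the posterior mean effect (in input
#'   units) and 95% credible bounds.
#' @export
marginal_effect_slack <- function(fit, covariate, input = "mort30d",
                                  mode = c("auto", "derivative", "discrete")) {
  mode <- match.arg(mode)
  name <- resolve_covariate(fit, covariate)
  if (mode == "auto") {
    mode <- if (covariate_is_binary(fit, name)) "discrete" else "derivative"
  }
  map <- input_coef_map()
  row <- map[map$input == input, ]
  if (!nrow(row) || !row$coef %in% colnames(fit$draws$beta)) {
    abort(sprintf("Input `%s` is not part of the fitted frontier.", input))
  }
  beta_k <- fit$draws$beta[, row$coef]
  xbar <- mean(fit$panel[[row$level]])
  ev <- effect_eval_point(fit, name)
  ok <- beta_k > 0
  slack_at <- function(z) {
    sig <- ev$sig_star[ok] * exp(ev$delta[ok] * (z - ev$zbar))
    umean <- sig * sqrt(2 / pi)
    slack_amount(xbar, umean, beta_k[ok])
  }
  eff <- if (mode == "derivative") {
    umean <- ev$sig_star[ok] * sqrt(2 / pi)
    dudz <- ev$delta[ok] * umean
    xbar * exp(-pmin(umean / beta_k[ok], 700)) * dudz / beta_k[ok]
  } else {
    slack_at(1) - slack_at(0)
  }
  tibble::tibble(covariate = covariate, term = name, input = input,
                 mode = mode, effect = mean(eff),
                 lower = unname(quantile(eff, 0.025)),
                 upper = unname(quantile(eff, 0.975)))
}

#' Marginal-effects table
#'
#' All inefficiency determinants against expected technical efficiency
#' (x100) and slack of every fitted input, in one tibble.
#'
#' @param fit An `sfa_fit`.
#' @param mode Passed to the individual effect functions.
#' @return A tibble with one row per determinant and columns `te_x100`
#'   plus one per input.
#' @export
marginal_effects <- function(fit, mode = "auto") {
  terms <- colnames(fit$draws$delta)
  inputs <- input_coef_map()
  inputs <- inputs$input[inputs$coef %in% colnames(fit$draws$beta)]
  purrr::map_dfr(terms, function(tm) {
    row <- tibble::tibble(covariate = tm,
                          te_x100 = marginal_effect_te(fit, tm, mode)$effect)
    for (inp in inputs) {
      row[[inp]] <- marginal_effect_slack(fit, tm, inp, mode)$effect
    }
    row
  })
}

#' National extrapolation of a per-hospital effect
#'
#' Multiplies a per-hospital marginal effect (e.g. deaths avoidable per
#' hospital-year) by the number of affected hospitals.  The raw product
#' is returned along with its nearest-integer and integer-part
#' roundings, the two conventions used when such totals are quoted.
#'
#' @param per_hospital_effect Non-negative per-hospital effect.
#' @param n_hospitals Non-negative hospital count.
#' @return A one-row tibble with `raw`, `rounded`, `truncated`.
#' @export
scenario_savings <- function(per_hospital_effect, n_hospitals) {
  if (per_hospital_effect < 0 || n_hospitals < 0) {
    abort("Effect and hospital count must be non-negative.")
  }
  raw <- per_hospital_effect * n_hospitals
  tibble::tibble(per_hospital_effect = per_hospital_effect,
                 n_hospitals = n_hospitals,
                 raw = raw, rounded = round(raw), truncated = trunc(raw))
}

#' Post-estimation effects report
#'
#' Bundles the post-estimation layer of a fitted frontier: technical
#' efficiency, the variance ratio gamma, average-hospital slack
#' distributions and the full marginal-effects table.
#'
#' @param fit An `sfa_fit`.
#' @return A list of class `effects_report`.
#' @export
compute_effects <- function(fit) {
  te <- technical_efficiency(fit)
  gam <- posterior_gamma(fit)
  inputs <- input_coef_map()
  inputs <- inputs$input[inputs$coef %in% colnames(fit$draws$beta)]
  slack <- purrr::map(setNames(inputs, inputs), function(inp) {
    tryCatch(slack_resources(fit, inp), error = function(err) NULL)
  })
  structure(
    list(te_by_obs = te,
         te_overall = attr(te, "te_overall"),
         gamma = mean(gam),
         gamma_draws = gam,
         slack_distributions = slack,
         marginal = marginal_effects(fit)),
    class = "effects_report")
}

#' @export
print.effects_report <- function(x, ...) {
  cat(sprintf("<effects_report> mean TE %.3f, gamma %.4f\n",
              x$te_overall, x$gamma))
  cat(sprintf("  slack inputs: %s\n",
              paste(names(x$slack_distributions), collapse = ", ")))
  invisible(x)
}
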