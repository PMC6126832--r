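spatial_labels <- function(panel, graph, level) {
  d <- as.character(panel$district_id)
  unknown <- setdiff(unique(d), graph$regions)
  if (length(unknown)) {
    abort(paste0("Districts absent from the region graph: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (level == "district") return(d)
  if (is.null(graph$coarse_map)) {
    abort("Coarse-level spatial effects require a graph with a coarse_map.")
  }
  unname(graph$coarse_map[d])
}

lookup_effect <- function(f, labels, what) {
  if (is.null(f)) return(rep(0, length(labels)))
  if (is.null(names(f))) abort(sprintf("`%s` must be a named vector.", what))
  miss <- setdiff(unique(labels), names(f))
  if (length(miss)) {
    abort(paste0(what, " missing entries for: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  unname(f[labels])
}

#' Frontier and inefficiency predictors
#'
#' `eta_y()` evaluates the production-frontier predictor
#' `X beta` (Cobb-Douglas, or translog when the specification adds the
#' second-order columns).  `eta_u()` evaluates the inefficiency
#' predictor: covariate part `Z delta` plus structured and unstructured
#' regional effects, the optional hospital effect and wave effects; the
#' multiplicative inefficiency scale is `alpha = exp(eta_u)`.
#'
#' @param state Named list of parameters; `beta` and `delta` must be
#'   named vectors matching the design columns, `f_struct`/`f_unstruct`
#'   named by region, `h` named by hospital id.
#' @param panel Prepared `hospital_panel`.
#' @param spec An `sfa_model_spec`.
#' @param graph A `region_graph` (needed when the spec has spatial
#'   terms).
#' @return Numeric vector, one value per observation.
#' @export
eta_y <- function(state, panel, spec) {
  X <- frontier_design(panel, spec)
  beta <- state$beta
  miss <- setdiff(colnames(X), names(beta))
  if (length(miss)) {
    abort(paste0("state$beta missing coefficients: ",
                 paste(miss, collapse = ", ")))
  }
  as.numeric(X %*% beta[colnames(X)])
}

#' @rdname eta_y
#' @export
eta_u <- function(state, panel, spec, graph = NULL) {
  Z <- inefficiency_design(panel, spec)
  eta <- rep(0, nrow(panel))
  if (ncol(Z)) {
    delta <- state$delta
    miss <- setdiff(colnames(Z), names(delta))
    if (length(miss)) {
      abort(paste0("state$delta missing coefficients: ",
                   paste(miss, collapse = ", ")))
    }
    eta <- eta + as.numeric(Z %*% delta[colnames(Z)])
  }
  if (spec$spatial %in% c("struct", "both")) {
    if (is.null(graph)) abort("Spatial terms need a region graph.")
    lab <- spatial_labels(panel, graph, spec$struct_level)
    eta <- eta + lookup_effect(state$f_struct, lab, "f_struct")
  }
  if (spec$spatial %in% c("unstruct", "both")) {
    if (is.null(graph)) abort("Spatial terms need a region graph.")
    lab <- spatial_labels(panel, graph, spec$unstruct_level)
    eta <- eta + lookup_effect(state$f_unstruct, lab, "f_unstruct")
  }
  if (spec$hospital_effect) {
    eta <- eta + lookup_effect(state$h, as.character(panel$hospital_id), "h")
  }
  eta
}

#' Composed-error log-likelihoods
#'
#' `loglik_conditional()` is the Gaussian log-likelihood given the
#' latent inefficiency innovations: with residual
#' `y - eta_y + alpha * u_star` distributed `N(0, sigma_v2)`.
#' `loglik_marginal()` integrates the half-normal innovations out
#' analytically, giving the classic skew-normal composed-error density
#' with observation-specific inefficiency scale
#' `sigma_u = sigma_ustar * alpha`.  The marginal form requires the
#' half-normal case (no free truncation mean).
#'
#' @inheritParams eta_y
#' @param graph A `region_graph`, passed through to [eta_u()].
#' @return Scalar log-likelihood.
#' @export
loglik_conditional <- function(state, panel, spec, graph = NULL) {
  if (is.null(state$u_star)) abort("state$u_star is required.")
  assert_positive(state$sigma_v2, "sigma_v2")
  alpha <- exp(eta_u(state, panel, spec, graph))
  eps <- panel$y - eta_y(state, panel, spec) + alpha * state$u_star
  if (any(!is.finite(eps))) abort("Non-finite residuals.")
  sum(dnorm(eps, 0, sqrt(state$sigma_v2), log = TRUE))
}

# pointwise skew-normal composed-error log-density; underflow in the
# Gaussian cdf is handled through its log-scale asymptotic expansion
# inside pnorm(log.p = TRUE)
marginal_logdens <- function(eps, sigma_v2, sigma_u) {
  s2 <- sigma_v2 + sigma_u^2
  sc <- sqrt(s2)
  lam <- sigma_u / sqrt(sigma_v2)
  log(2) - log(sc) + dnorm(eps / sc, log = TRUE) +
    pnorm(-eps * lam / sc, log.p = TRUE)
}

#' @rdname loglik_conditional
#' @param pointwise Return the per-observation log-density vector
#'   instead of the sum (used by WAIC).
#' @export
loglik_marginal <- function(state, panel, spec, graph = NULL,
                            pointwise = FALSE) {
  if (isTRUE(spec$mu_star_free)) {
    abort("The analytic marginal likelihood requires the half-normal case (mu_star = 0).")
  }
  assert_positive(state$sigma_v2, "sigma_v2")
  assert_positive(state$sigma_ustar2, "sigma_ustar2")
  alpha <- exp(eta_u(state, panel, spec, graph))
  eps <- panel$y - eta_y(state, panel, spec)
  if (any(!is.finite(eps))) abort("Non-finite residuals.")
  sigma_u <- sqrt(state$sigma_ustar2) * alpha
  ll <- marginal_logdens(eps, state$sigma_v2, sigma_u)
  if (pointwise) ll else sum(ll)
}
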