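# ---- engine internals -----------------------------------------------------
# The sampler lives in an environment so that single sweeps can be driven
# externally (simulation-based calibration / getting-it-right checks reuse
# exactly the kernel that fit_sfa() runs).

contract_graph <- function(graph) {
  if (is.null(graph$coarse_map)) {
    abort("Graph has no coarse_map; cannot build coarse-level structure.")
  }
  cm <- graph$coarse_map
  regions <- sort(unique(unname(cm)))
  e <- graph$edges
  a <- unname(cm[e$from]); b <- unname(cm[e$to])
  keep <- a != b
  pairs <- unique(data.frame(from = pmin(a[keep], b[keep]),
                             to = pmax(a[keep], b[keep]),
                             stringsAsFactors = FALSE))
  if (!nrow(pairs)) pairs <- data.frame(from = character(0), to = character(0))
  region_graph(regions, pairs)
}

spatial_setup <- function(panel, graph, level) {
  g <- if (level == "coarse") contract_graph(graph) else graph
  lab <- spatial_labels(panel, graph, level)
  idx <- match(lab, g$regions)
  obs <- split(seq_len(nrow(panel)), factor(idx, levels = seq_along(g$regions)))
  nb <- vector("list", length(g$regions))
  ef <- match(g$edges$from, g$regions); et <- match(g$edges$to, g$regions)
  for (k in seq_along(ef)) {
    nb[[ef[k]]] <- c(nb[[ef[k]]], et[k])
    nb[[et[k]]] <- c(nb[[et[k]]], ef[k])
  }
  list(graph = g, idx = idx, obs = obs, nb = nb,
       rankK = length(g$regions) - max(g$component))
}

engine_init <- function(panel, graph, spec) {
  if (!"y" %in% names(panel)) {
    abort("Panel has no output `y`; run prepare_panel() first.")
  }
  keep <- !is.na(panel$y)
  if (any(!keep)) {
    inform(sprintf("Excluding %d records without frontier output.", sum(!keep)))
    panel <- restore_panel_attrs(panel[keep, , drop = FALSE], panel)
  }
  e <- new.env(parent = emptyenv())
  e$panel <- panel
  e$spec <- spec
  e$graph <- graph
  e$y <- panel$y
  e$n <- length(e$y)
  X <- frontier_design(panel, spec)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    abort(sprintf("Frontier design is rank deficient (rank %d of %d columns).",
                  qrx$rank, ncol(X)))
  }
  e$X <- X
  e$XtX <- crossprod(X)
  Zraw <- inefficiency_design(panel, spec)
  # center the covariate design: the level of eta_u is not identified
  # separately from the innovation scale, so it is absorbed into
  # sigma_ustar2, which then measures inefficiency variance at
  # sample-mean covariates; slopes are unchanged
  e$zbar <- if (ncol(Zraw)) colMeans(Zraw) else numeric(0)
  e$Z <- if (ncol(Zraw)) sweep(Zraw, 2, e$zbar) else Zraw
  e$q <- ncol(e$Z)
  e$p <- ncol(X)

  e$use_struct <- spec$spatial %in% c("struct", "both")
  e$use_unstr <- spec$spatial %in% c("unstruct", "both")
  if ((e$use_struct || e$use_unstr) && is.null(graph)) {
    abort("Spatial terms need a region graph.")
  }
  if (e$use_struct) e$st <- spatial_setup(panel, graph, spec$struct_level)
  if (e$use_unstr) {
    un <- spatial_setup(panel, graph, spec$unstruct_level)
    # unstructured effects exist only for regions hosting observations
    un$observed <- which(lengths(un$obs) > 0)
    e$un <- un
  }
  if (spec$hospital_effect) {
    hid <- as.character(panel$hospital_id)
    e$h_levels <- unique(hid)
    e$h_idx <- match(hid, e$h_levels)
    e$h_obs <- split(seq_len(e$n), factor(e$h_idx, levels = seq_along(e$h_levels)))
  }

  pr <- spec$priors
  e$a <- vapply(pr$shape, as.numeric, 1)
  e$b <- vapply(pr$scale, as.numeric, 1)
  e$beta_var <- pr$beta_var
  e$delta_var <- pr$delta_var
  e$fixed <- spec$mcmc$fixed %||% list()

  # initial values: least squares for the frontier, diffuse inefficiency
  bhat <- qr.coef(qrx, e$y)
  e$beta <- as.numeric(bhat)
  resid <- e$y - as.numeric(X %*% e$beta)
  e$sigma_v2 <- e$fixed$sigma_v2 %||% max(0.5 * var(resid), 1e-4)
  e$sigma_ustar2 <- e$fixed$sigma_ustar2 %||% max(0.5 * var(resid), 1e-4)
  e$tau2_struct <- e$fixed$tau2_struct %||% 0.1
  e$tau2_unstruct <- e$fixed$tau2_unstruct %||% 0.1
  e$tau2_hospital <- e$fixed$tau2_hospital %||% 0.1
  e$delta <- if (!is.null(e$fixed$delta)) rep_len(e$fixed$delta, e$q) else rep(0, e$q)
  e$f_s <- if (e$use_struct) rep(0, length(e$st$graph$regions)) else numeric(0)
  e$f_u <- if (e$use_unstr) rep(0, length(e$un$graph$regions)) else numeric(0)
  e$h <- if (spec$hospital_effect) rep(0, length(e$h_levels)) else numeric(0)
  e$u_star <- e$fixed$u_star %||%
    rtnorm_lower0(e$n, 0, sqrt(e$sigma_ustar2))

  # delta proposal blocks, preconditioned by the covariate geometry
  if (e$q > 0) {
    nb <- ceiling(e$q / spec$mcmc$block_size)
    e$blocks <- split(seq_len(e$q), rep(seq_len(nb), each = spec$mcmc$block_size,
                                        length.out = e$q))
    V <- tryCatch(solve(crossprod(e$Z) / e$n + diag(1e-8, e$q)),
                  error = function(err) diag(e$q))
    e$Lb <- lapply(e$blocks, function(ix) {
      t(chol(V[ix, ix, drop = FALSE] + diag(1e-10, length(ix))))
    })
    e$log_scale <- rep(log(0.3), length(e$blocks))
    e$acc <- rep(0, length(e$blocks))
    e$try <- rep(0, length(e$blocks))
  } else {
    e$blocks <- list()
  }
  e$acc_f <- c(acc = 0, try = 0)
  e$ls_su <- log(0.3)   # proposal scale for the innovation-variance MH
  e$iter <- 0L
  refresh_caches(e)
  e
}

refresh_caches <- function(e) {
  e$sig_star <- sqrt(e$sigma_ustar2)
  e$eps <- e$y - as.numeric(e$X %*% e$beta)
  e$eta_cov <- if (e$q) as.numeric(e$Z %*% e$delta) else rep(0, e$n)
  e$eta_sp <- rep(0, e$n)
  if (e$use_struct) e$eta_sp <- e$eta_sp + e$f_s[e$st$idx]
  if (e$use_unstr) e$eta_sp <- e$eta_sp + e$f_u[e$un$idx]
  if (e$spec$hospital_effect) e$eta_sp <- e$eta_sp + e$h[e$h_idx]
  e$alpha <- exp(e$eta_cov + e$eta_sp)
  invisible(e)
}

# Robbins-Monro step size for proposal-scale adaptation
rm_step <- function(iter) 1 / max(iter, 10)^0.6

# site-wise Metropolis update for a group-level effect with Gaussian
# (conditional) prior N(prior_mean, 1/prior_prec).  The likelihood is
# the MARGINAL (u-integrated, skew-normal) likelihood of the site's
# observations; proposals come from the Gaussian combining the prior
# conditional with a finite-difference second-order expansion of the
# marginal log-likelihood at the current value ("GMRF-informed" for the
# structured field).  Working on the marginal scale decouples the field
# from the latent innovations, which are regenerated afterwards.
update_site <- function(e, f_cur, obs, prior_mean, prior_prec) {
  if (prior_prec <= 0 && !length(obs)) return(list(f = f_cur, acc = FALSE))
  if (length(obs)) {
    eps_o <- e$eps[obs]
    base <- e$sig_star * exp(e$eta_cov[obs] + e$eta_sp[obs] - f_cur)
    mll <- function(f) sum(marginal_logdens(eps_o, e$sigma_v2,
                                            base * exp(f)))
  } else {
    mll <- function(f) 0
  }
  h <- 0.15
  prop_pars <- function(f) {
    ll0 <- mll(f)
    if (length(obs)) {
      llp <- mll(f + h); llm <- mll(f - h)
      g <- (llp - llm) / (2 * h)
      H <- -(llp - 2 * ll0 + llm) / h^2
      if (!is.finite(H) || H <= 1e-10) H <- 0
      if (!is.finite(g)) g <- 0
    } else {
      g <- 0; H <- 0
    }
    P <- H + prior_prec
    m <- if (H > 0) (H * f + g + prior_prec * prior_mean) / P else prior_mean
    c(P, m, ll0)
  }
  cur <- prop_pars(f_cur)
  if (cur[1] <= 0) return(list(f = f_cur, acc = FALSE))
  f_new <- rnorm(1, cur[2], sqrt(1 / cur[1]))
  new <- prop_pars(f_new)
  log_r <- (new[3] - 0.5 * prior_prec * (f_new - prior_mean)^2) -
    (cur[3] - 0.5 * prior_prec * (f_cur - prior_mean)^2) +
    dnorm(f_cur, new[2], sqrt(1 / new[1]), log = TRUE) -
    dnorm(f_new, cur[2], sqrt(1 / cur[1]), log = TRUE)
  if (is.finite(log_r) && log(runif(1)) < log_r) {
    list(f = f_new, acc = TRUE)
  } else {
    list(f = f_cur, acc = FALSE)
  }
}

apply_site_change <- function(e, obs, df) {
  if (length(obs) && df != 0) {
    e$eta_sp[obs] <- e$eta_sp[obs] + df
    e$alpha[obs] <- exp(e$eta_cov[obs] + e$eta_sp[obs])
  }
}

engine_sweep <- function(e) {
  e$iter <- e$iter + 1L
  n <- e$n
  fixed <- e$fixed

  # Partially collapsed scan: the inefficiency coefficients, spatial and
  # hospital effects and the innovation variance move against the
  # MARGINAL (u-integrated, skew-normal) likelihood -- breaking the slow
  # ridge between the covariate-driven spread of eta_u and the
  # innovation scale -- after which the latent innovations are
  # regenerated from their exact conditional before the updates that
  # condition on them (frontier coefficients, noise variance).

  # (1) inefficiency coefficients: blocked adaptive random-walk MH on
  # the marginal likelihood
  if (e$q > 0 && is.null(fixed$delta)) {
    ll_cur <- sum(marginal_logdens(e$eps, e$sigma_v2, e$sig_star * e$alpha))
    for (bi in seq_along(e$blocks)) {
      ix <- e$blocks[[bi]]
      step <- exp(e$log_scale[bi]) *
        as.numeric(e$Lb[[bi]] %*% rnorm(length(ix)))
      deta <- as.numeric(e$Z[, ix, drop = FALSE] %*% step)
      eta_cov_new <- e$eta_cov + deta
      alpha_new <- exp(eta_cov_new + e$eta_sp)
      ll_new <- sum(marginal_logdens(e$eps, e$sigma_v2,
                                     e$sig_star * alpha_new))
      log_r <- ll_new - ll_cur
      if (is.finite(e$delta_var)) {
        dnew <- e$delta[ix] + step
        log_r <- log_r - sum(dnew^2 - e$delta[ix]^2) / (2 * e$delta_var)
      }
      acc_p <- if (is.nan(log_r) || !is.finite(ll_new)) 0
               else min(1, exp(log_r))
      e$try[bi] <- e$try[bi] + 1
      if (runif(1) < acc_p) {
        e$delta[ix] <- e$delta[ix] + step
        e$eta_cov <- eta_cov_new
        e$alpha <- alpha_new
        ll_cur <- ll_new
        e$acc[bi] <- e$acc[bi] + 1
      }
      if (e$iter <= e$spec$mcmc$adapt) {
        e$log_scale[bi] <- e$log_scale[bi] + rm_step(e$iter) * (acc_p - 0.25)
      }
    }
  }

  # (2) structured spatial field: site-wise marginal MH with
  # GMRF-informed proposals, then sum-to-zero centering per component
  if (e$use_struct && is.null(fixed$f_struct)) {
    st <- e$st
    for (r in seq_along(st$graph$regions)) {
      deg <- st$graph$degree[r]
      if (deg == 0) next   # island: structured effect pinned at 0
      mu_p <- mean(e$f_s[st$nb[[r]]])
      res <- update_site(e, e$f_s[r], st$obs[[r]], mu_p, deg / e$tau2_struct)
      e$acc_f["try"] <- e$acc_f["try"] + 1
      if (res$acc) {
        e$acc_f["acc"] <- e$acc_f["acc"] + 1
        apply_site_change(e, st$obs[[r]], res$f - e$f_s[r])
        e$f_s[r] <- res$f
      }
    }
    cent <- center_by_component(e$f_s, st$graph)
    if (any(cent != e$f_s)) {
      e$f_s <- cent
      e$eta_sp <- rep(0, n)
      e$eta_sp <- e$eta_sp + e$f_s[st$idx]
      if (e$use_unstr) e$eta_sp <- e$eta_sp + e$f_u[e$un$idx]
      if (e$spec$hospital_effect) e$eta_sp <- e$eta_sp + e$h[e$h_idx]
      e$alpha <- exp(e$eta_cov + e$eta_sp)
    }
  }

  # (3) unstructured regional and hospital effects (marginal MH)
  if (e$use_unstr && is.null(fixed$f_unstruct)) {
    for (r in e$un$observed) {
      res <- update_site(e, e$f_u[r], e$un$obs[[r]], 0, 1 / e$tau2_unstruct)
      if (res$acc) {
        apply_site_change(e, e$un$obs[[r]], res$f - e$f_u[r])
        e$f_u[r] <- res$f
      }
    }
  }
  if (e$spec$hospital_effect && is.null(fixed$h)) {
    for (k in seq_along(e$h_levels)) {
      res <- update_site(e, e$h[k], e$h_obs[[k]], 0, 1 / e$tau2_hospital)
      if (res$acc) {
        apply_site_change(e, e$h_obs[[k]], res$f - e$h[k])
        e$h[k] <- res$f
      }
    }
  }

  # (4) innovation variance: adaptive log-scale MH on the marginal
  # likelihood with its inverse-gamma prior
  if (is.null(fixed$sigma_ustar2)) {
    ll_cur <- sum(marginal_logdens(e$eps, e$sigma_v2, e$sig_star * e$alpha))
    a_su <- e$a[["sigma_ustar2"]]; b_su <- e$b[["sigma_ustar2"]]
    lpost <- function(s2, ll) ll - (a_su + 1) * log(s2) - b_su / s2 + log(s2)
    s2_new <- e$sigma_ustar2 * exp(exp(e$ls_su) * rnorm(1))
    ll_new <- sum(marginal_logdens(e$eps, e$sigma_v2,
                                   sqrt(s2_new) * e$alpha))
    log_r <- lpost(s2_new, ll_new) - lpost(e$sigma_ustar2, ll_cur)
    acc_p <- if (is.nan(log_r) || !is.finite(ll_new)) 0
             else min(1, exp(log_r))
    if (runif(1) < acc_p) {
      e$sigma_ustar2 <- s2_new
      e$sig_star <- sqrt(s2_new)
    }
    if (e$iter <= e$spec$mcmc$adapt) {
      e$ls_su <- e$ls_su + rm_step(e$iter) * (acc_p - 0.44)
    }
  }

  # (5) latent inefficiency innovations: exact truncated-normal draws
  if (is.null(fixed$u_star)) {
    e$u_star <- sample_ustar_conditional(e$eps, e$alpha, e$sigma_v2,
                                         e$sigma_ustar2)
  }

  # (6) frontier coefficients: conjugate Gaussian given the adjusted
  # response y + alpha * u_star
  if (is.null(fixed$beta)) {
    ytil <- e$y + e$alpha * e$u_star
    prec <- e$XtX / e$sigma_v2
    if (is.finite(e$beta_var)) prec <- prec + diag(1 / e$beta_var, e$p)
    ch <- chol(prec)
    m <- backsolve(ch, backsolve(ch, crossprod(e$X, ytil) / e$sigma_v2,
                                 transpose = TRUE))
    e$beta <- as.numeric(m + backsolve(ch, rnorm(e$p)))
    e$eps <- e$y - as.numeric(e$X %*% e$beta)
  }

  # (7) remaining variances: conjugate inverse-gamma draws
  rinvgamma1 <- function(shape, rate) 1 / rgamma(1, shape = shape, rate = rate)
  if (is.null(fixed$sigma_v2)) {
    v <- e$eps + e$alpha * e$u_star
    e$sigma_v2 <- rinvgamma1(e$a[["sigma_v2"]] + n / 2,
                             e$b[["sigma_v2"]] + sum(v^2) / 2)
  }
  if (e$use_struct && is.null(fixed$tau2_struct)) {
    qf <- as.numeric(e$f_s %*% (e$st$graph$K %*% e$f_s))
    e$tau2_struct <- rinvgamma1(e$a[["tau2_struct"]] + e$st$rankK / 2,
                                e$b[["tau2_struct"]] + qf / 2)
  }
  if (e$use_unstr && is.null(fixed$tau2_unstruct)) {
    fo <- e$f_u[e$un$observed]
    e$tau2_unstruct <- rinvgamma1(e$a[["tau2_unstruct"]] + length(fo) / 2,
                                  e$b[["tau2_unstruct"]] + sum(fo^2) / 2)
  }
  if (e$spec$hospital_effect && is.null(fixed$tau2_hospital)) {
    e$tau2_hospital <- rinvgamma1(e$a[["tau2_hospital"]] + length(e$h) / 2,
                                  e$b[["tau2_hospital"]] + sum(e$h^2) / 2)
  }

  if (!all(is.finite(c(e$beta, e$delta, e$sigma_v2, e$sigma_ustar2)))) {
    abort(paste0(
      "Non-finite sampler state at iteration ", e$iter, ": ",
      sprintf("sigma_v2=%.3g sigma_ustar2=%.3g max|beta|=%.3g max|delta|=%.3g",
              e$sigma_v2, e$sigma_ustar2, max(abs(e$beta)),
              if (e$q) max(abs(e$delta)) else 0)))
  }
  invisible(e)
}

engine_state <- function(e) {
  list(beta = setNames(e$beta, colnames(e$X)),
       delta = if (e$q) setNames(e$delta, colnames(e$Z)) else numeric(0),
       f_struct = if (e$use_struct) setNames(e$f_s, e$st$graph$regions) else NULL,
       f_unstruct = if (e$use_unstr) setNames(e$f_u, e$un$graph$regions) else NULL,
       h = if (e$spec$hospital_effect) setNames(e$h, e$h_levels) else NULL,
       u_star = e$u_star,
       sigma_v2 = e$sigma_v2, sigma_ustar2 = e$sigma_ustar2,
       tau2_struct = e$tau2_struct, tau2_unstruct = e$tau2_unstruct,
       tau2_hospital = e$tau2_hospital)
}

# ---- public fitting interface ---------------------------------------------

#' Fit the geoadditive stochastic frontier model by MCMC
#'
#' Runs the blocked Gibbs/Metropolis sampler: conjugate Gaussian updates
#' for the frontier coefficients, exact truncated-normal draws for the
#' latent inefficiency innovations, blocked adaptive random-walk
#' Metropolis for the inefficiency coefficients, site-wise
#' Taylor-proposal Metropolis for structured/unstructured regional (and
#' hospital) effects with per-component sum-to-zero centering of the
#' structured field, and conjugate inverse-gamma draws for all
#' variances.  Identical seeds give bitwise-identical stored draws.
#'
#' @param panel Prepared `hospital_panel` (see [prepare_panel()]).
#' @param graph A [region_graph()] (required for spatial specifications).
#' @param spec An [sfa_model_spec()] or preset.
#' @param verbose Print progress every 2000 iterations.
#' @return An object of class `sfa_fit` holding the thinned posterior
#'   draws, acceptance rates, the data fingerprint and the model
#'   specification.
#' @export
fit_sfa <- function(panel, graph = NULL, spec = sfa_preset("model2"),
                    verbose = FALSE) {
  t0 <- Sys.time()
  ctrl <- spec$mcmc
  set.seed(ctrl$seed)
  e <- engine_init(panel, graph, spec)
  n_store <- n_stored_draws(ctrl$iterations, ctrl$burnin, ctrl$thin)
  store <- list(
    beta = matrix(NA_real_, n_store, e$p, dimnames = list(NULL, colnames(e$X))),
    delta = matrix(NA_real_, n_store, e$q,
                   dimnames = list(NULL, if (e$q) colnames(e$Z))),
    f_struct = if (e$use_struct)
      matrix(NA_real_, n_store, length(e$st$graph$regions),
             dimnames = list(NULL, e$st$graph$regions)),
    f_unstruct = if (e$use_unstr)
      matrix(NA_real_, n_store, length(e$un$graph$regions),
             dimnames = list(NULL, e$un$graph$regions)),
    h = if (spec$hospital_effect)
      matrix(NA_real_, n_store, length(e$h_levels),
             dimnames = list(NULL, e$h_levels)),
    u_star = matrix(NA_real_, n_store, e$n),
    variances = matrix(NA_real_, n_store, 5,
                       dimnames = list(NULL, c("sigma_v2", "sigma_ustar2",
                                               "tau2_struct", "tau2_unstruct",
                                               "tau2_hospital"))))
  s <- 0L
  for (it in seq_len(ctrl$iterations)) {
    engine_sweep(e)
    if (it > ctrl$burnin && (it - ctrl$burnin) %% ctrl$thin == 0L &&
        s < n_store) {
      s <- s + 1L
      store$beta[s, ] <- e$beta
      if (e$q) store$delta[s, ] <- e$delta
      if (e$use_struct) store$f_struct[s, ] <- e$f_s
      if (e$use_unstr) store$f_unstruct[s, ] <- e$f_u
      if (spec$hospital_effect) store$h[s, ] <- e$h
      store$u_star[s, ] <- e$u_star
      store$variances[s, ] <- c(e$sigma_v2, e$sigma_ustar2, e$tau2_struct,
                                e$tau2_unstruct, e$tau2_hospital)
    }
    if (verbose && it %% 2000L == 0L) {
      inform(sprintf("iteration %d / %d", it, ctrl$iterations))
    }
  }
  acc_rates <- if (length(e$blocks)) e$acc / pmax(e$try, 1) else numeric(0)
  if (length(acc_rates) && any(acc_rates < 0.05 | acc_rates > 0.7)) {
    warn(sprintf(
      "Metropolis acceptance outside [0.05, 0.7] for delta block(s): %s",
      paste(which(acc_rates < 0.05 | acc_rates > 0.7), collapse = ", ")))
  }
  fit <- structure(
    list(draws = store,
         spec = spec,
         n_obs = e$n,
         panel = e$panel,
         graph = graph,
         design = list(X = e$X, Z = e$Z, zbar = e$zbar,
                       struct_idx = if (e$use_struct) e$st$idx,
                       unstruct_idx = if (e$use_unstr) e$un$idx,
                       hospital_idx = if (spec$hospital_effect) e$h_idx),
         acceptance = list(delta = acc_rates,
                           spatial = unname(e$acc_f["acc"] /
                                              max(e$acc_f["try"], 1))),
         seed = ctrl$seed,
         fingerprint = data_fingerprint(e$y),
         runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "sfa_fit")
  fit
}

#' @export
print.sfa_fit <- function(x, ...) {
  cat(sprintf("<sfa_fit> %s: %d observations, %d stored draws (seed %d)\n",
              x$spec$label, x$n_obs, nrow(x$draws$beta), x$seed))
  g <- glance(x)
  cat(sprintf("  DIC %.1f (pD %.1f), WAIC %.1f, mean TE %.3f, gamma %.3f\n",
              g$DIC, g$p_D, g$WAIC, g$te_overall, g$gamma))
  invisible(x)
}

# per-draw pointwise marginal log-density matrix (draws x observations)
pointwise_loglik <- function(fit, likelihood = c("marginal", "conditional")) {
  likelihood <- match.arg(likelihood)
  d <- fit$draws
  S <- nrow(d$beta)
  eta_y_draws <- tcrossprod(d$beta, fit$design$X)   # S x n
  eta_u_draws <- if (ncol(d$delta)) tcrossprod(d$delta, fit$design$Z)
                 else matrix(0, S, fit$n_obs)
  if (!is.null(d$f_struct)) {
    eta_u_draws <- eta_u_draws + d$f_struct[, fit$design$struct_idx, drop = FALSE]
  }
  if (!is.null(d$f_unstruct)) {
    eta_u_draws <- eta_u_draws + d$f_unstruct[, fit$design$unstruct_idx, drop = FALSE]
  }
  if (!is.null(d$h)) {
    eta_u_draws <- eta_u_draws + d$h[, fit$design$hospital_idx, drop = FALSE]
  }
  eps <- sweep(-eta_y_draws, 2, fit$panel$y, `+`)
  alpha <- exp(eta_u_draws)
  if (likelihood == "marginal") {
    sig_u <- sqrt(d$variances[, "sigma_ustar2"]) * alpha
    marginal_logdens(eps, d$variances[, "sigma_v2"], sig_u)
  } else {
    vres <- eps + alpha * d$u_star
    dnorm(vres, 0, sqrt(d$variances[, "sigma_v2"]), log = TRUE)
  }
}

mean_state <- function(fit) {
  d <- fit$draws
  list(beta = colMeans(d$beta),
       delta = if (ncol(d$delta)) colMeans(d$delta) else numeric(0),
       f_struct = if (!is.null(d$f_struct)) colMeans(d$f_struct),
       f_unstruct = if (!is.null(d$f_unstruct)) colMeans(d$f_unstruct),
       h = if (!is.null(d$h)) colMeans(d$h),
       sigma_v2 = mean(d$variances[, "sigma_v2"]),
       sigma_ustar2 = mean(d$variances[, "sigma_ustar2"]))
}

loglik_at_state <- function(fit, st, likelihood) {
  X <- fit$design$X; Z <- fit$design$Z
  eta_y <- as.numeric(X %*% st$beta)
  eta_u <- if (length(st$delta)) as.numeric(Z %*% st$delta) else rep(0, fit$n_obs)
  if (!is.null(st$f_struct)) eta_u <- eta_u + st$f_struct[fit$design$struct_idx]
  if (!is.null(st$f_unstruct)) eta_u <- eta_u + st$f_unstruct[fit$design$unstruct_idx]
  if (!is.null(st$h)) eta_u <- eta_u + st$h[fit$design$hospital_idx]
  eps <- fit$panel$y - eta_y
  alpha <- exp(eta_u)
  if (likelihood == "marginal") {
    sum(marginal_logdens(eps, st$sigma_v2, sqrt(st$sigma_ustar2) * alpha))
  } else {
    sum(dnorm(eps + alpha * st$u_star, 0, sqrt(st$sigma_v2), log = TRUE))
  }
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(posterior mean)`.  By default the deviance uses the
#' marginal (skew-normal) likelihood with the latent innovations
#' integrated out analytically, so that models with different latent
#' dimensions are comparable; the conditional-on-u alternative is
#' available behind the `likelihood` flag.
#'
#' @param fit An `sfa_fit` with at least 100 stored draws.
#' @param likelihood `"marginal"` (default) or `"conditional"`.
#' @return A tibble with `DIC`, `p_D`, `Dbar` and the likelihood flavour
#'   and data fingerprint (used to guard cross-model comparisons).
#' @export
compute_dic <- function(fit, likelihood = c("marginal", "conditional")) {
  likelihood <- match.arg(likelihood)
  if (nrow(fit$draws$beta) < 100) {
    abort("DIC needs at least 100 stored draws.")
  }
  lp <- pointwise_loglik(fit, likelihood)
  dev_draws <- -2 * rowSums(lp)
  dbar <- mean(dev_draws)
  st <- mean_state(fit)
  if (likelihood == "conditional") st$u_star <- colMeans(fit$draws$u_star)
  dhat <- -2 * loglik_at_state(fit, st, likelihood)
  pd <- dbar - dhat
  tibble::tibble(DIC = dbar + pd, p_D = pd, Dbar = dbar,
                 likelihood = likelihood, fingerprint = fit$fingerprint)
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 * sum_i [ log mean_s p(y_i | theta_s) -
#' var_s log p(y_i | theta_s) ]`, with the summed posterior variance of
#' the pointwise log-density as the effective parameter count `p_waic`.
#'
#' @inheritParams compute_dic
#' @return A tibble with `WAIC`, `p_waic`, `lppd`.
#' @export
compute_waic <- function(fit, likelihood = c("marginal", "conditional")) {
  likelihood <- match.arg(likelihood)
  if (nrow(fit$draws$beta) < 100) {
    abort("WAIC needs at least 100 stored draws.")
  }
  lp <- pointwise_loglik(fit, likelihood)
  S <- nrow(lp)
  mx <- apply(lp, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(lp, 2, mx)))) # log mean exp, stabilized
  pw_i <- apply(lp, 2, var)
  tibble::tibble(WAIC = -2 * (sum(lppd_i) - sum(pw_i)),
                 p_waic = sum(pw_i), lppd = sum(lppd_i),
                 likelihood = likelihood, fingerprint = fit$fingerprint)
}
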