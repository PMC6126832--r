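#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

ci_stars <- function(draws) {
  stars <- function(x, lo, hi) {
    q <- quantile(x, c(0.005, 0.995, 0.025, 0.975, 0.05, 0.95))
    if (q[1] > 0 || q[2] < 0) return("***")
    if (q[3] > 0 || q[4] < 0) return("**")
    if (q[5] > 0 || q[6] < 0) return("*")
    ""
  }
  apply(draws, 2, stars)
}

#' Tidy posterior summaries of a fitted frontier model
#'
#' One row per coefficient with posterior mean, standard deviation, 95%
#' credible interval and significance stars (1/5/10% credibility
#' intervals excluding zero, the usual starring convention for these
#' models).
#'
#' @param x An `sfa_fit`.
#' @param component `"beta"` (frontier), `"delta"` (inefficiency) or
#'   `"variances"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sfa_fit
#' @export
tidy.sfa_fit <- function(x, component = c("beta", "delta", "variances"),
                         ...) {
  component <- match.arg(component)
  m <- x$draws[[component]]
  if (is.null(m) || !ncol(m)) return(tibble::tibble())
  if (component == "variances") {
    keep <- apply(m, 2, function(col) var(col) > 0)
    m <- m[, keep, drop = FALSE]
  }
  sig <- if (component == "variances") rep("", ncol(m)) else ci_stars(m)
  tibble::tibble(
    component = component,
    term = colnames(m),
    estimate = colMeans(m),
    std.error = apply(m, 2, sd),
    conf.low = apply(m, 2, quantile, 0.025),
    conf.high = apply(m, 2, quantile, 0.975),
    sig = unname(sig))
}

#' One-row model summary
#'
#' @param x An `sfa_fit`.
#' @param ... Unused.
#' @return A tibble with observation and draw counts, DIC, pD, WAIC,
#'   p_waic, overall posterior-mean technical efficiency and the
#'   variance ratio gamma.
#' @method glance sfa_fit
#' @export
glance.sfa_fit <- function(x, ...) {
  dic <- compute_dic(x)
  waic <- compute_waic(x)
  te <- technical_efficiency(x)
  tibble::tibble(
    n_obs = x$n_obs, n_draws = nrow(x$draws$beta),
    DIC = dic$DIC, p_D = dic$p_D,
    WAIC = waic$WAIC, p_waic = waic$p_waic,
    te_overall = attr(te, "te_overall"),
    gamma = mean(posterior_gamma(x)),
    sigma_v2 = mean(x$draws$variances[, "sigma_v2"]),
    sigma_u2 = mean(x$draws$variances[, "sigma_ustar2"]))
}

#' Trace plots of the stored chains
#'
#' @param object An `sfa_fit`.
#' @param pars Parameter names (design column names) to show; defaults
#'   to the variances plus up to four coefficients.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfa_fit
#' @export
autoplot.sfa_fit <- function(object, pars = NULL, ...) {
  d <- object$draws
  all <- cbind(d$beta,
               if (ncol(d$delta)) d$delta,
               d$variances[, apply(d$variances, 2, var) > 0, drop = FALSE])
  pars <- pars %||% head(colnames(all), 6)
  pars <- intersect(pars, colnames(all))
  df <- tibble::tibble(
    iteration = rep(seq_len(nrow(all)), length(pars)),
    parameter = rep(pars, each = nrow(all)),
    value = as.numeric(all[, pars]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue4") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "stored draw", y = NULL,
                  title = "Posterior sampling paths") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Posterior density of average-hospital slack resources
#'
#' @param fit An `sfa_fit`.
#' @param inputs Input names (see [slack_resources()]).
#' @return A ggplot object, one panel per input.
#' @export
plot_slack_density <- function(fit, inputs = c("mort30d", "readm30d",
                                               "phys", "nurses")) {
  df <- purrr::map_dfr(inputs, function(inp) {
    tryCatch(slack_resources(fit, inp), error = function(e) tibble::tibble())
  })
  if (!nrow(df)) abort("No slack distributions available.")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slack)) +
    ggplot2::geom_density(fill = "steelblue3", alpha = 0.5) +
    ggplot2::facet_wrap(~input, scales = "free") +
    ggplot2::labs(x = "slack at the average hospital (input units)",
                  y = "posterior density",
                  title = "Posterior distribution of slack resources") +
    ggplot2::theme_minimal()
}

#' Map of posterior spatial inefficiency effects
#'
#' Tile map of the posterior means of the structured, unstructured and
#' composite regional effects for lattice graphs.
#'
#' @param fit An `sfa_fit` with spatial terms.
#' @return A ggplot object.
#' @export
plot_spatial_effects <- function(fit) {
  d <- fit$draws
  if (is.null(d$f_struct) && is.null(d$f_unstruct)) {
    abort("Fit has no spatial effects.")
  }
  fs <- if (!is.null(d$f_struct)) colMeans(d$f_struct) else NULL
  fu <- if (!is.null(d$f_unstruct)) colMeans(d$f_unstruct) else NULL
  regions <- names(fs) %||% names(fu)
  if (!all(grepl("^d[0-9]+$", regions))) {
    abort("Tile maps are only drawn for lattice region ids.")
  }
  k <- as.integer(sub("^d", "", regions))
  g <- ceiling(sqrt(max(k)))
  sp <- tibble::tibble(
    region = regions, row = (k - 1L) %/% g, col = (k - 1L) %% g,
    structured = if (!is.null(fs)) unname(fs) else 0,
    unstructured = if (!is.null(fu)) unname(fu[regions] %na% 0) else 0)
  sp$unstructured[is.na(sp$unstructured)] <- 0
  sp$composite <- sp$structured + sp$unstructured
  df <- tidyr::pivot_longer(sp, c("structured", "unstructured", "composite"),
                            names_to = "effect", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~effect) +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Centered regional inefficiency effects",
                  fill = "posterior\nmean") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
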