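# split-chain potential scale reduction on a single chain: the stored
# chain is split into two halves which play the role of parallel chains
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  chains <- list(x[seq_len(half)], x[(n - half + 1):n])
  m <- length(chains)
  means <- vapply(chains, mean, 1)
  vars <- vapply(chains, var, 1)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size by the initial-monotone-positive-sequence
# estimator on the chain autocorrelations
ess_imse <- function(x) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
  # sum pairs while their sums stay positive and decreasing
  pair <- ac[seq(1, length(ac) - 1, by = 2)] + ac[seq(2, length(ac), by = 2)]
  keep <- which(pair <= 0)
  last <- if (length(keep)) keep[1] - 1 else length(pair)
  if (last > 1) pair[1:last] <- cummin(pair[1:last])
  s <- if (last >= 1) sum(pair[1:last]) else 0
  max(1, n / (1 + 2 * max(s, 0) + 2 * ac[1] * 0))
}

#' Convergence diagnostics for a fitted model
#'
#' Split-chain potential scale reduction and effective sample size for
#' every frontier coefficient, inefficiency coefficient and variance,
#' computed from the stored (thinned) chain.  A warning is raised for
#' effective sizes below 100.
#'
#' @param fit An `sfa_fit`.
#' @param ess_warn Threshold below which a warning is emitted.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `rhat`,
#'   `ess`.
#' @export
mcmc_diagnostics <- function(fit, ess_warn = 100) {
  d <- fit$draws
  mats <- list(beta = d$beta, delta = d$delta, variances = d$variances)
  rows <- purrr::map_dfr(names(mats), function(nm) {
    m <- mats[[nm]]
    if (is.null(m) || !ncol(m)) return(tibble::tibble())
    keep <- colnames(m)
    # variances of switched-off components are constant placeholders
    ok <- apply(m, 2, function(x) var(x) > 0 | nm != "variances")
    tibble::tibble(
      parameter = paste0(nm, ".", keep),
      mean = colMeans(m), sd = apply(m, 2, sd),
      rhat = apply(m, 2, split_rhat),
      ess = apply(m, 2, ess_imse))[ok, ]
  })
  low <- rows$ess < ess_warn & is.finite(rows$ess)
  if (any(low)) {
    warn(sprintf("Effective sample size below %d for: %s", ess_warn,
                 paste(head(rows$parameter[low], 6), collapse = ", ")))
  }
  rows
}
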