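#' Exact draws from a normal distribution truncated below at zero
#'
#' Inverse-CDF sampler for `N(mean, sd^2)` restricted to `[0, Inf)`.
#' Works entirely on the log scale of the upper-tail probability, so it
#' neither loops (no rejection step) nor fails for extreme standardized
#' bounds: for `mean/sd` of either sign and magnitude in the hundreds the
#' draws remain exact to numerical precision.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the untruncated normal
#'   (vectorized, recycled to length `n`).
#' @return Numeric vector of `n` non-negative draws.
#' @export
rtnorm_lower0 <- function(n, mean, sd) {
  if (any(sd <= 0)) abort("`sd` must be positive.")
  a <- -mean / sd                    # standardized lower bound
  log_tail <- pnorm(a, lower.tail = FALSE, log.p = TRUE)
  u <- runif(n)
  x <- qnorm(log(u) + log_tail, lower.tail = FALSE, log.p = TRUE)
  pmax(mean + sd * x, 0)
}

#' Mean of the lower-truncated normal
#'
#' Closed-form `E[X | X >= 0]` for `X ~ N(mean, sd^2)`:
#' `mean + sd * phi(mean/sd) / Phi(mean/sd)`.  Used as an oracle for the
#' sampler and in efficiency summaries.
#'
#' @inheritParams rtnorm_lower0
#' @return Numeric vector.
#' @export
tnorm_lower0_mean <- function(mean, sd) {
  r <- mean / sd
  mean + sd * exp(dnorm(r, log = TRUE) - pnorm(r, log.p = TRUE))
}

#' Full-conditional draw of the latent inefficiency innovation
#'
#' In the composed-error model the innovation `u*` given everything else
#' is normal truncated below at zero with
#' `s2 = 1 / (1/sigma_ustar2 + alpha^2/sigma_v2)` and
#' `m = s2 * alpha * (eta_y - y) / sigma_v2`.  `residual` is
#' `y - eta_y`.  The draw is exact (inverse CDF), so extreme means pose
#' no failure mode.
#'
#' @param residual Composed-error residual `y - eta_y` (vector).
#' @param alpha Multiplicative inefficiency scale `exp(eta_u)` (vector).
#' @param sigma_v2,sigma_ustar2 Noise and innovation variances.
#' @return Non-negative draws, one per residual.
#' @export
sample_ustar_conditional <- function(residual, alpha, sigma_v2,
                                     sigma_ustar2) {
  assert_positive(sigma_v2, "sigma_v2")
  assert_positive(sigma_ustar2, "sigma_ustar2")
  s2 <- pmax(1 / (1 / sigma_ustar2 + alpha^2 / sigma_v2), 1e-300)
  m <- -s2 * alpha * residual / sigma_v2
  m[!is.finite(m)] <- 0   # overflowing scale: conditional collapses at 0
  rtnorm_lower0(length(residual), m, sqrt(s2))
}
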