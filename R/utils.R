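#' @importFrom rlang %||% abort warn inform
#' @importFrom stats dnorm pnorm qnorm rnorm runif rgamma rbeta rbinom rpois
#'   setNames var sd quantile cor glm binomial coef integrate
#' @importFrom utils head
NULL

# single place for the wave labels used throughout the stroke application
default_waves <- function() c(2006L, 2008L, 2010L, 2012L, 2013L)

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0L && all(x %in% c(0, 1))
}

# stable 32-bit-ish fingerprint of a numeric payload, used to guard that
# DIC/WAIC comparisons refer to identical observations
data_fingerprint <- function(y) {
  y <- round(as.numeric(y), 10)
  s <- sum(y * seq_along(y)) + sum(abs(y)) + length(y)
  sprintf("n%d-%.10e", length(y), s)
}

`%na%` <- function(x, default) ifelse(is.na(x), default, x)

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite.", name))
  }
  invisible(x)
}
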