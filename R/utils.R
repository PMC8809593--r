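## Shape parameters closer to zero than this are evaluated with the
## exponential-limit formulas to avoid catastrophic cancellation.
XI_EPS <- 1e-4

#' Standard Laplace distribution
#'
#' Quantile and distribution functions of the standard Laplace (double
#' exponential) distribution, the common margin onto which all variables are
#' transformed before dependence modelling.  Its upper and lower tails are
#' unit-rate exponential, so exceedances of a high level `v` are
#' `v + Exp(1)` distributed.
#'
#' @param p Probabilities in (0, 1).
#' @param y Quantiles.
#' @return `laplace_quantile()` returns quantiles; `laplace_cdf()` returns
#'   probabilities.
#' @examples
#' laplace_quantile(c(0.25, 0.5, 0.9))
#' laplace_cdf(0)
#' @export
laplace_quantile <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  ifelse(p < 0.5, log(2 * p), -log(2 * (1 - p)))
}

#' @rdname laplace_quantile
#' @export
laplace_cdf <- function(y) {
  ifelse(y < 0, 0.5 * exp(y), 1 - 0.5 * exp(-y))
}

## One empirical-quantile convention package-wide (linear interpolation,
## the common default "type 7").
quantile7 <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE)
}

#' Derive a child random seed
#'
#' Deterministically derives a stream of child seeds from a master seed so
#' that every stage and every bootstrap replicate of a run is reproducible
#' in isolation.  Results stay below 2^31 so they are valid R integer seeds.
#'
#' @param seed Master seed (single integer-valued number).
#' @param k Stream index (non-negative integer, may be vectorised).
#' @return Integer vector of child seeds.
#' @examples
#' derive_seed(1, 0:3)
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  as.integer(((abs(seed) %% 1000003) * 48271 + k * 104729) %% 2147483629 + 1)
}

## Small helper: stop unless all config quantile levels are in (0,1).
check_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    abort(paste0("`", what, "` must lie strictly inside (0, 1)"))
  }
  invisible(x)
}
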