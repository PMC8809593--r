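#' Fit the semi-parametric marginal model
#'
#' Models one variable with the empirical distribution below a high
#' threshold and a generalized Pareto tail above it:
#' \deqn{\hat F(x) = 1 - \{1 - \tilde F(u)\}\{1 + \xi (x-u)/\beta\}_+^{-1/\xi}
#'   \quad (x > u), \qquad \hat F(x) = \tilde F(x) \quad (x \le u),}
#' where \eqn{\tilde F} is the empirical distribution function evaluated as
#' ranks/(n+1) so it never reaches 1.  The threshold is an empirical
#' quantile of the sample (default the 80th percentile); mean-residual-life
#' diagnostics to support that choice are available from
#' [mean_residual_life()].
#'
#' @param x Numeric sample, no missing values.
#' @param threshold_quantile Quantile level of the GPD threshold, in (0, 1);
#'   default 0.8.
#' @param min_exceedances Minimum exceedance count for the tail fit.
#' @return An object of class `marginal_model`: list with the sorted sample,
#'   threshold `u`, its empirical probability `F_u`, `tail_fraction`
#'   `1 - F_u`, and the `gpd_fit` for the excesses.
#' @seealso [marginal_cdf()], [marginal_quantile()], [to_laplace()]
#' @examples
#' set.seed(1)
#' m <- fit_marginal(rt(500, df = 5))
#' glance(m)
#' @export
fit_marginal <- function(x, threshold_quantile = 0.8, min_exceedances = 10) {
  stopifnot(is.numeric(x), !anyNA(x))
  check_prob(threshold_quantile, "threshold_quantile")
  n <- length(x)
  u <- quantile7(x, threshold_quantile)
  F_u <- sum(x <= u) / (n + 1)
  gpd <- fit_gpd(x, threshold = u, min_exceedances = min_exceedances)
  structure(
    list(
      x_sorted = sort(x), n = n, u = u,
      threshold_quantile = threshold_quantile,
      F_u = F_u, tail_fraction = 1 - F_u, gpd = gpd
    ),
    class = "marginal_model"
  )
}

#' Semi-parametric distribution and quantile functions
#'
#' `marginal_cdf()` evaluates the fitted semi-parametric distribution
#' function (empirical ranks/(n+1) below the threshold, GPD tail above);
#' `marginal_quantile()` is its generalized inverse, with the closed-form
#' GPD inversion used for probabilities at or above the threshold
#' probability.
#'
#' @param model A `marginal_model`.
#' @param x Values at which to evaluate the CDF.
#' @param p Probabilities in (0, 1).
#' @return Numeric vector of probabilities (in `[0, 1)`) or quantiles.
#' @examples
#' set.seed(1)
#' m <- fit_marginal(rnorm(500))
#' marginal_cdf(m, marginal_quantile(m, 0.99))
#' @export
marginal_cdf <- function(model, x) {
  stopifnot(inherits(model, "marginal_model"))
  n <- model$n
  p <- findInterval(x, model$x_sorted) / (n + 1)
  above <- x > model$u
  if (any(above)) {
    g <- model$gpd
    p[above] <- 1 - model$tail_fraction *
      (1 - pgpd(x[above] - model$u, scale = g$scale, shape = g$shape))
  }
  p
}

#' @rdname marginal_cdf
#' @export
marginal_quantile <- function(model, p) {
  stopifnot(inherits(model, "marginal_model"))
  if (any(p <= 0) || any(p >= 1)) {
    abort("probabilities must lie strictly inside (0, 1)")
  }
  n <- model$n
  out <- numeric(length(p))
  tail <- p >= model$F_u
  if (any(tail)) {
    g <- model$gpd
    ptail <- 1 - (1 - p[tail]) / model$tail_fraction
    out[tail] <- model$u + qgpd(ptail, scale = g$scale, shape = g$shape)
  }
  if (any(!tail)) {
    k <- pmin(pmax(ceiling(p[!tail] * (n + 1)), 1), n)
    out[!tail] <- model$x_sorted[k]
  }
  out
}

#' Transform between original and standard Laplace margins
#'
#' `to_laplace()` maps data through the fitted semi-parametric distribution
#' onto the standard Laplace scale:
#' `y = log(2F)` when `F < 1/2` and `y = -log(2(1 - F))` otherwise.
#' `from_laplace()` inverts the transformation through
#' [marginal_quantile()].  Probabilities that reach 0 or 1 numerically are
#' clamped into `[eps, 1 - eps]` with `eps = 1/(2n)`, with a warning.
#'
#' @param model A `marginal_model`.
#' @param x Data on the original scale.
#' @param y Data on the Laplace scale.
#' @return Numeric vector on the Laplace (`to_laplace`) or original
#'   (`from_laplace`) scale.
#' @examples
#' set.seed(1)
#' m <- fit_marginal(rnorm(2000))
#' y <- to_laplace(m, c(-1, 0, 2))
#' from_laplace(m, y)
#' @export
to_laplace <- function(model, x) {
  stopifnot(inherits(model, "marginal_model"))
  p <- marginal_cdf(model, x)
  eps <- 1 / (2 * model$n)
  if (any(p < eps) || any(p > 1 - eps)) {
    warn(
      sprintf(
        "%d probabilities clamped to within [eps, 1 - eps], eps = %.3g, before the Laplace transform",
        sum(p < eps | p > 1 - eps), eps
      ),
      class = "cropfragility_clamp"
    )
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  laplace_quantile(p)
}

#' @rdname to_laplace
#' @export
from_laplace <- function(model, y) {
  stopifnot(inherits(model, "marginal_model"))
  marginal_quantile(model, laplace_cdf(y))
}

#' Mean residual life diagnostic
#'
#' Mean excess over each candidate threshold with a normal-approximation
#' pointwise confidence band.  Approximate linearity of the curve above a
#' threshold supports the GPD assumption there.  Thresholds with fewer than
#' two exceedances (including any at or above the sample maximum) are
#' returned with `defined = FALSE`.
#'
#' @param x Numeric sample.
#' @param thresholds Candidate thresholds; default 30 values spanning the
#'   sample range up to its 98th percentile.
#' @param level Confidence level of the band (default 0.95).
#' @return A tibble of class `mrl_curve` with columns `threshold`, `n_exc`,
#'   `mean_excess`, `se`, `ci_low`, `ci_high`, `defined`.
#' @examples
#' set.seed(1)
#' mean_residual_life(rexp(1000))
#' @export
mean_residual_life <- function(x, thresholds = NULL,
                               level = 0.95) {
  stopifnot(is.numeric(x), !anyNA(x))
  if (is.null(thresholds)) {
    thresholds <- seq(min(x), quantile7(x, 0.98), length.out = 30)
  }
  z <- qnorm(1 - (1 - level) / 2)
  rows <- purrr::map(thresholds, function(t) {
    exc <- x[x > t] - t
    if (t >= max(x) || length(exc) < 2) {
      return(tibble::tibble(
        threshold = t, n_exc = length(exc), mean_excess = NA_real_,
        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_, defined = FALSE
      ))
    }
    m <- mean(exc)
    se <- sd(exc) / sqrt(length(exc))
    tibble::tibble(
      threshold = t, n_exc = length(exc), mean_excess = m, se = se,
      ci_low = m - z * se, ci_high = m + z * se, defined = TRUE
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mrl_curve", class(out))
  out
}

#' @export
print.marginal_model <- function(x, ...) {
  cat(sprintf(
    "Semi-parametric marginal: n = %d, threshold u = %.4g (q = %.2f, F(u) = %.4f)\n",
    x$n, x$u, x$threshold_quantile, x$F_u
  ))
  print(x$gpd)
  invisible(x)
}

#' @method tidy marginal_model
#' @export
tidy.marginal_model <- function(x, ...) {
  tidy(x$gpd)
}

#' @method glance marginal_model
#' @export
glance.marginal_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, threshold = x$u, threshold_quantile = x$threshold_quantile,
    F_u = x$F_u, tail_fraction = x$tail_fraction,
    scale = x$gpd$scale, shape = x$gpd$shape, n_exc = x$gpd$n_exc
  )
}
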