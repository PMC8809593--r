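## Default extrapolation grid: the 91st to 99.99th conditioning quantiles.
default_grid <- function() {
  c(seq(0.91, 0.99, by = 0.01), 0.995, 0.999, 0.9999)
}

#' Simulate pseudo-samples from the fitted conditional model
#'
#' Draws from the fitted joint tail conditional on the conditioning
#' variable exceeding its `q_c` quantile.  On the Laplace scale the
#' exceedance of a high level is unit-exponential, so each draw is
#' `y_cond = v + E` with `v` the Laplace `q_c` level and `E ~ Exp(1)`; the
#' residual `z` is resampled with replacement from the fitted empirical
#' residual distribution and `y_resp = a y_cond + y_cond^b z`.  When the
#' marginal models are supplied, draws are also back-transformed to the
#' original scale.
#'
#' @param fit An `ht_fit`.
#' @param q_c Conditioning quantile level; must be at or above the fit's
#'   `q_dep` (extrapolation only above the fitted threshold).
#' @param n_sim Number of draws (default 1000).
#' @param seed Optional seed for reproducibility.
#' @param marginals Optional list with `marginal_model`s `response` and
#'   `conditioning` (as attached to a `laplace_pair`) for back-transforming.
#' @return A tibble of class `pseudo_sample` with columns `y_cond`,
#'   `y_resp` (and `x_cond`, `x_resp` when `marginals` is given); `q_c`,
#'   `n_sim` and `seed` are attributes.
#' @export
simulate_conditional <- function(fit, q_c, n_sim = 1000, seed = NULL,
                                 marginals = NULL) {
  stopifnot(inherits(fit, "ht_fit"))
  check_prob(q_c, "q_c")
  if (q_c < fit$q_dep) {
    abort(sprintf(
      "q_c = %.4f is below the fitted dependence threshold q_dep = %.4f; extrapolation is only valid above it",
      q_c, fit$q_dep
    ))
  }
  if (!is.null(seed)) set.seed(seed)
  v <- laplace_quantile(q_c)
  y_cond <- v + rexp(n_sim)
  z <- sample(fit$residuals, n_sim, replace = TRUE)
  y_resp <- fit$a * y_cond + y_cond^fit$b * z
  out <- tibble::tibble(y_cond = y_cond, y_resp = y_resp)
  if (!is.null(marginals)) {
    out$x_cond <- from_laplace(marginals$conditioning, y_cond)
    out$x_resp <- from_laplace(marginals$response, y_resp)
  }
  attr(out, "q_c") <- q_c
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  class(out) <- c("pseudo_sample", class(out))
  out
}

#' Conditional loss-probability point estimate
#'
#' Estimates `P(response > its q_r quantile | conditioning > its q_c
#' quantile)` as the fraction of pseudo-sample draws whose response exceeds
#' the Laplace-scale `q_r` level.  Because the Laplace transform is
#' monotone, counting exceedances on the Laplace or the original scale
#' gives identical estimates.
#'
#' @param pseudo A `pseudo_sample`.
#' @param q_r Response quantile level (default 0.90, i.e. a loss beyond its
#'   90th-percentile severity).
#' @return A one-row tibble with `q_c`, `q_r`, `point`, `n_sim`.
#' @export
conditional_probability <- function(pseudo, q_r = 0.9) {
  stopifnot(inherits(pseudo, "pseudo_sample"), nrow(pseudo) > 0)
  check_prob(q_r, "q_r")
  tibble::tibble(
    q_c = attr(pseudo, "q_c", exact = TRUE),
    q_r = q_r,
    point = mean(pseudo$y_resp > laplace_quantile(q_r)),
    n_sim = nrow(pseudo)
  )
}

## Run `expr` while counting (and muffling) marginal clamp warnings, so
## high-volume loops report one count instead of a warning per fit.
count_clamp_warnings <- function(expr) {
  n <- 0L
  value <- withCallingHandlers(
    expr,
    cropfragility_clamp = function(w) {
      n <<- n + 1L
      invokeRestart("muffleWarning")
    }
  )
  list(value = value, n_clamped = n)
}

## Shared driver: marginals + transform + dependence fit for one pair.
fit_pair_pipeline <- function(pair, threshold_quantile, q_dep,
                              min_exceedances, n_starts = 5) {
  lp <- transform_pair(pair, threshold_quantile = threshold_quantile,
                       min_exceedances = min_exceedances)
  fit <- fit_conditional(lp, q_dep = q_dep,
                         min_exceedances = min_exceedances,
                         n_starts = n_starts)
  list(pair = lp, fit = fit, marginals = attr(lp, "marginals", exact = TRUE))
}

curve_points <- function(fit, grid, q_r, n_sim, seed) {
  purrr::imap(grid, function(q_c, i) {
    ps <- simulate_conditional(fit, q_c, n_sim = n_sim,
                               seed = derive_seed(seed, i))
    conditional_probability(ps, q_r = q_r)
  }) |>
    dplyr::bind_rows()
}

#' Conditional loss-probability curve
#'
#' Runs the full pipeline for one variable pair on the original scale:
#' fits both semi-parametric marginals, transforms to Laplace margins,
#' fits the conditional dependence model, and estimates the conditional
#' loss probability by Monte-Carlo simulation at each level of an
#' increasing grid of conditioning quantiles (default the 91st to 99.99th).
#' Fully deterministic given `seed`.
#'
#' @param pair A `variable_pair` on the original (standardized) scale.
#' @param threshold_quantile Marginal GPD threshold quantile (default 0.8).
#' @param q_dep Dependence threshold quantile (default 0.90).
#' @param grid Strictly increasing conditioning-quantile grid, all at or
#'   above `q_dep`.
#' @param q_r Response quantile defining a severe loss (default 0.90).
#' @param n_sim Simulated observations per grid level (default 1000).
#' @param seed Master seed for this curve.
#' @param min_exceedances Minimum exceedance counts for all fits.
#' @return A tibble of class `cond_prob_curve` with columns `region`,
#'   `crop`, `variable`, `orientation`, `q_c`, `q_r`, `point`, `n_sim`;
#'   the fitted models are kept in the `"fits"` attribute.
#' @export
probability_curve <- function(pair, threshold_quantile = 0.8, q_dep = 0.9,
                              grid = default_grid(), q_r = 0.9,
                              n_sim = 1000, seed = 1,
                              min_exceedances = 10) {
  check_prob(grid, "grid")
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing")
  }
  if (any(grid < q_dep)) {
    abort("all grid levels must be at or above the dependence threshold q_dep")
  }
  piped <- fit_pair_pipeline(pair, threshold_quantile, q_dep, min_exceedances)
  pts <- curve_points(piped$fit, grid, q_r, n_sim, seed)
  labels <- pair_labels(pair)
  out <- dplyr::bind_cols(tibble::as_tibble(labels[c("region", "crop",
                                                     "variable", "orientation")]),
                          pts)
  attr(out, "fits") <- piped
  attr(out, "config") <- list(
    threshold_quantile = threshold_quantile, q_dep = q_dep, grid = grid,
    q_r = q_r, n_sim = n_sim, seed = seed
  )
  class(out) <- c("cond_prob_curve", class(out))
  out
}

#' Bootstrap confidence intervals for a probability curve
#'
#' Percentile bootstrap for the conditional loss-probability curve:
#' observation rows (paired response/conditioning values) are resampled
#' with replacement `n_boot` times and the whole pipeline - marginal fits,
#' Laplace transform, dependence fit, simulation - is refit on each
#' replicate with deterministically derived seeds.  Interval bounds at
#' level `level` are the `ceiling(alpha/2 * m)` and
#' `ceiling((1 - alpha/2) * m)` order statistics of the `m` successful
#' replicate estimates (for 100 replicates at the 95% level: the 3rd and
#' 98th).  Replicates that fail to fit are counted and excluded, with a
#' warning; more than 50% failures is an error.
#'
#' @inheritParams probability_curve
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param level Confidence level (default 0.95).
#' @param refit_marginals Refit the marginal GPDs inside each replicate
#'   (default TRUE, the fully non-parametric reading)?  When FALSE the
#'   original marginal transforms are frozen and only the dependence stage
#'   and simulation are refit.
#' @param boot_starts Optimisation starts per bootstrap replicate (default
#'   2, for speed).
#' @return A `cond_prob_curve` tibble with additional columns `ci_low`,
#'   `ci_high`, `n_boot`; the replicate estimates matrix, the failure
#'   count and the count of marginal clamp warnings are attributes.
#' @export
bootstrap_cis <- function(pair, threshold_quantile = 0.8, q_dep = 0.9,
                          grid = default_grid(), q_r = 0.9, n_sim = 1000,
                          n_boot = 100, level = 0.95, seed = 1,
                          min_exceedances = 10, refit_marginals = TRUE,
                          boot_starts = 2) {
  stopifnot(n_boot >= 2)
  check_prob(level, "level")
  counted <- count_clamp_warnings(
    probability_curve(
      pair, threshold_quantile = threshold_quantile, q_dep = q_dep,
      grid = grid, q_r = q_r, n_sim = n_sim, seed = derive_seed(seed, 0),
      min_exceedances = min_exceedances
    )
  )
  curve <- counted$value
  n_clamped <- counted$n_clamped
  piped <- attr(curve, "fits", exact = TRUE)
  n <- nrow(pair)
  reps_counted <- count_clamp_warnings(purrr::map(seq_len(n_boot), function(k) {
    seed_k <- derive_seed(seed, k)
    set.seed(seed_k)
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch({
      if (refit_marginals) {
        bp <- fit_pair_pipeline(pair[idx, , drop = FALSE],
                                threshold_quantile, q_dep,
                                min_exceedances, n_starts = boot_starts)
        bfit <- bp$fit
      } else {
        lp <- piped$pair[idx, , drop = FALSE]
        attr(lp, "marginals") <- piped$marginals
        bfit <- fit_conditional(lp, q_dep = q_dep,
                                min_exceedances = min_exceedances,
                                n_starts = boot_starts)
      }
      curve_points(bfit, grid, q_r, n_sim, derive_seed(seed_k, 1))$point
    }, error = function(e) rep(NA_real_, length(grid)))
  }))
  reps <- reps_counted$value
  n_clamped <- n_clamped + reps_counted$n_clamped
  mat <- do.call(rbind, reps)
  ok <- rowSums(is.na(mat)) == 0
  n_failed <- sum(!ok)
  if (n_failed > n_boot / 2) {
    abort(sprintf("%d of %d bootstrap replicates failed to fit", n_failed, n_boot))
  }
  if (n_failed > 0) {
    warn(sprintf("%d of %d bootstrap replicates failed and were excluded",
                 n_failed, n_boot))
  }
  mat <- mat[ok, , drop = FALSE]
  alpha <- 1 - level
  m <- nrow(mat)
  lo_k <- max(1, ceiling(alpha / 2 * m))
  hi_k <- min(m, ceiling((1 - alpha / 2) * m))
  ci <- apply(mat, 2, function(p) sort(p)[c(lo_k, hi_k)])
  curve$ci_low <- ci[1, ]
  curve$ci_high <- ci[2, ]
  curve$n_boot <- m
  attr(curve, "boot_estimates") <- mat
  attr(curve, "n_failed") <- n_failed
  attr(curve, "n_clamped") <- n_clamped
  attr(curve, "level") <- level
  curve
}
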