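#' Transform a variable pair to Laplace margins
#'
#' Fits the semi-parametric marginal model to each component of a pair and
#' maps both onto the standard Laplace scale, the common margin on which
#' the conditional dependence model is estimated.
#'
#' @param pair A `variable_pair` (columns `response`, `conditioning`).
#' @param threshold_quantile Marginal GPD threshold quantile, a single
#'   value or a length-2 vector `(response, conditioning)`; default 0.8 for
#'   both.
#' @param min_exceedances Minimum marginal exceedance count.
#' @return A tibble of class `laplace_pair` with transformed `response` and
#'   `conditioning`; the two `marginal_model` fits are kept in the
#'   `"marginals"` attribute and pair labels are carried over.
#' @export
transform_pair <- function(pair, threshold_quantile = 0.8,
                           min_exceedances = 10) {
  stopifnot(all(c("response", "conditioning") %in% names(pair)))
  tq <- rep_len(threshold_quantile, 2)
  m_resp <- fit_marginal(pair$response, tq[1], min_exceedances)
  m_cond <- fit_marginal(pair$conditioning, tq[2], min_exceedances)
  out <- pair
  out$response <- to_laplace(m_resp, pair$response)
  out$conditioning <- to_laplace(m_cond, pair$conditioning)
  attr(out, "marginals") <- list(response = m_resp, conditioning = m_cond)
  class(out) <- unique(c("laplace_pair", class(pair)))
  out
}

## Profiled negative log-likelihood of the conditional model at (a, b):
## residual location/scale are the Gaussian working model's closed-form
## optima, so only (a, b) are searched numerically.  Additive constants
## dropped.
ht_profile_nll <- function(a, b, y, y_resp) {
  logw <- b * log(y)
  z <- (y_resp - a * y) * exp(-logw)
  if (any(!is.finite(z))) return(1e10)
  s2 <- mean((z - mean(z))^2)
  if (!is.finite(s2)) return(1e10)
  sum(logw) + length(y) * 0.5 * log(max(s2, 1e-300))
}

#' Joint consistency constraints on the dependence parameters
#'
#' Checks whether a candidate `(a, b)` is admissible: inside the box
#' `-1 <= a <= 1`, `b < 1`, and such that the fitted conditional quantiles
#' of the response do not exceed (fall below) the quantiles implied by
#' perfect positive (negative) dependence, evaluated at the largest
#' conditioning exceedance and in the limit of an infinitely large
#' conditioning value.  The reference quantile levels of the residual
#' distribution default to 2.5% and 97.5%.
#'
#' @param a,b Candidate dependence parameters (scalars).
#' @param y Conditioning exceedances on the Laplace scale (positive).
#' @param y_resp Corresponding response values on the Laplace scale.
#' @param q Residual quantile levels `(lower, upper)` at which the bounds
#'   are enforced.
#' @return `TRUE` if the candidate is feasible.
#' @export
constraints_feasible <- function(a, b, y, y_resp, q = c(0.025, 0.975)) {
  stopifnot(length(a) == 1, length(b) == 1, length(y) == length(y_resp))
  if (!is.finite(a) || !is.finite(b)) return(FALSE)
  if (a < -1 || a > 1 || b >= 1) return(FALSE)
  z <- (y_resp - a * y) / y^b
  feasible_core(
    a, b, z,
    v = max(y),
    c_pos = quantile7(y_resp - y, q[2]),
    c_neg = quantile7(y_resp + y, q[1]),
    q = q
  )
}

## Core of the joint-constraint predicate, with the perfect-dependence
## bound quantiles (c_pos, c_neg) and the largest conditioning value (v)
## precomputed by the caller so the check is cheap inside optimisation
## loops.  Fast O(n) type-7 quantiles via partial sorting.
q7_fast <- function(x, p) {
  n <- length(x)
  h <- (n - 1) * p + 1
  fl <- floor(h)
  up <- min(fl + 1, n)
  xs <- sort(x, partial = unique(c(fl, up)))
  xs[fl] + (h - fl) * (xs[up] - xs[fl])
}

feasible_core <- function(a, b, z, v, c_pos, c_neg, q = c(0.025, 0.975)) {
  if (!is.finite(a) || !is.finite(b)) return(FALSE)
  if (a < -1 || a > 1 || b >= 1) return(FALSE)
  if (any(!is.finite(z))) return(FALSE)
  z_lo <- q7_fast(z, q[1])
  z_hi <- q7_fast(z, q[2])
  tol <- 1e-10
  vb <- v^b
  ## fitted upper conditional quantile must not exceed the perfect
  ## positive-dependence bound at v ...
  if (a * v + vb * z_hi > v + c_pos + tol) return(FALSE)
  ## ... nor as y -> infinity
  up_lim <- if (a < 1) {
    -Inf
  } else if (b > 0) {
    if (z_hi > 0) Inf else if (z_hi < 0) -Inf else -c_pos
  } else if (b == 0) {
    z_hi - c_pos
  } else {
    -c_pos
  }
  if (up_lim > tol) return(FALSE)
  ## fitted lower conditional quantile must not fall below the perfect
  ## negative-dependence bound at v ...
  if (a * v + vb * z_lo < -v + c_neg - tol) return(FALSE)
  ## ... nor as y -> infinity
  lo_lim <- if (a > -1) {
    -Inf
  } else if (b > 0) {
    if (z_lo < 0) Inf else if (z_lo > 0) -Inf else c_neg
  } else if (b == 0) {
    c_neg - z_lo
  } else {
    c_neg
  }
  if (lo_lim > tol) return(FALSE)
  TRUE
}

## Default deterministic starting points for the (a, b) search, augmented
## with a correlation-based guess.
ht_default_starts <- function(y, y_resp, n_starts = 5) {
  a0 <- suppressWarnings(cor(y, y_resp))
  if (!is.finite(a0)) a0 <- 0
  a0 <- max(-0.95, min(0.95, a0))
  all <- list(
    c(a0, 0.2), c(0.5, 0.2), c(-0.5, 0.2), c(0.1, 0.6), c(0.9, -0.2),
    c(-0.9, -0.2), c(0, 0), c(a0, -0.5)
  )
  all[seq_len(max(1, min(n_starts, length(all))))]
}

#' Fit the conditional extremal dependence model
#'
#' Estimates the conditional extremes regression
#' \deqn{Y_{resp} \mid Y_{cond} = y \;=\; a\,y + y^{b} Z, \qquad y > u,}
#' for conditioning values above the `q_dep` empirical quantile on the
#' Laplace scale, with `-1 <= a <= 1`, `b < 1` and the joint consistency
#' constraints of [constraints_feasible()].  Estimation maximises the
#' pseudo-likelihood in which `Z` is treated as independent Gaussian with
#' free location and scale; the residual distribution used downstream is
#' the empirical one regardless.  The search runs in unconstrained internal
#' coordinates (`a = tanh`, `b = 1 - exp`) from several deterministic
#' starting points, and infeasible candidates are rejected.
#'
#' @param pair A `laplace_pair` (see [transform_pair()]), or any tibble
#'   with Laplace-scale `response` and `conditioning` columns.
#' @param q_dep Dependence threshold quantile of the conditioning variable
#'   (default 0.90).
#' @param min_exceedances Minimum conditioning exceedances (default 10).
#' @param n_starts Number of optimisation starts (default 5).
#' @param starts Optional list of explicit `c(a, b)` starting points,
#'   overriding the deterministic defaults.
#' @param constrain Apply the joint consistency constraints? (default TRUE)
#' @param constraint_q Residual quantile levels for the constraints.
#' @return An object of class `ht_fit`: list with `a`, `b`, `mu`, `sigma`
#'   (Gaussian working residual location/scale), `residuals`, the
#'   exceedance data `y` and `y_resp`, `u_y`, `q_dep`, `n_exc`,
#'   `b_unidentified` (TRUE when the residual spread is numerically zero so
#'   `b` carries no information), `nll` and convergence metadata.
#' @examples
#' spec <- synthetic_spec("gaussian", dep = 0.6, n = 2000, seed = 7)
#' pair <- transform_pair(gen_pair(spec))
#' fit <- fit_conditional(pair)
#' tidy(fit)
#' @export
fit_conditional <- function(pair, q_dep = 0.9, min_exceedances = 10,
                            n_starts = 5, constrain = TRUE,
                            constraint_q = c(0.025, 0.975), starts = NULL) {
  stopifnot(all(c("response", "conditioning") %in% names(pair)))
  check_prob(q_dep, "q_dep")
  ## the regression form y^b needs positive conditioning values, so the
  ## Laplace-scale threshold is floored at zero (the standard Laplace
  ## median) when a scan quantile falls below it
  u_y <- max(quantile7(pair$conditioning, q_dep), 0)
  sel <- pair$conditioning > u_y
  if (sum(sel) < min_exceedances) {
    abort(sprintf(
      "only %d conditioning exceedances above the %.3f quantile (minimum %d)",
      sum(sel), q_dep, min_exceedances
    ))
  }
  y <- pair$conditioning[sel]
  y_resp <- pair$response[sel]
  ## perfect-dependence bound quantiles, fixed across candidates
  v_max <- max(y)
  c_pos <- quantile7(y_resp - y, constraint_q[2])
  c_neg <- quantile7(y_resp + y, constraint_q[1])
  n_exc <- length(y)
  log_y <- log(y)
  feasible <- function(a, b) {
    !constrain ||
      feasible_core(a, b, (y_resp - a * y) / y^b, v_max, c_pos, c_neg,
                    q = constraint_q)
  }
  ## unconstrained internal coordinates; residuals computed once per
  ## candidate and shared between the constraint check and the likelihood
  obj <- function(par) {
    a <- tanh(par[1])
    b <- 1 - exp(-par[2])
    logw <- b * log_y
    z <- (y_resp - a * y) * exp(-logw)
    if (any(!is.finite(z))) return(1e10)
    if (constrain &&
          !feasible_core(a, b, z, v_max, c_pos, c_neg, q = constraint_q)) {
      return(1e10)
    }
    s2 <- mean((z - mean(z))^2)
    if (!is.finite(s2)) return(1e10)
    sum(logw) + n_exc * 0.5 * log(max(s2, 1e-300))
  }
  to_internal <- function(a, b) {
    c(atanh(max(-0.999999, min(0.999999, a))), -log(max(1 - b, 1e-8)))
  }
  if (is.null(starts)) starts <- ht_default_starts(y, y_resp, n_starts)
  ## guarantee at least one feasible launching point where possible
  if (!any(vapply(starts, function(s) feasible(s[1], s[2]), logical(1)))) {
    starts <- c(starts, list(c(0, 0)), ht_default_starts(y, y_resp, 8))
  }
  trace <- list()
  best <- NULL
  for (s in starts) {
    if (!feasible(s[1], s[2])) next
    o <- tryCatch(
      optim(to_internal(s[1], s[2]), obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    trace <- c(trace, list(list(start = s, value = o$value,
                                convergence = o$convergence)))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e10) {
    abort(paste0(
      "no feasible optimum found from ", length(starts), " starts; ",
      "inspect profile_surface() for the feasible region"
    ))
  }
  a_hat <- tanh(best$par[1])
  b_hat <- 1 - exp(-best$par[2])
  z <- (y_resp - a_hat * y) / y^b_hat
  sigma <- sqrt(mean((z - mean(z))^2))
  structure(
    list(
      a = a_hat, b = b_hat, mu = mean(z), sigma = sigma,
      residuals = z, y = y, y_resp = y_resp,
      u_y = u_y, q_dep = q_dep, n_exc = length(y),
      b_unidentified = sigma < 1e-8,
      constrained = constrain, constraint_q = constraint_q,
      nll = best$value, n_starts_used = length(trace), starts = trace,
      labels = pair_labels(pair)
    ),
    class = "ht_fit"
  )
}

#' @export
print.ht_fit <- function(x, ...) {
  cat(sprintf(
    "Conditional extremes fit: a = %.4f, b = %.4f%s\n  %d exceedances above the %.2f quantile (u_Y = %.3f); residual mu = %.3f, sigma = %.3f\n",
    x$a, x$b, if (x$b_unidentified) " (b unidentified: degenerate residuals)" else "",
    x$n_exc, x$q_dep, x$u_y, x$mu, x$sigma
  ))
  invisible(x)
}

#' @method tidy ht_fit
#' @export
tidy.ht_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "mu", "sigma"),
    estimate = c(x$a, x$b, x$mu, x$sigma)
  )
}

#' @method glance ht_fit
#' @export
glance.ht_fit <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, n_exc = x$n_exc, q_dep = x$q_dep, u_y = x$u_y,
    nll = x$nll, b_unidentified = x$b_unidentified,
    constrained = x$constrained
  )
}

#' Profile likelihood surface over the dependence parameters
#'
#' Evaluates the profiled working-model negative log-likelihood (residual
#' location and scale optimised out in closed form) on a grid over
#' `(a, b)`, together with the feasibility mask of the joint constraints.
#' The fitted point should sit within one grid cell of the feasible grid
#' optimum; a warning is raised otherwise.
#'
#' @param pair A `laplace_pair`.
#' @param q_dep Dependence threshold quantile (default 0.90).
#' @param a_grid,b_grid Grid nodes.
#' @param fit Optional existing `ht_fit` for the same pair and threshold.
#' @inheritParams fit_conditional
#' @return A tibble of class `ht_profile` with columns `a`, `b`, `nll`,
#'   `feasible`; the fitted point and consistency flag are attributes.
#' @export
profile_surface <- function(pair, q_dep = 0.9,
                            a_grid = seq(-1, 1, length.out = 41),
                            b_grid = seq(-2, 0.95, length.out = 41),
                            fit = NULL, constraint_q = c(0.025, 0.975)) {
  if (is.null(fit)) fit <- fit_conditional(pair, q_dep = q_dep,
                                           constraint_q = constraint_q)
  y <- fit$y
  y_resp <- fit$y_resp
  grid <- tidyr::expand_grid(a = a_grid, b = b_grid)
  grid$nll <- purrr::map2_dbl(grid$a, grid$b, ht_profile_nll, y = y, y_resp = y_resp)
  grid$feasible <- purrr::map2_lgl(
    grid$a, grid$b,
    ~ constraints_feasible(.x, .y, y, y_resp, q = constraint_q)
  )
  if (!any(grid$feasible)) {
    abort("no feasible grid node; widen the grid or relax the constraints")
  }
  feas <- grid[grid$feasible, ]
  opt <- feas[which.min(feas$nll), ]
  cell <- c(
    if (length(a_grid) > 1) max(diff(sort(unique(a_grid)))) else Inf,
    if (length(b_grid) > 1) max(diff(sort(unique(b_grid)))) else Inf
  )
  consistent <- abs(opt$a - fit$a) <= cell[1] + 1e-12 &&
    abs(opt$b - fit$b) <= cell[2] + 1e-12
  if (!consistent) {
    warn(sprintf(
      "fitted point (%.3f, %.3f) is more than one grid cell from the feasible grid optimum (%.3f, %.3f)",
      fit$a, fit$b, opt$a, opt$b
    ))
  }
  attr(grid, "fit") <- fit
  attr(grid, "grid_optimum") <- opt
  attr(grid, "optimum_consistent") <- consistent
  class(grid) <- c("ht_profile", class(grid))
  grid
}

#' Threshold stability of the dependence parameters
#'
#' Refits the conditional model at a grid of candidate dependence-threshold
#' quantiles (default the 50th to 90th percentiles in steps of 5) and
#' attaches percentile bootstrap bands, supporting the choice of the
#' dependence threshold: estimates should be stable, within uncertainty,
#' above a valid threshold.  Candidates that leave fewer than
#' `min_exceedances` exceedances are flagged rather than fitted.
#'
#' @param pair A `laplace_pair`.
#' @param quantiles Candidate threshold quantiles.
#' @param n_boot Bootstrap replicates per candidate (default 25).
#' @param level Band level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @inheritParams fit_conditional
#' @return A tibble of class `ht_stability` with one row per candidate:
#'   `q_dep`, `n_exc`, `fitted`, `a`, `b`, and band columns `a_lo`, `a_hi`,
#'   `b_lo`, `b_hi`.
#' @export
threshold_stability <- function(pair, quantiles = seq(0.5, 0.9, by = 0.05),
                                n_boot = 25, level = 0.95, seed = 1,
                                min_exceedances = 10) {
  check_prob(quantiles, "quantiles")
  n <- nrow(pair)
  rows <- purrr::imap(quantiles, function(q, i) {
    n_exc <- sum(pair$conditioning > quantile7(pair$conditioning, q))
    base <- tibble::tibble(
      q_dep = q, n_exc = n_exc, fitted = FALSE,
      a = NA_real_, b = NA_real_,
      a_lo = NA_real_, a_hi = NA_real_, b_lo = NA_real_, b_hi = NA_real_
    )
    if (n_exc < min_exceedances) return(base)
    fit <- tryCatch(
      fit_conditional(pair, q_dep = q, min_exceedances = min_exceedances),
      error = function(e) NULL
    )
    if (is.null(fit)) return(base)
    set.seed(derive_seed(seed, i))
    ab <- purrr::map(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- tryCatch(
        fit_conditional(pair[idx, , drop = FALSE], q_dep = q,
                        min_exceedances = min_exceedances, n_starts = 2),
        error = function(e) NULL
      )
      if (is.null(bf)) c(NA_real_, NA_real_) else c(bf$a, bf$b)
    })
    am <- vapply(ab, `[`, numeric(1), 1)
    bm <- vapply(ab, `[`, numeric(1), 2)
    alpha <- 1 - level
    base$fitted <- TRUE
    base$a <- fit$a
    base$b <- fit$b
    if (any(is.finite(am))) {
      base$a_lo <- quantile7(am[is.finite(am)], alpha / 2)
      base$a_hi <- quantile7(am[is.finite(am)], 1 - alpha / 2)
      base$b_lo <- quantile7(bm[is.finite(bm)], alpha / 2)
      base$b_hi <- quantile7(bm[is.finite(bm)], 1 - alpha / 2)
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ht_stability", class(out))
  out
}

#' Residual-independence diagnostic
#'
#' The conditional model assumes the standardized residual `Z` is
#' independent of the conditioning exceedance.  This diagnostic is the
#' machine-readable analogue of plotting `Z` against `Y`: a rank
#' (Spearman) correlation with its two-sided p-value, plus binned residual
#' location and spread summaries.
#'
#' @param fit An `ht_fit` with at least 10 residuals.
#' @param n_bins Number of conditioning bins for the summaries (default 5).
#' @return A list of class `ht_resid_diag`: `applicable`, `rho`, `p_value`,
#'   `n`, and a tibble `bins` with per-bin residual mean and SD.
#' @export
residual_independence_diag <- function(fit, n_bins = 5) {
  stopifnot(inherits(fit, "ht_fit"))
  if (fit$n_exc < 10) {
    abort("at least 10 residuals are required for the independence diagnostic")
  }
  z <- fit$residuals
  if (sd(z) < 1e-8) {
    return(structure(
      list(applicable = FALSE, rho = NA_real_, p_value = NA_real_,
           n = fit$n_exc, bins = tibble::tibble()),
      class = "ht_resid_diag"
    ))
  }
  ct <- suppressWarnings(
    stats::cor.test(fit$y, z, method = "spearman", exact = FALSE)
  )
  brk <- quantile7(fit$y, seq(0, 1, length.out = n_bins + 1))
  brk[1] <- brk[1] - 1e-9
  bins <- tibble::tibble(
    bin = cut(fit$y, breaks = brk, labels = FALSE),
    y = fit$y, z = z
  ) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      y_mid = mean(.data$y), n = dplyr::n(),
      z_mean = mean(.data$z), z_sd = sd(.data$z), .groups = "drop"
    )
  structure(
    list(applicable = TRUE, rho = unname(ct$estimate),
         p_value = ct$p.value, n = fit$n_exc, bins = bins),
    class = "ht_resid_diag"
  )
}

#' @export
print.ht_resid_diag <- function(x, ...) {
  if (!x$applicable) {
    cat("Residual-independence diagnostic: not applicable (degenerate residuals)\n")
  } else {
    cat(sprintf(
      "Residual-independence diagnostic: Spearman rho = %.3f (p = %.3g, n = %d)\n",
      x$rho, x$p_value, x$n
    ))
  }
  invisible(x)
}
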