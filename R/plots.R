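#' Plot a mean residual life curve
#'
#' @param object An `mrl_curve` from [mean_residual_life()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mrl_curve
#' @export
autoplot.mrl_curve <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$defined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$mean_excess)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "threshold", y = "mean excess",
                  title = "Mean residual life") +
    ggplot2::theme_minimal()
}

#' Plot a profile likelihood surface
#'
#' Shows the profiled negative log-likelihood over the dependence
#' parameters, the feasible region of the joint constraints, and the
#' fitted point.
#'
#' @param object An `ht_profile` from [profile_surface()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ht_profile
#' @export
autoplot.ht_profile <- function(object, ...) {
  fit <- attr(object, "fit", exact = TRUE)
  df <- tibble::as_tibble(object)
  df$nll_capped <- pmin(df$nll, quantile7(df$nll[df$feasible], 0.95))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$nll_capped)) +
    ggplot2::geom_point(data = df[!df$feasible, ], shape = 4, size = 0.4,
                        alpha = 0.3, colour = "grey40") +
    ggplot2::annotate("point", x = fit$a, y = fit$b, colour = "red") +
    ggplot2::scale_fill_viridis_c(name = "profile NLL", direction = -1) +
    ggplot2::labs(title = "Profile likelihood surface",
                  subtitle = "red: fitted optimum; crosses: infeasible") +
    ggplot2::theme_minimal()
}

#' Plot threshold stability of the dependence parameters
#'
#' @param object An `ht_stability` from [threshold_stability()].
#' @param ... Unused.
#' @return A ggplot with one panel per parameter.
#' @method autoplot ht_stability
#' @export
autoplot.ht_stability <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$fitted)
  long <- dplyr::bind_rows(
    dplyr::transmute(df, .data$q_dep, param = "a", est = .data$a,
                     lo = .data$a_lo, hi = .data$a_hi),
    dplyr::transmute(df, .data$q_dep, param = "b", est = .data$b,
                     lo = .data$b_lo, hi = .data$b_hi)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$q_dep, y = .data$est)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "dependence threshold quantile", y = "estimate",
                  title = "Threshold stability") +
    ggplot2::theme_minimal()
}

#' Plot a conditional loss-probability curve
#'
#' Point estimates (and bootstrap intervals, when present) of the
#' conditional loss probability across the conditioning-quantile grid.
#'
#' @param object A `cond_prob_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cond_prob_curve
#' @export
autoplot.cond_prob_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q_c, y = .data$point))
  if ("ci_low" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), alpha = 0.2
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "conditioning quantile",
                  y = "P(severe loss | hazard beyond quantile)",
                  title = "Conditional loss probability") +
    ggplot2::theme_minimal()
}

#' Plot the residual-independence diagnostic of a dependence fit
#'
#' Standardized residuals against the conditioning exceedances; under a
#' valid fit the cloud shows no location or spread trend.
#'
#' @param object An `ht_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ht_fit
#' @export
autoplot.ht_fit <- function(object, ...) {
  df <- tibble::tibble(y = object$y, z = object$residuals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "conditioning exceedance (Laplace scale)",
                  y = "standardized residual Z",
                  title = "Residual independence diagnostic") +
    ggplot2::theme_minimal()
}
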