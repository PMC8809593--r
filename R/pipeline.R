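## The four hazard orientations analysed by default: high precipitation,
## low precipitation (drought), high minimum and high maximum temperature.
default_variables <- function() {
  tibble::tibble(
    weather_variable = c("prec", "prec", "tmin", "tmax"),
    low_tail = c(FALSE, TRUE, FALSE, FALSE)
  )
}

#' Configure an end-to-end fragility analysis
#'
#' Bundles and validates every setting of the pipeline.  The defaults are
#' the reference analysis settings: marginal GPD thresholds at the 80th
#' percentile, dependence threshold at the 90th, extrapolation over the
#' 91st to 99.99th conditioning quantiles, severe loss defined as the
#' response's 90th percentile, 1000 simulated observations per level, and
#' 95% intervals from 100 bootstrap samples.
#'
#' @param panel Panel tibble (see [read_panel()]) or a path to its CSV.
#' @param map Country-to-region map tibble or path (default the packaged
#'   map).
#' @param crops Crops to analyse (default: all crops present in the panel).
#' @param regions Regions to analyse (default: all regions of the map
#'   present in the panel).
#' @param variables Tibble with columns `weather_variable` and `low_tail`
#'   listing the hazard orientations (default: high prec, low prec, high
#'   tmin, high tmax).
#' @param threshold_quantile Marginal GPD threshold quantile (default 0.80).
#' @param q_dep Dependence threshold quantile (default 0.90).
#' @param grid Conditioning-quantile grid (default 0.91 ... 0.9999).
#' @param q_r Response quantile defining a severe loss (default 0.90).
#' @param n_sim Simulated observations per grid level (default 1000).
#' @param n_boot Bootstrap samples (default 100).
#' @param level Confidence level (default 0.95).
#' @param seed Master seed (default 1).
#' @param min_exceedances Minimum exceedances for any fit (default 10).
#' @param min_years Minimum complete years per country (default 0).
#' @param out_dir Optional output directory for serialized results.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(panel, map = NULL, crops = NULL, regions = NULL,
                       variables = default_variables(),
                       threshold_quantile = 0.8, q_dep = 0.9,
                       grid = default_grid(), q_r = 0.9, n_sim = 1000,
                       n_boot = 100, level = 0.95, seed = 1,
                       min_exceedances = 10, min_years = 0,
                       out_dir = NULL) {
  if (is.character(panel)) panel <- read_panel(panel)
  if (is.null(map)) {
    map <- region_map()
  } else if (is.character(map)) {
    map <- region_map(map)
  }
  check_prob(c(threshold_quantile, q_dep, grid, q_r, level), "quantile levels")
  if (any(grid < q_dep)) {
    abort("all extrapolation grid levels must be at or above q_dep")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing")
  }
  stopifnot(n_sim >= 1, n_boot >= 2,
            all(c("weather_variable", "low_tail") %in% names(variables)))
  crops <- crops %||% sort(unique(panel$crop))
  regions <- regions %||%
    sort(unique(map$region[map$country %in% panel$country]))
  structure(
    list(panel = panel, map = map, crops = crops, regions = regions,
         variables = variables, threshold_quantile = threshold_quantile,
         q_dep = q_dep, grid = grid, q_r = q_r, n_sim = n_sim,
         n_boot = n_boot, level = level, seed = seed,
         min_exceedances = min_exceedances, min_years = min_years,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full fragility analysis
#'
#' Executes preprocessing, marginal fitting, dependence fitting,
#' Monte-Carlo extrapolation with bootstrap intervals, and the fragility
#' summaries for every (region, crop, hazard orientation) combination of
#' the configuration.  Each combination gets a deterministically derived
#' seed, so the whole run is reproducible from the master seed; failures
#' are recorded in the manifest and do not stop other combinations.
#'
#' @param config A [run_config()].
#' @return A list of class `fragility_run`: `curves` (all probability
#'   curves, row-bound), `fragility` (the cell table at the 98th hazard
#'   percentile), `worst_case` (per-region index), `manifest` (one row per
#'   attempted combination with status), and the `config`.  When
#'   `config$out_dir` is set, `curves.csv`, `fragility.csv`,
#'   `worst_case.csv` and `manifest.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  combos <- tidyr::expand_grid(
    region = config$regions, crop = config$crops,
    config$variables
  )
  results <- purrr::pmap(
    list(combos$region, combos$crop, combos$weather_variable,
         combos$low_tail, seq_len(nrow(combos))),
    function(region, crop, wv, low, k) {
      seed_k <- derive_seed(config$seed, k)
      res <- tryCatch({
        panel <- build_region_panel(config$panel, region, crop,
                                    map = config$map,
                                    min_years = config$min_years)
        pair <- assemble_pair(panel, wv, low_tail = low)
        curve <- bootstrap_cis(
          pair, threshold_quantile = config$threshold_quantile,
          q_dep = config$q_dep, grid = config$grid, q_r = config$q_r,
          n_sim = config$n_sim, n_boot = config$n_boot,
          level = config$level, seed = seed_k,
          min_exceedances = config$min_exceedances
        )
        list(curve = curve, status = "ok", message = "",
             n_rows = nrow(pair), n_failed = attr(curve, "n_failed"),
             n_clamped = attr(curve, "n_clamped"))
      }, error = function(e) {
        list(curve = NULL, status = "error", message = conditionMessage(e),
             n_rows = NA_integer_, n_failed = NA_integer_,
             n_clamped = NA_integer_)
      })
      manifest_row <- tibble::tibble(
        region = region, crop = crop, variable = wv,
        orientation = if (low) "low" else "high",
        status = res$status, message = res$message,
        n_rows = res$n_rows, n_failed_boot = res$n_failed,
        n_clamp_warnings = res$n_clamped, seed = seed_k
      )
      list(curve = res$curve, manifest = manifest_row)
    }
  )
  manifest <- dplyr::bind_rows(purrr::map(results, "manifest"))
  ## plain tibbles: model objects and bootstrap matrices stay with the
  ## individual curve results, not the pooled table
  as_plain <- function(x) {
    tibble::new_tibble(as.list(x)[names(x)], nrow = nrow(x))
  }
  curves <- purrr::compact(purrr::map(results, "curve"))
  curves <- if (length(curves) > 0) {
    dplyr::bind_rows(purrr::map(curves, as_plain))
  } else {
    tibble::tibble()
  }
  frag <- if (nrow(curves) > 0) fragility_table(curves) else tibble::tibble()
  wc <- if (nrow(frag) > 0) worst_case(frag) else tibble::tibble()
  out <- structure(
    list(curves = curves, fragility = frag, worst_case = wc,
         manifest = manifest, config = config),
    class = "fragility_run"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(curves, file.path(config$out_dir, "curves.csv"))
    readr::write_csv(frag, file.path(config$out_dir, "fragility.csv"))
    readr::write_csv(wc, file.path(config$out_dir, "worst_case.csv"))
    jsonlite::write_json(
      list(
        manifest = manifest,
        settings = config[c("crops", "regions", "threshold_quantile",
                            "q_dep", "grid", "q_r", "n_sim", "n_boot",
                            "level", "seed", "min_exceedances", "min_years")]
      ),
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  out
}

#' @export
print.fragility_run <- function(x, ...) {
  ok <- sum(x$manifest$status == "ok")
  cat(sprintf(
    "Fragility run: %d/%d combinations fitted, %d curve points, %d regions summarised\n",
    ok, nrow(x$manifest), nrow(x$curves), nrow(x$worst_case)
  ))
  invisible(x)
}

#' Fast self-checks of an installation
#'
#' Runs a reduced battery of statistical checks against known truths: GPD
#' parameter recovery, the Laplace probability-integral transform,
#' conditional-probability recovery under independence, and Gaussian-copula
#' dependence-parameter recovery.  Intended as a smoke test that the
#' numerical machinery of an installation behaves.
#'
#' @param seed Seed (default 1).
#' @param n Sample size for the recovery checks (default 20000).
#' @return A tibble of class `validation_report` with columns `check`,
#'   `value`, `target`, `tolerance`, `pass`; serialise with
#'   `jsonlite::toJSON()` if a machine-readable report is needed.
#' @export
validate_install <- function(seed = 1, n = 20000) {
  checks <- list()
  ## GPD recovery
  set.seed(derive_seed(seed, 1))
  g <- fit_gpd(rgpd(5000, scale = 1, shape = 0.2), threshold = 0)
  checks$gpd_scale <- c(g$scale, 1, 3 * g$se_scale)
  checks$gpd_shape <- c(g$shape, 0.2, 3 * g$se_shape)
  ## Laplace PIT
  set.seed(derive_seed(seed, 2))
  x <- rt(2000, df = 5)
  y <- to_laplace(fit_marginal(x), x)
  ks <- max(abs(laplace_cdf(sort(y)) - seq_along(y) / length(y)),
            abs(laplace_cdf(sort(y)) - (seq_along(y) - 1) / length(y)))
  checks$laplace_ks <- c(ks, 0, 1.63 / sqrt(2000))
  ## independence probability
  set.seed(derive_seed(seed, 3))
  sp <- synthetic_spec("independent", n = n, seed = derive_seed(seed, 3))
  cv <- probability_curve(gen_pair(sp), grid = c(0.95, 0.98), n_sim = 5000,
                          seed = derive_seed(seed, 4))
  checks$indep_prob <- c(mean(cv$point), 0.10, 0.05)
  ## gaussian recovery
  sp <- synthetic_spec("gaussian", dep = 0.7, n = n,
                       seed = derive_seed(seed, 5))
  fit <- fit_conditional(transform_pair(gen_pair(sp)))
  checks$gauss_a <- c(fit$a, 0.49, 0.15)
  checks$gauss_b <- c(fit$b, 0.5, 0.3)
  out <- purrr::imap(checks, function(v, nm) {
    tibble::tibble(check = nm, value = v[1], target = v[2], tolerance = v[3],
                   pass = abs(v[1] - v[2]) <= v[3])
  }) |>
    dplyr::bind_rows()
  class(out) <- c("validation_report", class(out))
  out
}
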