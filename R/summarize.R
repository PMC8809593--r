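#' Fragility table at a fixed hazard level
#'
#' Extracts, for every (region, crop, variable, orientation) curve, the
#' conditional loss probability at the `q_c` conditioning quantile
#' (default the 98th percentile of the hazard; for low-precipitation
#' curves, already on the reflected scale, this is the 2nd percentile of
#' precipitation).  Cells whose bootstrap interval includes zero
#' (`ci_low <= 0`) are flagged `shown = FALSE`: they carry no evidence of
#' tail association.
#'
#' @param curves One or more probability curves with bootstrap intervals,
#'   row-bound into a single tibble (columns `region`, `crop`, `variable`,
#'   `orientation`, `q_c`, `point`, `ci_low`, `ci_high`).
#' @param q_c Conditioning quantile at which cells are read (default 0.98).
#' @return A tibble with one row per curve: the labels, `point`, `ci_low`,
#'   `ci_high`, and `shown`.
#' @export
fragility_table <- function(curves, q_c = 0.98) {
  needed <- c("region", "crop", "variable", "orientation",
              "q_c", "point", "ci_low", "ci_high")
  stopifnot(all(needed %in% names(curves)))
  keys <- dplyr::distinct(curves, .data$region, .data$crop,
                          .data$variable, .data$orientation)
  cells <- curves |>
    dplyr::filter(abs(.data$q_c - !!q_c) < 1e-12)
  missing <- dplyr::anti_join(
    keys, cells,
    by = c("region", "crop", "variable", "orientation")
  )
  if (nrow(missing) > 0) {
    bad <- missing |>
      dplyr::mutate(id = paste(.data$region, .data$crop, .data$variable,
                               .data$orientation, sep = "/")) |>
      dplyr::pull("id")
    abort(paste0(
      "curves without the ", format(q_c), " grid level: ",
      paste(bad, collapse = ", ")
    ))
  }
  cells |>
    dplyr::transmute(
      .data$region, .data$crop, .data$variable, .data$orientation,
      .data$point, .data$ci_low, .data$ci_high,
      shown = .data$ci_low > 0
    )
}

#' Worst-case fragility index per region
#'
#' For each region, the maximum upper 95% bootstrap bound of the
#' conditional loss probability across all crop-by-hazard combinations at
#' the fixed hazard level, together with the crop and hazard attaining it.
#' Ties are broken by lexicographic (crop, variable) order.
#'
#' @param cells A fragility table from [fragility_table()], or raw curves
#'   (then [fragility_table()] is applied first with `q_c`).
#' @param q_c Conditioning quantile used when `cells` are raw curves.
#' @return A tibble with one row per region: `region`, `crop`, `variable`,
#'   `orientation`, `point`, `worst_case` (the maximum `ci_high`).
#' @export
worst_case <- function(cells, q_c = 0.98) {
  if (!"shown" %in% names(cells)) {
    cells <- fragility_table(cells, q_c = q_c)
  }
  cells |>
    dplyr::group_by(.data$region) |>
    dplyr::arrange(dplyr::desc(.data$ci_high), .data$crop, .data$variable,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      .data$region, .data$crop, .data$variable, .data$orientation,
      .data$point, worst_case = .data$ci_high
    )
}
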