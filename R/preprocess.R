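PANEL_COLS <- c("country", "year", "crop", "yield", "prec", "tmin", "tmax")
VALUE_COLS <- c("yield", "prec", "tmin", "tmax")

#' Read an annual crop-weather panel
#'
#' Reads a long-format panel of country-year records with one row per
#' (country, year, crop): yield (hg/ha), growing-season precipitation (mm),
#' and mean daily minimum / maximum growing-season temperature (deg C).
#' Empty cells are missing values.
#'
#' @param path Path to a CSV file with header
#'   `country,year,crop,yield,prec,tmin,tmax`.
#' @return A tibble with those columns.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(
    path,
    col_types = readr::cols(
      country = readr::col_character(),
      year = readr::col_integer(),
      crop = readr::col_character(),
      yield = readr::col_double(),
      prec = readr::col_double(),
      tmin = readr::col_double(),
      tmax = readr::col_double()
    )
  )
  missing <- setdiff(PANEL_COLS, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel is missing columns: ", paste(missing, collapse = ", ")))
  }
  panel
}

#' Country-to-region map
#'
#' Returns the mapping from countries to pooled analysis regions.  The
#' packaged default assigns countries in Africa, Asia and Latin America to
#' six regions following the UN Statistics Division geographical
#' composition; a user-supplied CSV with columns `country,region` may be
#' given instead.
#'
#' @param path Optional path to a `country,region` CSV; when `NULL` the
#'   packaged default map is used.
#' @return A tibble with columns `country` and `region`.
#' @examples
#' head(region_map())
#' @export
region_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "region_map.csv", package = "cropfragility")
  }
  readr::read_csv(
    path,
    col_types = readr::cols(
      country = readr::col_character(),
      region = readr::col_character()
    )
  )
}

#' Drop incomplete country-year records
#'
#' Removes records for which any of the four analysis variables (yield,
#' prec, tmin, tmax) is missing.  Per-country drop counts are attached as
#' the `"drop_counts"` attribute (also available through [drop_counts()]);
#' a country that loses all of its records triggers a warning and is absent
#' from the output.
#'
#' @param records Panel tibble with the columns of [read_panel()].
#' @return The complete-case records, with a `drop_counts` attribute.
#' @export
drop_incomplete <- function(records) {
  stopifnot(all(VALUE_COLS %in% names(records)))
  keep <- complete.cases(records[VALUE_COLS])
  counts <- records |>
    dplyr::mutate(.dropped = !keep) |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      n_dropped = sum(.data$.dropped),
      n_retained = sum(!.data$.dropped),
      .groups = "drop"
    )
  gone <- counts$country[counts$n_retained == 0]
  if (length(gone) > 0) {
    warn(paste0(
      "countries with no complete records excluded from pooling: ",
      paste(gone, collapse = ", ")
    ))
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "drop_counts") <- counts
  out
}

#' @rdname drop_incomplete
#' @param x A tibble returned by [drop_incomplete()].
#' @export
drop_counts <- function(x) {
  attr(x, "drop_counts")
}

#' Standardize variables within countries
#'
#' Centres and scales each analysis variable within each country
#' (subtracting the country mean and dividing by the country standard
#' deviation, denominator n-1), so that countries with different levels
#' and variability can be pooled into one region without masking each
#' other's extremes.  The per-country means and SDs are attached as the
#' `"scaling"` attribute for back-transformation.
#'
#' @param records Complete-case panel records.
#' @param vars Variables to standardize (default the four analysis
#'   variables present in the data).
#' @return Records with standardized values and a `scaling` attribute.
#' @export
standardize_by_group <- function(records, vars = intersect(VALUE_COLS, names(records))) {
  stopifnot("country" %in% names(records), length(vars) > 0)
  if (anyNA(records[vars])) {
    abort("records must be complete cases; run drop_incomplete() first")
  }
  small <- records |>
    dplyr::count(.data$country) |>
    dplyr::filter(.data$n < 2)
  if (nrow(small) > 0) {
    abort(paste0(
      "countries with fewer than 2 records cannot be standardized: ",
      paste(small$country, collapse = ", ")
    ))
  }
  scaling <- records |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(vars),
                    list(mean = mean, sd = sd),
                    .names = "{.col}.{.fn}"),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"country",
                        names_to = c("variable", ".value"),
                        names_sep = "\\.")
  zero <- scaling[scaling$sd == 0, ]
  if (nrow(zero) > 0) {
    abort(paste0(
      "zero variance: standardization undefined for ",
      paste(sprintf("%s/%s", zero$country, zero$variable), collapse = ", ")
    ))
  }
  out <- records |>
    dplyr::group_by(.data$country) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vars),
                                ~ (.x - mean(.x)) / sd(.x))) |>
    dplyr::ungroup()
  attr(out, "scaling") <- scaling
  out
}

#' Reflect a variable
#'
#' Negates a series so that its lower tail becomes an upper tail.  The
#' upper-tail machinery then addresses droughts (low precipitation) and
#' yield losses (low yield) directly; applying the reflection twice returns
#' the input exactly.
#'
#' @param x Numeric vector.
#' @return `-x`.
#' @examples
#' reflect_variable(c(-1.2, 0, 2.5))
#' @export
reflect_variable <- function(x) {
  stopifnot(is.numeric(x))
  -x
}

#' Build a pooled, standardized region panel
#'
#' Restricts the panel to one crop, keeps the countries mapped to `region`,
#' applies the complete-case rule, drops countries with fewer than
#' `min_years` retained years (and always those with fewer than 2, which
#' cannot be standardized), standardizes each variable within each country,
#' and pools the result.
#'
#' @param records Raw panel records (see [read_panel()]).
#' @param region Region name to pool.
#' @param crop Crop name.
#' @param map Country-to-region map (default [region_map()]).
#' @param min_years Minimum retained years per country (default 0; values
#'   below 2 are raised to 2).
#' @return A tibble of class `region_panel` with columns `country`, `year`,
#'   and standardized `yield`, `prec`, `tmin`, `tmax`; region/crop labels
#'   and provenance (drop counts, scaling parameters) as attributes.
#' @export
build_region_panel <- function(records, region, crop, map = region_map(),
                               min_years = 0) {
  stopifnot(is.character(region), is.character(crop))
  countries <- map$country[map$region == region]
  if (length(countries) == 0) {
    abort(sprintf("no countries mapped to region '%s'", region))
  }
  sub <- records |>
    dplyr::filter(.data$crop == !!crop, .data$country %in% countries)
  if (nrow(sub) == 0) {
    abort(sprintf("no records for crop '%s' in region '%s'", crop, region))
  }
  cc <- drop_incomplete(sub)
  counts <- drop_counts(cc)
  keep_min <- max(2, min_years)
  cc <- cc |>
    dplyr::group_by(.data$country) |>
    dplyr::filter(dplyr::n() >= keep_min) |>
    dplyr::ungroup()
  if (nrow(cc) == 0) {
    abort(sprintf(
      "no country in region '%s' retains %d complete years for crop '%s'",
      region, keep_min, crop
    ))
  }
  std <- standardize_by_group(cc)
  out <- std |> dplyr::select(dplyr::all_of(c("country", "year", VALUE_COLS)))
  attr(out, "region") <- region
  attr(out, "crop") <- crop
  attr(out, "drop_counts") <- counts
  attr(out, "scaling") <- attr(std, "scaling")
  class(out) <- c("region_panel", class(out))
  out
}

#' Assemble a response/conditioning variable pair
#'
#' Builds the bivariate vector analysed by the dependence model: the
#' response is always the reflected yield (so that yield *losses* are the
#' upper tail) and the conditioning variable is one weather variable,
#' reflected when the interest is in its lower tail (low precipitation,
#' i.e. drought).
#'
#' @param panel A `region_panel` (or any tibble with standardized `yield`
#'   and weather columns).
#' @param weather_variable One of `"prec"`, `"tmin"`, `"tmax"`.
#' @param low_tail Condition on the lower tail of the weather variable?
#'   (Reflects it; meaningful chiefly for precipitation.)
#' @return A tibble of class `variable_pair` with columns `country`, `year`
#'   (when present), `response` and `conditioning`; the orientation record
#'   and region/crop labels are attributes.
#' @export
assemble_pair <- function(panel, weather_variable = c("prec", "tmin", "tmax"),
                          low_tail = FALSE) {
  weather_variable <- rlang::arg_match(weather_variable)
  stopifnot("yield" %in% names(panel), weather_variable %in% names(panel))
  cond <- panel[[weather_variable]]
  if (low_tail) cond <- reflect_variable(cond)
  keep <- intersect(c("country", "year"), names(panel))
  out <- dplyr::bind_cols(
    panel[keep],
    tibble::tibble(response = reflect_variable(panel$yield), conditioning = cond)
  )
  attr(out, "orientation") <- list(
    response = "yield_refl",
    conditioning = paste0(weather_variable, if (low_tail) "_refl" else ""),
    response_reflected = TRUE,
    conditioning_reflected = low_tail
  )
  attr(out, "region") <- attr(panel, "region", exact = TRUE)
  attr(out, "crop") <- attr(panel, "crop", exact = TRUE)
  class(out) <- c("variable_pair", class(out))
  out
}

## Carry pair labels through downstream results.
pair_labels <- function(pair) {
  orient <- attr(pair, "orientation", exact = TRUE)
  list(
    region = attr(pair, "region", exact = TRUE) %||% NA_character_,
    crop = attr(pair, "crop", exact = TRUE) %||% NA_character_,
    variable = orient$conditioning %||% NA_character_,
    orientation = if (isTRUE(orient$conditioning_reflected)) "low" else "high"
  )
}
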