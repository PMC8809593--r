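make_records <- function(n_per_country = 42, countries = c("Alpha", "Beta"),
                         seed = 1) {
  set.seed(seed)
  n <- n_per_country * length(countries)
  tibble::tibble(
    country = rep(countries, each = n_per_country),
    year = rep(seq(1961, length.out = n_per_country), length(countries)),
    crop = "maize",
    yield = runif(n, 5000, 20000),
    prec = runif(n, 200, 900),
    tmin = runif(n, 10, 18),
    tmax = runif(n, 22, 32)
  )
}

test_that("incomplete country-year records are dropped with per-country accounting", {
  rec <- make_records(42, "Alpha")
  rec$prec[c(3, 17, 40)] <- NA
  out <- drop_incomplete(rec)
  expect_equal(nrow(out), 39)
  expect_false(anyNA(out[c("yield", "prec", "tmin", "tmax")]))
  counts <- drop_counts(out)
  expect_equal(counts$n_dropped[counts$country == "Alpha"], 3L)

  # a fully complete record passes through unchanged
  one <- make_records(1, "Gamma")
  expect_equal(drop_incomplete(one)$yield, one$yield)

  # a country missing one variable everywhere disappears, with a warning
  rec2 <- make_records(10, c("Alpha", "Beta"))
  rec2$tmax[rec2$country == "Beta"] <- NA
  expect_warning(out2 <- drop_incomplete(rec2), "Beta")
  expect_false("Beta" %in% out2$country)
})

test_that("within-country standardization gives exact zero mean and unit SD", {
  rec <- tibble::tibble(
    country = "Alpha", year = 1:3, crop = "maize",
    yield = c(1, 2, 3), prec = c(10, 20, 30),
    tmin = c(1, 2, 3), tmax = c(2, 3, 4)
  )
  std <- standardize_by_group(rec)
  expect_equal(std$yield, c(-1, 0, 1))
  scaling <- attr(std, "scaling")
  expect_equal(scaling$mean[scaling$variable == "yield"], 2)
  expect_equal(scaling$sd[scaling$variable == "yield"], 1)

  # constant series cannot be standardized
  rec$prec <- 5
  expect_error(standardize_by_group(rec), "zero variance")

  # generated fixture: every country ends up with moments (0, 1)
  fx <- gen_region_fixture(
    synthetic_spec("gaussian", dep = 0.5, n_countries = 8, n_years = 30,
                   missing_rate = 0.05, seed = 4)
  )
  std2 <- standardize_by_group(drop_incomplete(fx))
  moments <- std2 |>
    dplyr::group_by(country) |>
    dplyr::summarise(dplyr::across(c(yield, prec, tmin, tmax),
                                   list(m = mean, s = sd)))
  for (v in c("yield", "prec", "tmin", "tmax")) {
    expect_lt(max(abs(moments[[paste0(v, "_m")]])), 1e-10)
    expect_lt(max(abs(moments[[paste0(v, "_s")]] - 1)), 1e-10)
  }

  # idempotence up to tolerance
  std3 <- standardize_by_group(std2)
  expect_lt(max(abs(std3$yield - std2$yield)), 1e-10)
})

test_that("reflection negates, is an involution, and swaps tail quantiles exactly", {
  expect_equal(reflect_variable(c(-1.2, 0, 2.5)), c(1.2, 0, -2.5))
  x <- rnorm(100)
  expect_identical(reflect_variable(reflect_variable(x)), x)
  set.seed(2)
  prec <- rexp(500, 1 / 300)
  expect_equal(
    unname(quantile(prec, 0.02, type = 7)),
    -unname(quantile(reflect_variable(prec), 0.98, type = 7))
  )
  # upper-tail exceedance counts map to lower-tail counts
  q <- unname(quantile(prec, 0.05, type = 7))
  expect_equal(sum(prec < q), sum(-prec > -q))
})

test_that("region pooling preserves rows and pairs are aligned and oriented", {
  fx <- gen_region_fixture(
    synthetic_spec("gaussian", dep = 0.5, n_countries = 6, n_years = 30,
                   missing_rate = 0.08, seed = 9)
  )
  map <- tibble::tibble(country = unique(fx$country), region = "TestRegion")
  panel <- build_region_panel(fx, "TestRegion", "maize", map = map)
  retained <- drop_incomplete(fx) |> dplyr::count(country)
  expect_equal(nrow(panel), sum(retained$n))
  expect_identical(attr(panel, "region"), "TestRegion")

  pair <- assemble_pair(panel, "prec", low_tail = FALSE)
  expect_equal(nrow(pair), nrow(panel))
  expect_equal(pair$response, -panel$yield)
  expect_equal(pair$conditioning, panel$prec)
  orient <- attr(pair, "orientation")
  expect_identical(orient$conditioning, "prec")
  expect_true(orient$response_reflected)

  pair_lo <- assemble_pair(panel, "prec", low_tail = TRUE)
  expect_equal(pair_lo$conditioning, -panel$prec)
  expect_identical(attr(pair_lo, "orientation")$conditioning, "prec_refl")

  expect_error(assemble_pair(panel, "snow"))
})

test_that("min_years filter drops short series from the pool", {
  fx <- gen_region_fixture(
    synthetic_spec("gaussian", dep = 0.5, n_countries = 5, n_years = 20,
                   missing_rate = 0, seed = 3)
  )
  short <- fx |> dplyr::filter(country == "C01") |> dplyr::slice(1:4)
  fx2 <- dplyr::bind_rows(fx |> dplyr::filter(country != "C01"), short)
  map <- tibble::tibble(country = unique(fx2$country), region = "R")
  panel <- build_region_panel(fx2, "R", "maize", map = map, min_years = 10)
  expect_false("C01" %in% panel$country)
})
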