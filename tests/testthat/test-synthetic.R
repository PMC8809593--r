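test_that("generator families have the advertised dependence structure", {
  # independence: vanishing rank correlation
  ind <- gen_pair(synthetic_spec("independent", n = 10000, seed = 61))
  expect_lt(abs(cor(ind$response, ind$conditioning, method = "spearman")),
            3 / sqrt(10000))

  # perfect dependence: identical columns
  per <- gen_pair(synthetic_spec("perfect", n = 500, seed = 62))
  expect_identical(per$response, per$conditioning)

  # logistic family: empirical chi at the 99th percentile matches 2 - 2^alpha
  for (alpha in c(0.3, 0.6)) {
    pair <- gen_pair(synthetic_spec("logistic", dep = alpha, n = 200000,
                                    margins = "t", seed = 63))
    qr <- quantile(pair$response, 0.99, type = 7)
    qc <- quantile(pair$conditioning, 0.99, type = 7)
    sel <- pair$conditioning > qc
    chi_hat <- mean(pair$response[sel] > qr)
    chi <- 2 - 2^alpha
    se <- sqrt(chi * (1 - chi) / sum(sel))
    expect_lt(abs(chi_hat - chi), 3 * se)
  }
})

test_that("generated margins follow the specified marginal law", {
  pair <- gen_pair(synthetic_spec("gaussian", dep = 0.5, n = 5000,
                                  margins = "t", df = 5, seed = 64))
  crit <- 1.63 / sqrt(5000) # 1% KS level
  expect_lt(ks_distance(pair$response, function(q) pt(q, df = 5)), crit)
  expect_lt(ks_distance(pair$conditioning, function(q) pt(q, df = 5)), crit)

  hpair <- gen_pair(synthetic_spec("ht", a = 0.3, b = 0.2, n = 5000, seed = 65))
  expect_lt(ks_distance(hpair$conditioning, ref_laplace_cdf), crit)
})

test_that("theoretical dependence parameters follow the limit theory", {
  expect_equal(theoretical_dependence_params(synthetic_spec("gaussian", dep = 0.7)),
               list(a = 0.49, b = 0.5))
  expect_equal(theoretical_dependence_params(synthetic_spec("gaussian", dep = -0.6)),
               list(a = -0.36, b = 0.5))
  expect_equal(theoretical_dependence_params(synthetic_spec("independent")),
               list(a = 0, b = 0))
  expect_equal(theoretical_dependence_params(synthetic_spec("perfect")),
               list(a = 1, b = 0))
  expect_equal(theoretical_dependence_params(synthetic_spec("logistic", dep = 0.4)),
               list(a = 1, b = 0))
  expect_equal(theoretical_dependence_params(synthetic_spec("logistic", dep = 1)),
               list(a = 0, b = 0))
  expect_equal(
    theoretical_dependence_params(synthetic_spec("gaussian", dep = 0.7,
                                                 negate = TRUE)),
    list(a = -0.49, b = 0.5)
  )
  expect_equal(
    theoretical_dependence_params(synthetic_spec("ht", a = 0.3, b = -0.2)),
    list(a = 0.3, b = -0.2)
  )
})

test_that("invalid generator parameters are refused", {
  expect_error(synthetic_spec("gaussian", dep = 1.2), "correlation")
  expect_error(synthetic_spec("logistic", dep = 0), "alpha")
  expect_error(synthetic_spec("ht", a = 2, b = 0), "ht family")
})

test_that("region fixtures honour the panel layout, dependence and determinism", {
  spec <- synthetic_spec("gaussian", dep = 0.6, n_countries = 16, n_years = 42,
                         missing_rate = 0.05, seed = 66)
  fx <- gen_region_fixture(spec)
  expect_equal(nrow(fx), 16 * 42)
  expect_setequal(names(fx), c("country", "year", "crop", "yield", "prec",
                               "tmin", "tmax"))
  # roughly the expected number of complete records at a 5% missing rate
  n_complete <- sum(stats::complete.cases(fx[c("yield", "prec", "tmin", "tmax")]))
  expect_gt(n_complete, 16 * 42 * 0.90)
  expect_lt(n_complete, 16 * 42 * 0.99)
  # physical invariants where present
  both <- !is.na(fx$tmin) & !is.na(fx$tmax)
  expect_true(all(fx$tmax[both] >= fx$tmin[both]))
  expect_true(all(fx$yield >= 0, na.rm = TRUE))
  expect_true(all(fx$prec >= 0, na.rm = TRUE))

  # byte-identical regeneration from the same spec
  fx2 <- gen_region_fixture(spec)
  expect_identical(readr::format_csv(fx), readr::format_csv(fx2))
})

test_that("the Monte-Carlo oracle matches analytic values and is self-consistent", {
  expect_lt(
    abs(oracle_cond_prob(synthetic_spec("independent"), q_c = 0.98,
                         n_mc = 2e5, seed = 67)$probability - 0.10),
    3 * sqrt(0.09 / 2e5)
  )
  perf <- oracle_cond_prob(synthetic_spec("perfect"), q_c = 0.99, q_r = 0.9)
  expect_equal(perf$probability, 1)
  expect_equal(perf$se, 0)
  # negative perfect dependence never produces a joint upper-tail event
  perf_neg <- oracle_cond_prob(synthetic_spec("perfect", negate = TRUE),
                               q_c = 0.98, q_r = 0.9)
  expect_equal(perf_neg$probability, 0)

  sp <- synthetic_spec("gaussian", dep = 0.7)
  o1 <- oracle_cond_prob(sp, q_c = 0.98, n_mc = 3e5, seed = 68)
  o2 <- oracle_cond_prob(sp, q_c = 0.98, n_mc = 3e5, seed = 69)
  expect_lt(abs(o1$probability - o2$probability),
            3 * sqrt(o1$se^2 + o2$se^2))

  # logistic oracle: strong asymptotic dependence keeps the conditional
  # probability far above the independence value
  ol <- oracle_cond_prob(synthetic_spec("logistic", dep = 0.3), q_c = 0.98,
                         n_mc = 5e5, seed = 70)
  expect_gt(ol$probability, 0.5)
})

test_that("refitting data simulated from the exact model form recovers (a, b)", {
  truth_a <- 0.5
  truth_b <- 0.3
  covered <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    pair <- gen_pair(synthetic_spec("ht", a = truth_a, b = truth_b, n = 1500,
                                    seed = 7000 + r))
    fit <- fit_conditional(pair, n_starts = 2)
    ## bootstrap band for (a, b): the range of 50 resampled estimates,
    ## whose nominal per-parameter coverage is 1 - 2/51
    set.seed(8000 + r)
    ab <- vapply(1:50, function(k) {
      idx <- sample.int(nrow(pair), nrow(pair), replace = TRUE)
      bf <- tryCatch(
        fit_conditional(pair[idx, ], n_starts = 2),
        error = function(e) NULL
      )
      if (is.null(bf)) c(NA_real_, NA_real_) else c(bf$a, bf$b)
    }, numeric(2))
    a_ok <- truth_a >= min(ab[1, ], na.rm = TRUE) &&
      truth_a <= max(ab[1, ], na.rm = TRUE)
    b_ok <- truth_b >= min(ab[2, ], na.rm = TRUE) &&
      truth_b <= max(ab[2, ], na.rm = TRUE)
    if (a_ok && b_ok) covered <- covered + 1L
  }
  expect_gte(covered, 90)
})
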