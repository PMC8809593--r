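test_that("conditional simulation follows the Laplace exceedance law", {
  set.seed(41)
  fit <- stub_ht_fit(a = 0.4, b = 0.3, residuals = rnorm(2000))
  ps <- simulate_conditional(fit, q_c = 0.98, n_sim = 100000, seed = 42)
  v <- laplace_quantile(0.98)
  expect_true(all(ps$y_cond > v))
  expect_equal(nrow(ps), 100000)
  # exceedances over the level are unit exponential
  expect_lt(abs(mean(ps$y_cond - v) - 1), 3 / sqrt(100000))
  # extrapolating below the fitted threshold is refused
  expect_error(simulate_conditional(fit, q_c = 0.5), "q_dep")
})

test_that("under an independence fit the simulated response margin is standard Laplace", {
  set.seed(43)
  fit <- stub_ht_fit(a = 0, b = 0, residuals = laplace_quantile(runif(50000)))
  ps <- simulate_conditional(fit, q_c = 0.95, n_sim = 50000, seed = 44)
  expect_lt(ks_distance(ps$y_resp, ref_laplace_cdf), 0.02)
  # and the conditional probability sits at 1 - q_r
  p <- conditional_probability(ps, q_r = 0.9)
  expect_lt(abs(p$point - 0.10), 3 * sqrt(0.09 / nrow(ps)))
})

test_that("perfect dependence gives probability one above the response level", {
  fit <- stub_ht_fit(a = 1, b = 0, residuals = rep(0, 100))
  ps <- simulate_conditional(fit, q_c = 0.99, n_sim = 5000, seed = 45)
  expect_equal(conditional_probability(ps, q_r = 0.9)$point, 1)
})

test_that("exceedance counting is identical on the Laplace and original scales", {
  spec <- synthetic_spec("gaussian", dep = 0.6, n = 4000, seed = 46)
  pair <- gen_pair(spec)
  lp <- suppressWarnings(transform_pair(pair))
  fit <- fit_conditional(lp)
  marg <- attr(lp, "marginals")
  ps <- simulate_conditional(fit, q_c = 0.98, n_sim = 5000, seed = 47,
                             marginals = marg)
  p_laplace <- mean(ps$y_resp > laplace_quantile(0.9))
  p_original <- mean(ps$x_resp > marginal_quantile(marg$response, 0.9))
  expect_identical(p_laplace, p_original)
})

test_that("probability curves validate their grid and are reproducible", {
  spec <- synthetic_spec("gaussian", dep = 0.6, n = 3000, seed = 48)
  pair <- gen_pair(spec)
  expect_error(
    suppressWarnings(probability_curve(pair, q_dep = 0.9, grid = c(0.85, 0.95))),
    "q_dep"
  )
  expect_error(
    suppressWarnings(probability_curve(pair, grid = c(0.95, 0.93))),
    "increasing"
  )
  c1 <- suppressWarnings(probability_curve(pair, grid = c(0.95, 0.98),
                                           n_sim = 500, seed = 7))
  c2 <- suppressWarnings(probability_curve(pair, grid = c(0.95, 0.98),
                                           n_sim = 500, seed = 7))
  expect_identical(tibble::as_tibble(c1), tibble::as_tibble(c2))
  expect_equal(nrow(c1), 2)
})

test_that("a deterministic increasing response gives probability one along the curve", {
  set.seed(49)
  x <- laplace_quantile(runif(4000))
  pair <- tibble::tibble(response = 2 * x + 1, conditioning = x)
  cv <- suppressWarnings(probability_curve(pair, grid = c(0.95, 0.99),
                                           n_sim = 1000, seed = 8))
  expect_true(all(cv$point == 1))
})

test_that("bootstrap intervals use the stated order statistics and cover the point", {
  spec <- synthetic_spec("gaussian", dep = 0.5, n = 2000, seed = 50)
  pair <- gen_pair(spec)
  grid <- seq(0.91, 0.9955, length.out = 20)
  cv <- suppressWarnings(
    bootstrap_cis(pair, grid = grid, n_sim = 1000, n_boot = 50, seed = 9)
  )
  mat <- attr(cv, "boot_estimates")
  m <- nrow(mat)
  lo_k <- ceiling(0.025 * m)
  hi_k <- ceiling(0.975 * m)
  manual <- apply(mat, 2, function(p) sort(p)[c(lo_k, hi_k)])
  expect_equal(cv$ci_low, manual[1, ])
  expect_equal(cv$ci_high, manual[2, ])
  expect_true(all(cv$ci_low <= cv$ci_high))
  expect_true(all(cv$ci_low >= 0 & cv$ci_high <= 1))
  # the interval contains its point estimate in at least 95% of levels
  inside <- mean(cv$point >= cv$ci_low & cv$point <= cv$ci_high)
  expect_gte(inside, 0.95)
})

test_that("doubling the simulation size shrinks the Monte-Carlo spread", {
  fit <- stub_ht_fit(a = 0.45, b = 0.35,
                     residuals = rnorm(5000, 0.3, 0.9))
  spread <- function(n_sim) {
    ps <- vapply(1:40, function(k) {
      s <- simulate_conditional(fit, q_c = 0.98, n_sim = n_sim, seed = 900 + k)
      conditional_probability(s, q_r = 0.9)$point
    }, numeric(1))
    sd(ps)
  }
  s1 <- spread(500)
  s2 <- spread(2000)
  expect_lt(s2, s1)
})
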