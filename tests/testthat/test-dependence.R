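test_that("stored residuals reconstruct the observed responses exactly", {
  pair <- ref_gauss_laplace_pair(5000, 0.6, seed = 21)
  fit <- fit_conditional(pair)
  rebuilt <- fit$a * fit$y + fit$y^fit$b * fit$residuals
  expect_lt(max(abs(rebuilt - fit$y_resp)), 1e-10)
  expect_equal(fit$n_exc, length(fit$residuals))
})

test_that("perfect dependence drives a to one with degenerate residuals", {
  set.seed(22)
  y <- laplace_quantile(runif(3000))
  pair <- tibble::tibble(response = y, conditioning = y)
  fit <- fit_conditional(pair)
  expect_lt(abs(fit$a - 1), 0.02)
  expect_lt(sd(fit$residuals), 1e-6)
  expect_true(fit$b_unidentified)
})

test_that("independent pairs give a near zero and Laplace-like residuals", {
  set.seed(23)
  pair <- tibble::tibble(
    response = laplace_quantile(runif(50000)),
    conditioning = laplace_quantile(runif(50000))
  )
  fit <- fit_conditional(pair)
  expect_lt(abs(fit$a), 0.1)
  expect_lt(ks_distance(fit$residuals, ref_laplace_cdf), 0.05)
})

test_that("the sign of a tracks the sign of the tail dependence", {
  hits_pos <- 0L
  hits_neg <- 0L
  for (r in 1:100) {
    pair <- ref_gauss_laplace_pair(5000, 0.5, seed = 3000 + r)
    fit <- fit_conditional(pair, n_starts = 2)
    if (fit$a > 0) hits_pos <- hits_pos + 1L
    neg <- pair
    neg$response <- -neg$response
    fitn <- fit_conditional(neg, n_starts = 2)
    if (fitn$a < 0) hits_neg <- hits_neg + 1L
  }
  expect_gte(hits_pos, 95)
  expect_gte(hits_neg, 95)
})

test_that("the constraint predicate enforces the box and matches direct bound evaluation", {
  set.seed(24)
  y <- 1.6 + rexp(200)
  y_resp <- 0.5 * y + sqrt(y) * rnorm(200)
  expect_false(constraints_feasible(1.2, 0.5, y, y_resp))
  expect_false(constraints_feasible(-1.4, 0.5, y, y_resp))
  expect_false(constraints_feasible(0.5, 1.0, y, y_resp))
  # an interior candidate, checked against an independent implementation
  # of the perfect-dependence bound conditions
  expect_identical(
    constraints_feasible(0.9, 0.9, y, y_resp),
    ref_constraint_check(0.9, 0.9, y, y_resp)
  )
})

test_that("the profile surface is consistent with the fitted optimum", {
  pair <- ref_gauss_laplace_pair(8000, 0.7, seed = 25)
  fit <- fit_conditional(pair)
  surf <- profile_surface(pair, fit = fit)
  expect_true(attr(surf, "optimum_consistent"))
  # the fitted value beats 50 random feasible nodes
  feas <- dplyr::filter(tibble::as_tibble(surf), feasible)
  set.seed(26)
  nodes <- feas[sample.int(nrow(feas), min(50, nrow(feas))), ]
  fit_val <- min(surf$nll[surf$feasible])
  expect_true(all(fit_val <= nodes$nll + 1e-9))

  # perfect dependence: the feasible optimum sits on the a = 1 edge
  set.seed(27)
  yy <- laplace_quantile(runif(2000))
  ppair <- tibble::tibble(response = yy, conditioning = yy)
  pfit <- fit_conditional(ppair)
  psurf <- suppressWarnings(
    profile_surface(ppair, fit = pfit, a_grid = seq(-1, 1, length.out = 21),
                    b_grid = seq(-1, 0.9, length.out = 20))
  )
  opt <- attr(psurf, "grid_optimum")
  expect_equal(opt$a, 1)
})

test_that("threshold stability refits across candidate quantiles and flags thin tails", {
  spec <- synthetic_spec("ht", a = 0.5, b = 0.3, n = 2000, seed = 28)
  pair <- gen_pair(spec)
  tr <- threshold_stability(pair, n_boot = 15, seed = 5)
  expect_equal(nrow(tr), 9)
  expect_true(all(tr$fitted))
  # generated from the model form itself: a moves less across the grid
  # than the widest bootstrap band
  expect_lt(diff(range(tr$a)), max(tr$a_hi - tr$a_lo))

  small <- gen_pair(synthetic_spec("ht", a = 0.5, b = 0.3, n = 500, seed = 29))
  tr2 <- threshold_stability(small, quantiles = c(0.5, 0.999), n_boot = 2)
  expect_false(tr2$fitted[tr2$q_dep == 0.999])
})

test_that("residual independence diagnostic separates valid and broken fits", {
  # under the model form the residuals carry no rank correlation with y
  pvals <- vapply(1:40, function(r) {
    pair <- gen_pair(synthetic_spec("ht", a = 0.4, b = 0.2, n = 1500,
                                    seed = 600 + r))
    d <- residual_independence_diag(fit_conditional(pair, n_starts = 2))
    d$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)

  # constructed failure: residuals equal to the conditioning values
  set.seed(30)
  y <- 2 + rexp(200)
  fake <- stub_ht_fit(a = 0, b = 0, residuals = y)
  fake$y <- y
  d <- residual_independence_diag(fake)
  expect_gt(abs(d$rho), 0.99)

  # guard and degenerate cases
  tiny <- stub_ht_fit(a = 0, b = 0, residuals = rnorm(5))
  tiny$y <- rexp(5) + 2
  tiny$n_exc <- 5L
  expect_error(residual_independence_diag(tiny), "10")
  flat <- stub_ht_fit(a = 1, b = 0, residuals = rep(0, 50))
  flat$y <- rexp(50) + 2
  expect_false(residual_independence_diag(flat)$applicable)
})

test_that("the optimum is insensitive to the starting point on well-conditioned data", {
  pair <- ref_gauss_laplace_pair(5000, 0.7, seed = 31)
  set.seed(32)
  vals <- vapply(1:10, function(i) {
    s <- c(runif(1, -0.8, 0.8), runif(1, -0.8, 0.8))
    fit_conditional(pair, starts = list(s))$nll
  }, numeric(1))
  expect_lt(diff(range(vals)), 1e-6)
})

test_that("guards: too few exceedances are refused and low thresholds floor at zero", {
  pair <- ref_gauss_laplace_pair(50, 0.5, seed = 33)
  expect_error(fit_conditional(pair, q_dep = 0.95), "exceedances")
  # below the Laplace median the threshold is floored at zero, keeping the
  # conditioning exceedances positive
  big <- ref_gauss_laplace_pair(2000, 0.5, seed = 34)
  fit <- fit_conditional(big, q_dep = 0.2)
  expect_equal(fit$u_y, 0)
  expect_true(all(fit$y > 0))
})
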