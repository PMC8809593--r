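#' Specify a synthetic bivariate panel generator
#'
#' Describes a generative law with known tail-dependence structure, used to
#' validate every pipeline stage against a known truth.  Families:
#'
#' * `"gaussian"`: Gaussian copula with correlation `dep` - asymptotically
#'   independent, with conditional-extremes parameters
#'   `a = sign(dep) dep^2`, `b = 1/2`;
#' * `"logistic"`: bivariate logistic max-stable (Gumbel) copula with
#'   `dep` = alpha in (0, 1] - asymptotically dependent for alpha < 1
#'   (`a = 1`, `b = 0`), independent at alpha = 1;
#' * `"independent"`: `a = 0`, `b = 0`;
#' * `"perfect"`: comonotone pair, `a = 1`, `b = 0`;
#' * `"ht"`: exact conditional-model form `y_resp = a y + y^b z` with
#'   independent Gaussian residuals, on Laplace margins, holding at every
#'   positive conditioning value.
#'
#' `negate = TRUE` reflects the response margin, turning positive into
#' negative extremal dependence (mirroring the reflection device used for
#' droughts): the theoretical `a` changes sign.
#'
#' @param family Generator family (see above).
#' @param dep Dependence parameter: correlation in (-1, 1) for
#'   `"gaussian"`, alpha in (0, 1] for `"logistic"`.
#' @param a,b Conditional-model parameters for `family = "ht"`
#'   (`-1 <= a <= 1`, `b < 1`).
#' @param margins Marginal family for the pair on the original scale:
#'   `"t"` (Student t, heavy GPD-compatible tails), `"norm"`, or
#'   `"laplace"`.  `"ht"` always generates on Laplace margins.
#' @param df Degrees of freedom of the `"t"` margins (default 5).
#' @param n Number of draws for [gen_pair()].
#' @param n_countries,n_years Panel layout for [gen_region_fixture()].
#' @param missing_rate Fraction of country-year records with one variable
#'   missing (default 0.05).
#' @param negate Reflect the response margin (negative dependence)?
#' @param seed Seed making generation a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @examples
#' synthetic_spec("gaussian", dep = 0.7, n = 5000, seed = 1)
#' @export
synthetic_spec <- function(family = c("gaussian", "logistic", "independent",
                                      "perfect", "ht"),
                           dep = NULL, a = NULL, b = NULL,
                           margins = c("t", "norm", "laplace"), df = 5,
                           n = 1000, n_countries = 12, n_years = 42,
                           missing_rate = 0.05, negate = FALSE, seed = 1) {
  family <- rlang::arg_match(family)
  margins <- rlang::arg_match(margins)
  if (family == "gaussian") {
    if (is.null(dep) || abs(dep) >= 1) {
      abort("gaussian family needs a correlation `dep` in (-1, 1)")
    }
  } else if (family == "logistic") {
    if (is.null(dep) || dep <= 0 || dep > 1) {
      abort("logistic family needs `dep` = alpha in (0, 1]")
    }
  } else if (family == "ht") {
    if (is.null(a) || is.null(b) || a < -1 || a > 1 || b >= 1) {
      abort("ht family needs `a` in [-1, 1] and `b` < 1")
    }
    margins <- "laplace"
  }
  stopifnot(n >= 1, n_countries >= 1, n_years >= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(
    list(family = family, dep = dep, a = a, b = b, margins = margins,
         df = df, n = n, n_countries = n_countries, n_years = n_years,
         missing_rate = missing_rate, negate = isTRUE(negate), seed = seed),
    class = "synthetic_spec"
  )
}

#' Theoretical conditional-extremes parameters of a generator
#'
#' The known limiting normalization `(a, b)` of the conditional extremes
#' model for the spec's family: `(sign(rho) rho^2, 1/2)` for the Gaussian
#' copula, `(1, 0)` for the logistic with alpha < 1 and for perfect
#' dependence, `(0, 0)` for independence (including logistic alpha = 1),
#' and the spec's own `(a, b)` for the exact form.  With `negate = TRUE`
#' the sign of `a` flips.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with elements `a` and `b`, or the string `"unknown"`.
#' @examples
#' theoretical_dependence_params(synthetic_spec("gaussian", dep = 0.7))
#' @export
theoretical_dependence_params <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ab <- switch(spec$family,
    gaussian = list(a = sign(spec$dep) * spec$dep^2, b = 0.5),
    logistic = if (spec$dep < 1) list(a = 1, b = 0) else list(a = 0, b = 0),
    independent = list(a = 0, b = 0),
    perfect = list(a = 1, b = 0),
    ht = list(a = spec$a, b = spec$b),
    "unknown"
  )
  if (is.list(ab) && spec$negate) ab$a <- -ab$a
  ab
}

## Kanter's sampler for the positive alpha-stable law with Laplace
## transform exp(-t^alpha); drives the Gumbel-copula mixture construction.
rstable_pos <- function(n, alpha) {
  theta <- runif(n, 0, pi)
  W <- rexp(n)
  A <- sin(alpha * theta)^(alpha / (1 - alpha)) * sin((1 - alpha) * theta) /
    sin(theta)^(1 / (1 - alpha))
  (A / W)^((1 - alpha) / alpha)
}

## Uniform-margin draws from the bivariate logistic (Gumbel) copula; the
## tail-dependence coefficient is chi = 2 - 2^alpha.
rlogistic_cop <- function(n, alpha) {
  if (alpha == 1) return(cbind(runif(n), runif(n)))
  S <- rstable_pos(n, alpha)
  E <- matrix(rexp(2 * n), n, 2)
  exp(-(E / S)^alpha)
}

## Uniform-margin draws per family (response, conditioning).
copula_draws <- function(spec, n) {
  switch(spec$family,
    gaussian = {
      z2 <- rnorm(n)
      z1 <- spec$dep * z2 + sqrt(1 - spec$dep^2) * rnorm(n)
      cbind(pnorm(z1), pnorm(z2))
    },
    logistic = rlogistic_cop(n, spec$dep),
    independent = cbind(runif(n), runif(n)),
    perfect = {
      u <- runif(n)
      cbind(u, u)
    },
    abort(sprintf("no copula representation for family '%s'", spec$family))
  )
}

marginal_transform <- function(u, spec) {
  switch(spec$margins,
    t = qt(u, df = spec$df),
    norm = qnorm(u),
    laplace = laplace_quantile(pmin(pmax(u, 1e-12), 1 - 1e-12))
  )
}

## Exact conditional-model generator on Laplace margins: the model form
## holds for every positive conditioning value (all levels >= the median).
ht_draws <- function(spec, n) {
  y <- laplace_quantile(runif(n))
  z <- rnorm(n)
  w <- pmax(abs(y), 1e-6)^spec$b
  cbind(spec$a * y + w * z, y)
}

#' Generate a bivariate pair with known dependence
#'
#' Draws `spec$n` observations of (response, conditioning) with the spec's
#' copula and margins.  The theoretical conditional-extremes parameters are
#' attached as the `"truth"` attribute.
#'
#' @param spec A `synthetic_spec`.
#' @return A tibble of class `variable_pair` with columns `response` and
#'   `conditioning`; attributes `truth` and `spec`.
#' @examples
#' gen_pair(synthetic_spec("independent", n = 100, seed = 2))
#' @export
gen_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  if (spec$family == "ht") {
    xy <- ht_draws(spec, spec$n)
    resp <- xy[, 1]
    cond <- xy[, 2]
  } else {
    u <- copula_draws(spec, spec$n)
    resp <- marginal_transform(u[, 1], spec)
    cond <- marginal_transform(u[, 2], spec)
  }
  if (spec$negate) resp <- -resp
  out <- tibble::tibble(response = resp, conditioning = cond)
  attr(out, "truth") <- theoretical_dependence_params(spec)
  attr(out, "spec") <- spec
  attr(out, "orientation") <- list(
    response = "response", conditioning = "conditioning",
    response_reflected = spec$negate, conditioning_reflected = FALSE
  )
  class(out) <- c("variable_pair", class(out))
  out
}

#' Generate a synthetic country-year panel fixture
#'
#' Emulates the structure of the study panels: `n_countries` countries with
#' up to `n_years` annual records each, country-specific offsets and scales
#' (so per-country standardization is non-trivial), the spec's bivariate
#' tail dependence between yield losses and one weather hazard, plausible
#' independent filler values for the remaining weather variables, and
#' missingness at the spec rate (one variable blanked per affected
#' record).  Yield and precipitation are kept non-negative and
#' `tmax >= tmin` always holds.
#'
#' The dependence is oriented so that, after the preprocessing pipeline
#' (complete cases, per-country standardization, [assemble_pair()] with
#' `low_tail` as given here), the resulting pair has the spec's theoretical
#' `(a, b)`: large *reflected* yield (a loss) co-occurs with the hazard's
#' modelled tail.
#'
#' @param spec A `synthetic_spec` (its `n` is ignored; the layout fields
#'   are used).
#' @param crop Crop label for the records.
#' @param hazard Which weather variable carries the dependence.
#' @param low_tail Put the dependence in the hazard's lower tail (e.g.
#'   drought)?
#' @param start_year First year of the panel (default 1961).
#' @param country_prefix Prefix of the synthetic country labels (default
#'   `"C"`); use distinct prefixes when binding several regions together.
#' @return A tibble in the panel schema of [read_panel()], with the
#'   ground-truth metadata in the `"truth"` attribute.
#' @export
gen_region_fixture <- function(spec, crop = "maize",
                               hazard = c("prec", "tmin", "tmax"),
                               low_tail = FALSE, start_year = 1961,
                               country_prefix = "C") {
  stopifnot(inherits(spec, "synthetic_spec"))
  hazard <- rlang::arg_match(hazard)
  set.seed(spec$seed)
  nc <- spec$n_countries
  ny <- spec$n_years
  n <- nc * ny
  if (spec$family == "ht") {
    xy <- ht_draws(spec, n)
    resp <- xy[, 1]
    cond <- xy[, 2]
  } else {
    u <- copula_draws(spec, n)
    resp <- marginal_transform(u[, 1], spec)
    cond <- marginal_transform(u[, 2], spec)
  }
  if (spec$negate) resp <- -resp
  ## response is the *reflected* yield; orient the hazard column so the
  ## preprocessing reflections recover (resp, cond)
  yield_std <- -resp
  hazard_std <- if (low_tail) -cond else cond
  country <- rep(sprintf("%s%02d", country_prefix, seq_len(nc)), each = ny)
  year <- rep(seq(start_year, length.out = ny), times = nc)
  ## country-specific levels and scales
  y_mu <- rep(runif(nc, 10000, 40000), each = ny)
  y_sd <- 0.12 * y_mu
  p_mu <- rep(runif(nc, 400, 1200), each = ny)
  p_sd <- 0.2 * p_mu
  t_mu <- rep(runif(nc, 12, 22), each = ny)
  t_sd <- rep(runif(nc, 0.8, 1.6), each = ny)
  gap <- runif(n, 6, 12)
  yield <- pmax(y_mu + y_sd * yield_std, 0)
  filler <- rnorm(n)
  if (hazard == "prec") {
    prec <- pmax(p_mu + p_sd * hazard_std, 0)
    tmin <- t_mu + t_sd * filler
    tmax <- tmin + gap
  } else if (hazard == "tmin") {
    prec <- pmax(p_mu + p_sd * filler, 0)
    tmin <- t_mu + t_sd * hazard_std
    tmax <- tmin + gap
  } else {
    prec <- pmax(p_mu + p_sd * filler, 0)
    tmax <- t_mu + gap + t_sd * hazard_std
    tmin <- tmax - gap
  }
  out <- tibble::tibble(
    country = country, year = as.integer(year), crop = crop,
    yield = yield, prec = prec, tmin = tmin, tmax = tmax
  )
  if (spec$missing_rate > 0) {
    hit <- runif(n) < spec$missing_rate
    which_var <- sample(VALUE_COLS, n, replace = TRUE)
    for (v in VALUE_COLS) {
      out[[v]][hit & which_var == v] <- NA_real_
    }
  }
  attr(out, "truth") <- list(
    params = theoretical_dependence_params(spec), spec = spec,
    hazard = hazard, low_tail = low_tail
  )
  out
}

#' Brute-force Monte-Carlo oracle for the conditional loss probability
#'
#' Estimates `P(response > its q_r quantile | conditioning > its q_c
#' quantile)` directly from the true generative law, independently of the
#' fitted pipeline: the acceptance oracle.  For the Gaussian copula (and
#' the trivial families) conditional draws are generated exactly, so all
#' `n_mc` draws are conditional exceedances; for the logistic and exact
#' conditional-model families, `n_mc` unconditional draws are generated in
#' chunks and the reported `n_mc` is the number of conditional exceedances
#' actually used.  Perfect dependence is returned in closed form.
#'
#' @param spec A `synthetic_spec`.
#' @param q_c Conditioning quantile level.
#' @param q_r Response quantile level (default 0.90).
#' @param n_mc Monte-Carlo size (default 1e7).
#' @param seed Seed.
#' @return A one-row tibble: `probability`, `se` (binomial), `n_mc` (the
#'   conditional draws used), `q_c`, `q_r`, `family`.
#' @examples
#' oracle_cond_prob(synthetic_spec("independent"), q_c = 0.98, n_mc = 1e5)
#' @export
oracle_cond_prob <- function(spec, q_c, q_r = 0.9, n_mc = 1e7, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  check_prob(q_c, "q_c")
  check_prob(q_r, "q_r")
  set.seed(seed)
  flip <- function(u) if (spec$negate) 1 - u else u
  if (spec$family == "perfect") {
    p <- if (spec$negate) {
      max(0, (1 - q_r) - q_c) / (1 - q_c)
    } else {
      (1 - max(q_c, q_r)) / (1 - q_c)
    }
    return(tibble::tibble(probability = p, se = 0, n_mc = NA_integer_,
                          q_c = q_c, q_r = q_r, family = spec$family))
  }
  if (spec$family == "independent") {
    u <- runif(n_mc)
    p <- mean(u > q_r)
    return(tibble::tibble(probability = p, se = sqrt(p * (1 - p) / n_mc),
                          n_mc = n_mc, q_c = q_c, q_r = q_r,
                          family = spec$family))
  }
  if (spec$family == "gaussian") {
    v <- qnorm(runif(n_mc, q_c, 1))
    z <- spec$dep * v + sqrt(1 - spec$dep^2) * rnorm(n_mc)
    u <- flip(pnorm(z))
    p <- mean(u > q_r)
    return(tibble::tibble(probability = p, se = sqrt(p * (1 - p) / n_mc),
                          n_mc = n_mc, q_c = q_c, q_r = q_r,
                          family = spec$family))
  }
  ## logistic / ht: unconditional chunked simulation
  chunk <- 1e6
  done <- 0
  n_cond <- 0
  n_joint <- 0
  resp_pool <- NULL
  cond_pool <- NULL
  if (spec$family == "ht") {
    ## thresholds are empirical quantiles of a large pre-sample
    pre <- ht_draws(spec, min(n_mc, 2e6))
    r_lvl <- quantile7(if (spec$negate) -pre[, 1] else pre[, 1], q_r)
    c_lvl <- quantile7(pre[, 2], q_c)
  } else {
    r_lvl <- q_r
    c_lvl <- q_c
  }
  while (done < n_mc) {
    m <- min(chunk, n_mc - done)
    if (spec$family == "ht") {
      xy <- ht_draws(spec, m)
      r <- if (spec$negate) -xy[, 1] else xy[, 1]
      cc <- xy[, 2]
    } else {
      u <- rlogistic_cop(m, spec$dep)
      r <- flip(u[, 1])
      cc <- u[, 2]
    }
    sel <- cc > c_lvl
    n_cond <- n_cond + sum(sel)
    n_joint <- n_joint + sum(sel & r > r_lvl)
    done <- done + m
  }
  if (n_cond == 0) {
    abort("no conditioning exceedances in the Monte-Carlo run; increase n_mc")
  }
  p <- n_joint / n_cond
  tibble::tibble(probability = p, se = sqrt(p * (1 - p) / n_cond),
                 n_mc = n_cond, q_c = q_c, q_r = q_r, family = spec$family)
}
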