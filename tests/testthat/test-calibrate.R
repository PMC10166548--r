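test_that("prior log-densities match closed-form references", {
  set.seed(100)
  checks <- list(
    list(p = prior_normal(-6.5, 1.5),
         ref = function(v) dnorm(v, -6.5, 1.5, log = TRUE), lo = -12, hi = 0),
    list(p = prior_exponential(0.25),
         ref = function(v) dexp(v, 4, log = TRUE), lo = 0.01, hi = 2),
    list(p = prior_uniform(0, 100),
         ref = function(v) dunif(v, 0, 100, log = TRUE), lo = 1, hi = 99),
    list(p = prior_laplace(0, 0.1),
         ref = function(v) log(1 / 0.2) - abs(v) / 0.1, lo = -1, hi = 1),
    list(p = prior_invgamma(3, 0.2),
         ref = function(v) log(0.2^3 / gamma(3)) - 4 * log(v) - 0.2 / v,
         lo = 0.01, hi = 1)
  )
  for (ck in checks) {
    for (v in runif(100, ck$lo, ck$hi))
      expect_equal(ck$p$logd(v), ck$ref(v), tolerance = 1e-10)
  }
  # truncated Cauchy: renormalized on the positive half line
  pc <- prior_cauchy(0.2, 0.05, lower = 0)
  for (v in runif(50, 0.001, 1)) {
    ref <- dcauchy(v, 0.2, 0.05, log = TRUE) -
      log(1 - pcauchy(0, 0.2, 0.05))
    expect_equal(pc$logd(v), ref, tolerance = 1e-10)
  }
  expect_identical(pc$logd(-0.1), -Inf)
})

test_that("support violations give -Inf and genotype truncation is respected", {
  priors <- c(list(prior_normal(0, 1)), rep(list(prior_exponential(0.25)), 3))
  expect_identical(log_prior(c(0, 0.1, -0.01, 0.2), priors), -Inf)
  expect_true(is.finite(log_prior(c(0, 0.1, 0.01, 0.2), priors)))
  expect_error(log_prior(c(0, 1), priors), "layout")
  # truncated log-scale genotype prior: above the bound is impossible
  pd <- prior_normal_trunc(0, 1.5, upper = 0)
  expect_identical(pd$logd(0.5), -Inf)
  expect_true(is.finite(pd$logd(-0.5)))
  set.seed(2)
  expect_true(all(pd$sample(500) <= 0))
})

test_that("prior samplers agree with their densities", {
  set.seed(42)
  # Kolmogorov-Smirnov-style quantile agreement for the Laplace sampler
  pl <- prior_laplace(0.5, 0.2)
  s <- pl$sample(20000)
  # Laplace quantiles: median and the 1/4, 3/4 points at location +- scale ln 2
  expect_equal(median(s), 0.5, tolerance = 0.01)
  expect_equal(unname(quantile(s, 0.75)), 0.5 + 0.2 * log(2), tolerance = 0.02)
  pc <- prior_cauchy(0.2, 0.05, lower = 0)
  sc <- pc$sample(5000)
  expect_true(all(sc > 0))
  # analytic median of the truncated distribution: quantile at p0 + (1-p0)/2
  p0 <- pcauchy(0, 0.2, 0.05)
  med_ref <- qcauchy(p0 + (1 - p0) / 2, 0.2, 0.05)
  expect_equal(median(sc), med_ref, tolerance = 0.03)
})

test_that("inverse-gamma moment matching reproduces the CV prior", {
  ab <- invgamma_cv_match(0.20, 0.015)
  set.seed(7)
  v <- prior_invgamma(ab$a, ab$b)$sample(2e5)
  cv <- sqrt(v)
  expect_equal(mean(cv), 0.20, tolerance = 0.02)
  expect_equal(sd(cv), 0.015, tolerance = 0.02)
})

test_that("ordinal prior variants cover the documented families", {
  pr <- ordinal_priors(5, "exponential")
  expect_length(pr, 5)
  expect_equal(pr[[1]]$args$scale, 100)
  expect_equal(pr[[2]]$args$scale, 0.25)
  pu <- ordinal_priors(5, "uniform")
  expect_equal(pu[[1]]$args$max, 100); expect_equal(pu[[2]]$args$max, 1)
  pw <- ordinal_priors(5, "cauchy_wide")
  expect_equal(pw[[1]]$args, list(location = 50, scale = 10))
  expect_equal(pw[[2]]$args, list(location = 0.2, scale = 0.05))
  pn <- ordinal_priors(5, "cauchy_narrow")
  expect_equal(pn[[1]]$args$scale, 1)
  expect_equal(pn[[2]]$args$scale, 0.005)
  pnm <- nominal_priors(3)
  expect_length(pnm, 5)
  expect_equal(pnm[[1]]$args$scale, 1)
  expect_equal(pnm[[3]]$args$scale, 0.10)
})

test_that("the sampler recovers a known 2-D Gaussian target", {
  mu <- c(1, -2); sdv <- c(0.5, 2)
  logpost <- function(x) sum(dnorm(x, mu, sdv, log = TRUE))
  priors <- list(prior_normal(0, 5), prior_normal(0, 5))
  cfg <- sampler_config(burn_in = 500, max_steps = 4000, seed = 31)
  ch <- dream_sample(logpost, priors, cfg)
  dr <- posterior_draws(ch, 4000)
  for (j in 1:2) {
    mcse <- sd(dr[, j]) / sqrt(200)          # conservative effective size
    expect_lt(abs(mean(dr[, j]) - mu[j]), 3 * mcse + 0.05)
    expect_lt(abs(sd(dr[, j]) - sdv[j]) / sdv[j], 0.10)
  }
})

test_that("chains are reproducible and never leave the prior support", {
  logpost <- function(x) dnorm(x[1], 0, 1, log = TRUE) +
    dexp(x[2], 2, log = TRUE)
  priors <- list(prior_normal(0, 2), prior_exponential(0.5))
  cfg <- sampler_config(burn_in = 200, max_steps = 1200, seed = 9)
  ch1 <- dream_sample(logpost, priors, cfg)
  ch2 <- dream_sample(logpost, priors, cfg)
  expect_identical(ch1$draws, ch2$draws)
  expect_true(all(ch1$draws[, 2, ] > 0))
})

test_that("a double-well density is sampled with correct mass balance", {
  # log density of a symmetric 1-D double well: modes at +-1.5
  logpost <- function(x) -((x[1]^2 - 2.25)^2) / 1.5
  priors <- list(prior_normal(0, 3))
  cfg <- sampler_config(burn_in = 2000, max_steps = 25000, seed = 17,
                        p_gamma_unity = 0.2)
  ch <- dream_sample(logpost, priors, cfg)
  dr <- posterior_draws(ch, 50000, fraction = 0.8)
  # analytic CDF by quadrature
  xs <- seq(-4, 4, length.out = 2001)
  dens <- exp(-((xs^2 - 2.25)^2) / 1.5)
  cdf <- cumsum(dens) / sum(dens)
  emp <- ecdf(dr[, 1])
  ks <- max(abs(emp(xs) - cdf))
  expect_lt(ks, 0.05)
  # both wells visited with near-equal mass
  expect_lt(abs(mean(dr[, 1] > 0) - 0.5), 0.05)
})

test_that("the Gelman-Rubin statistic matches its formula and detects non-mixing", {
  set.seed(12)
  iid <- array(rnorm(5000 * 2 * 4), c(5000, 2, 4))
  gr <- gelman_rubin(iid)
  expect_true(all(gr > 0.99 & gr < 1.05))
  # two chains parked far apart are flagged
  apart <- array(c(rnorm(1000, 0), rnorm(1000, 100)), c(1000, 1, 2))
  expect_gt(gelman_rubin(apart)[1], 1.2)
  # textbook formula oracle on a fixed 3-chain toy (latter half only)
  toy <- array(sin(1:300) + rep(c(0, 0.3, -0.1), each = 100), c(100, 1, 3))
  keep <- 51:100
  expect_equal(unname(gelman_rubin(toy)[1]),
               psrf_oracle(toy[keep, 1, ]))
  # degenerate zero-variance parameter reported NA
  flat <- array(1, c(100, 1, 3))
  expect_true(is.na(gelman_rubin(flat)[1]))
})

test_that("convergence control stops only when all parameters pass", {
  logpost <- function(x) sum(dnorm(x, 0, 1, log = TRUE))
  priors <- list(prior_normal(0, 2), prior_normal(0, 2))
  prob <- list(logpost = logpost, priors = priors,
               par_names = c("a", "b"))
  cfg <- sampler_config(burn_in = 200, max_steps = 3000, seed = 3,
                        check_interval = 200)
  ch <- run_until_converged(prob, cfg)
  expect_true(ch$converged)
  expect_named(ch$gelman_rubin, c("a", "b"))
  expect_true(all(ch$gelman_rubin <= 1.2))
  # the convergence report lists every free parameter exactly once
  expect_length(ch$gelman_rubin, 2)
})

test_that("chain archives round-trip through the text serialization", {
  logpost <- function(x) dnorm(x[1], 0, 1, log = TRUE)
  ch <- dream_sample(logpost, list(prior_normal(0, 2)),
                     sampler_config(burn_in = 100, max_steps = 300, seed = 5))
  base <- tempfile()
  save_chains(ch, base)
  back <- load_chains(base)
  expect_equal(back$draws, ch$draws, tolerance = 1e-12)
  expect_equal(back$par_names, ch$par_names)
  expect_equal(back$converged, ch$converged)
})
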