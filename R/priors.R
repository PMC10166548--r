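## Prior specifications.  A prior spec is an ordered list of single-
## coordinate prior objects, one per free parameter; each object carries a
## log-density, a sampler and its support.  Mechanism rate constants are
## handled on the log10 scale (rate uncertainty spans orders of magnitude),
## so their "lognormal, scale 1.5" prior is a normal on log10 rates.

mm_prior <- function(type, logd, sample, lower = -Inf, upper = Inf, args = list()) {
  structure(list(type = type, logd = logd, sample = sample,
                 lower = lower, upper = upper, args = args),
            class = "mm_prior")
}

#' @export
print.mm_prior <- function(x, ...) {
  cat("prior:", x$type,
      if (length(x$args)) paste0("(", paste(names(x$args), unlist(x$args),
                                            sep = "=", collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Prior distribution constructors
#'
#' Single-coordinate priors used to assemble a prior specification:
#' * `prior_normal(mean, sd)` — e.g. on log10 rate constants, where a
#'   lognormal rate prior with scale 1.5 becomes `prior_normal(log10_truth, 1.5)`.
#' * `prior_exponential(scale)` — support `(0, Inf)`.
#' * `prior_laplace(location, scale)` — double exponential.
#' * `prior_uniform(min, max)`.
#' * `prior_cauchy(location, scale, lower)` — optionally truncated below
#'   (renormalized), e.g. `lower = 0` for offset distances.
#' * `prior_normal_trunc(mean, sd, upper)` — normal truncated above, e.g. on
#'   log10 genotype multipliers (`upper = 0` keeps the multiplier <= 1).
#' * `prior_invgamma(a, b)` — inverse gamma on a variance.
#'
#' @param mean,sd,location,scale,min,max,lower,upper,a,b distribution
#'   parameters.
#' @return An object of class `mm_prior`.
#' @name priors
NULL

#' @rdname priors
#' @export
prior_normal <- function(mean, sd) {
  mm_prior("normal",
           function(v) dnorm(v, mean, sd, log = TRUE),
           function(n) rnorm(n, mean, sd),
           args = list(mean = mean, sd = sd))
}

#' @rdname priors
#' @export
prior_exponential <- function(scale) {
  stopifnot(scale > 0)
  mm_prior("exponential",
           function(v) dexp(v, rate = 1 / scale, log = TRUE),
           function(n) rexp(n, rate = 1 / scale),
           lower = 0, args = list(scale = scale))
}

#' @rdname priors
#' @export
prior_laplace <- function(location, scale, lower = -Inf) {
  stopifnot(scale > 0)
  base_logd <- function(v) -log(2 * scale) - abs(v - location) / scale
  base_cdf <- function(v) {
    z <- (v - location) / scale
    ifelse(z < 0, exp(z) / 2, 1 - exp(-z) / 2)
  }
  lognorm <- if (is.finite(lower)) log1p(-base_cdf(lower)) else 0
  mm_prior("laplace",
           function(v) {
             if (v < lower) return(-Inf)
             base_logd(v) - lognorm
           },
           function(n) {
             p0 <- if (is.finite(lower)) base_cdf(lower) else 0
             u <- p0 + runif(n) * (1 - p0)
             ifelse(u < 0.5, location + scale * log(2 * u),
                    location - scale * log(2 * (1 - u)))
           },
           lower = lower, args = list(location = location, scale = scale))
}

#' @rdname priors
#' @export
prior_uniform <- function(min, max) {
  stopifnot(max > min)
  mm_prior("uniform",
           function(v) dunif(v, min, max, log = TRUE),
           function(n) runif(n, min, max),
           lower = min, upper = max, args = list(min = min, max = max))
}

#' @rdname priors
#' @export
prior_cauchy <- function(location, scale, lower = -Inf) {
  stopifnot(scale > 0)
  lognorm <- if (is.finite(lower))
    log1p(-pcauchy(lower, location, scale)) else 0
  mm_prior("cauchy",
           function(v) {
             if (v < lower) return(-Inf)
             dcauchy(v, location, scale, log = TRUE) - lognorm
           },
           function(n) {
             if (!is.finite(lower)) return(rcauchy(n, location, scale))
             p0 <- pcauchy(lower, location, scale)
             location + scale * tan(pi * (p0 + runif(n) * (1 - p0) - 0.5))
           },
           lower = lower, args = list(location = location, scale = scale))
}

#' @rdname priors
#' @export
prior_normal_trunc <- function(mean, sd, upper) {
  lognorm <- pnorm(upper, mean, sd, log.p = TRUE)
  mm_prior("normal_trunc",
           function(v) {
             if (v > upper) return(-Inf)
             dnorm(v, mean, sd, log = TRUE) - lognorm
           },
           function(n) qnorm(runif(n) * pnorm(upper, mean, sd), mean, sd),
           upper = upper, args = list(mean = mean, sd = sd, upper = upper))
}

#' @rdname priors
#' @export
prior_invgamma <- function(a, b) {
  stopifnot(a > 0, b > 0)
  mm_prior("invgamma",
           function(v) {
             if (v <= 0) return(-Inf)
             a * log(b) - lgamma(a) - (a + 1) * log(v) - b / v
           },
           function(n) 1 / rgamma(n, shape = a, rate = b),
           lower = 0, args = list(a = a, b = b))
}

#' Inverse-gamma hyperparameters from coefficient-of-variation moments
#'
#' If the extrinsic variance `v` (the squared coefficient of variation of
#' the heterogeneous initial conditions) follows an inverse gamma
#' distribution, the induced CV is `sqrt(v)`.  This solves, by moment
#' matching, for the `(a, b)` pair such that `sqrt(v)` has the requested
#' prior mean and standard deviation (defaults 0.20 and 0.015).
#'
#' Uses `E[sqrt(v)] = sqrt(b) * Gamma(a - 1/2) / Gamma(a)` and
#' `E[v] = b / (a - 1)`; the ratio `E[v] / E[sqrt(v)]^2` depends on `a`
#' alone and is solved with `uniroot`.
#'
#' @param mean_cv,sd_cv target moments of the induced CV.
#' @return List with elements `a` and `b`.
#' @export
invgamma_cv_match <- function(mean_cv = 0.20, sd_cv = 0.015) {
  stopifnot(mean_cv > 0, sd_cv > 0)
  target <- (sd_cv^2 + mean_cv^2) / mean_cv^2
  ratio <- function(a) exp(-log(a - 1) + 2 * (lgamma(a) - lgamma(a - 0.5)))
  a <- uniroot(function(a) ratio(a) - target, c(1.5, 1e6), tol = 1e-12)$root
  b <- (mean_cv * exp(lgamma(a) - lgamma(a - 0.5)))^2
  list(a = a, b = b)
}

#' Log prior density of a full parameter vector
#'
#' @param x numeric parameter vector.
#' @param priors list of `mm_prior` objects, one per coordinate of `x`.
#' @return Sum of the independent log densities; `-Inf` outside any
#'   coordinate's support.
#' @export
log_prior <- function(x, priors) {
  if (length(x) != length(priors))
    stop("parameter vector layout does not match the prior specification")
  total <- 0
  for (i in seq_along(x)) {
    ld <- priors[[i]]$logd(x[i])
    if (ld == -Inf) return(-Inf)
    total <- total + ld
  }
  total
}

#' Draw parameter vectors from a prior specification
#'
#' @param n number of draws.
#' @param priors list of `mm_prior` objects.
#' @return `n` by `length(priors)` matrix.
#' @export
sample_prior <- function(n, priors) {
  vapply(priors, function(p) p$sample(n), numeric(n))
}

#' Ordinal measurement-model prior variants
#'
#' The data-driven default gives the shared slope an exponential prior
#' (scale 100) and the positive offset distances exponential priors
#' (scale 0.25).  Biased variants encode a prior belief that category
#' boundaries sit at every `spacing` interval of the normalized measurand:
#' `"uniform"` (slope U(0, 100), distances U(0, 1)), `"cauchy_wide"`
#' (slope Cauchy(50, 10), distances Cauchy(spacing, 0.05) truncated to
#' positive) and `"cauchy_narrow"` (slope Cauchy(50, 1), distances
#' Cauchy(spacing, 0.005) truncated to positive).
#'
#' @param n_categories number of ordinal categories `J`.
#' @param variant prior family.
#' @param spacing assumed boundary spacing for the Cauchy variants
#'   (default `1 / J`).
#' @return List of `J` `mm_prior` objects (slope first, then the `J - 1`
#'   distances).
#' @export
ordinal_priors <- function(n_categories,
                           variant = c("exponential", "uniform",
                                       "cauchy_wide", "cauchy_narrow"),
                           spacing = 1 / n_categories) {
  variant <- match.arg(variant)
  J <- as.integer(n_categories)
  stopifnot(J >= 2)
  nb <- J - 1L
  switch(variant,
    exponential = c(list(prior_exponential(100)),
                    rep(list(prior_exponential(0.25)), nb)),
    uniform = c(list(prior_uniform(0, 100)),
                rep(list(prior_uniform(0, 1)), nb)),
    cauchy_wide = c(list(prior_cauchy(50, 10, lower = 0)),
                    rep(list(prior_cauchy(spacing, 0.05, lower = 0)), nb)),
    cauchy_narrow = c(list(prior_cauchy(50, 1, lower = 0)),
                      rep(list(prior_cauchy(spacing, 0.005, lower = 0)), nb))
  )
}

#' Nominal measurement-model priors
#'
#' Laplace(0, 1) on the slope and Laplace(0, 0.10) on the intercept and each
#' feature weight.  The slope prior is truncated to the positive half-line:
#' the logistic cell-fate model is invariant under the joint sign flip of
#' slope, intercept and weights, so without the constraint the posterior has
#' two exact mirror modes and chain convergence on the raw parameters is
#' undefined.  Truncation removes the redundant copy and changes nothing
#' observable (predicted probabilities and effective weights are
#' flip-invariant).
#'
#' @param n_features number of features `L`.
#' @return List of `L + 2` `mm_prior` objects (slope, intercept, weights).
#' @export
nominal_priors <- function(n_features) {
  c(list(prior_laplace(0, 1, lower = 0), prior_laplace(0, 0.10)),
    rep(list(prior_laplace(0, 0.10)), n_features))
}

#' Mechanism rate priors on the log10 scale
#'
#' Independent normals on log10 rate constants centred at the ground-truth
#' (or reference) values with scale 1.5 — i.e. lognormal priors on the rates
#' spanning roughly three orders of magnitude.
#'
#' @param reference named vector of reference rate constants (linear scale).
#' @param sd prior scale on log10 rates.
#' @return Named list of `mm_prior` objects.
#' @export
mechanism_priors <- function(reference, sd = 1.5) {
  setNames(lapply(log10(reference), prior_normal, sd = sd), names(reference))
}
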