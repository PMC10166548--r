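## Measurement-model likelihood families.
##
## Four families link latent model trajectories to data: (i) Gaussian
## likelihoods for normalized fluorescence time courses, (ii) cumulative-link
## (ordinal logistic) models with an adjacent-category misclassification
## matrix, (iii) a logistic cell-fate model over dynamic features for nominal
## outcomes, and (iv) a zero-mean Gaussian process with an ARD radial-basis
## kernel for fractional cell death.  A composite likelihood multiplies the
## per-dataset likelihoods (sums their logs).

## --- fluorescence ----------------------------------------------------------

#' Gaussian log-likelihood for fluorescence time courses
#'
#' Sum over data points of `-(pred - obs)^2 / (2 sigma^2)`, i.e. the kernel
#' of an i.i.d. Gaussian noise model on normalized predictions.  Predictions
#' must already be aligned (interpolated) to the data time points.
#'
#' @param pred numeric vector of normalized model predictions.
#' @param obs numeric vector of observed normalized values.
#' @param sigma per-point standard deviations (recycled if scalar; must be
#'   positive wherever a data point exists).
#' @return Log-likelihood (Gaussian kernel; constant terms dropped).
#' @export
fluorescence_loglik <- function(pred, obs, sigma) {
  stopifnot(length(pred) == length(obs))
  sigma <- rep_len(sigma, length(obs))
  if (any(sigma <= 0)) stop("sigma must be positive at every data point")
  sum(-(pred - obs)^2 / (2 * sigma^2))
}

## --- ordinal ----------------------------------------------------------------

#' Cumulative-link ordinal measurement-model parameters
#'
#' A shared slope `alpha` and positive offset distances `theta` define
#' monotone category boundaries `beta_j = cumsum(theta)` on the normalized
#' measurand scale.  The cumulative probability of reaching category `j` or
#' above is `plogis(alpha * (x - beta_j))`; positivity of `theta` guarantees
#' the ordering constraint by construction.
#'
#' @param alpha slope (>= 0; 0 gives category probabilities independent of
#'   the measurand).
#' @param theta positive offset distances, one per category boundary
#'   (`J - 1` of them for `J` categories).
#' @return An object of class `mm_ordinal_params` with elements `alpha`,
#'   `theta`, `beta` and `n_categories`.
#' @export
ordinal_params <- function(alpha, theta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0)
  if (length(theta) < 1 || any(theta <= 0))
    stop("theta must be positive offset distances (J >= 2 categories)")
  structure(list(alpha = alpha, theta = as.numeric(theta),
                 beta = cumsum(as.numeric(theta)),
                 n_categories = length(theta) + 1L),
            class = "mm_ordinal_params")
}

#' Ordinal category probabilities under the cumulative model
#'
#' For each measurand value `x`, returns the probability of each ordinal
#' category `c_0 .. c_{J-1}` as differences of cumulative logistic terms:
#' `P(y = c_j | x) = P(y >= c_j | x) - P(y >= c_{j+1} | x)` with
#' `P(y >= c_0) = 1` and `P(y >= c_J) = 0`.
#'
#' @param x numeric vector of measurand values (normalized scale).
#' @param params an [ordinal_params()] object.
#' @return Matrix `length(x)` by `J` of probabilities; rows sum to 1.
#' @export
ordinal_category_probs <- function(x, params) {
  stopifnot(inherits(params, "mm_ordinal_params"))
  J <- params$n_categories
  cum <- vapply(params$beta,
                function(b) plogis(params$alpha * (x - b)),
                numeric(length(x)))
  cum <- matrix(cum, nrow = length(x))
  cum <- cbind(1, cum, 0)               # P(y >= c_0) = 1, P(y >= c_J) = 0
  probs <- cum[, 1:J, drop = FALSE] - cum[, 2:(J + 1), drop = FALSE]
  colnames(probs) <- paste0("c", seq_len(J) - 1L)
  probs
}

#' Adjacent-category misclassification matrix
#'
#' Row-stochastic `J x J` matrix of `P(reported | true)`: probability
#' `1 - p` on the diagonal and `p/2` on each adjacent category; terminal
#' categories put the whole `p` on their single neighbour.  The default
#' `p = 0.05` reproduces the 95% / 2.5% structure used to corrupt synthetic
#' ordinal data.
#'
#' @param n_categories number of categories `J >= 2`.
#' @param p total misclassification probability.
#' @return `J x J` row-stochastic matrix.
#' @export
misclassification_matrix <- function(n_categories, p = 0.05) {
  J <- as.integer(n_categories)
  stopifnot(J >= 2, p >= 0, p < 1)
  M <- diag(1 - p, J)
  for (j in seq_len(J)) {
    nb <- intersect(c(j - 1, j + 1), seq_len(J))
    M[j, nb] <- p / length(nb)
  }
  M
}

#' Ordinal log-likelihood with misclassification
#'
#' Marginalizes over the true category: for each observation the likelihood
#' is `sum_j P(reported | true = c_j) P(c_j | x)`, summed on the log scale
#' over all observations (Eq of the cumulative model with an error matrix).
#'
#' @param x measurand values aligned to the observations (normalized scale).
#' @param categories observed integer categories in `0 .. J-1`.
#' @param params an [ordinal_params()] object.
#' @param error misclassification matrix (`J x J`, row-stochastic);
#'   defaults to [misclassification_matrix()] with `p = 0.05`.
#' @return Log-likelihood; `-Inf` only if some observation has zero marginal
#'   probability.
#' @export
ordinal_loglik <- function(x, categories, params,
                           error = misclassification_matrix(params$n_categories)) {
  stopifnot(inherits(params, "mm_ordinal_params"),
            length(x) == length(categories))
  J <- params$n_categories
  categories <- as.integer(categories)
  if (any(categories < 0 | categories >= J))
    stop("categories must lie in [0, J)")
  stopifnot(nrow(error) == J, ncol(error) == J)
  probs <- ordinal_category_probs(x, params)
  marginal <- probs %*% error          # [t, r] = sum_j P(c_j|x_t) P(r | c_j)
  sum(log(marginal[cbind(seq_along(x), categories + 1L)]))
}

## --- nominal ----------------------------------------------------------------

#' Logistic cell-fate measurement-model parameters
#'
#' @param alpha slope term.
#' @param intercept intercept `beta`.
#' @param weights numeric vector of feature weights `beta_l`.
#' @return An object of class `mm_nominal_params`.
#' @export
nominal_params <- function(alpha, intercept, weights) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(intercept), length(intercept) == 1,
            is.numeric(weights), all(is.finite(weights)))
  structure(list(alpha = alpha, intercept = intercept,
                 weights = as.numeric(weights)),
            class = "mm_nominal_params")
}

#' Probability of a cell-death outcome
#'
#' `P(death | x) = plogis(alpha * (intercept + sum_l w_l x_l))`.
#'
#' @param features numeric vector of length `L`, or matrix with `L` columns
#'   (one row per cell).
#' @param params an [nominal_params()] object.
#' @return Probability (vector of probabilities for a matrix input).
#' @export
nominal_prob <- function(features, params) {
  stopifnot(inherits(params, "mm_nominal_params"))
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(X) != length(params$weights))
    stop("feature count does not match the number of weights")
  z <- params$alpha * (params$intercept + drop(X %*% params$weights))
  plogis(z)
}

#' Bernoulli log-likelihood for nominal cell-fate data
#'
#' Each observation is an independent Bernoulli draw with success
#' probability [nominal_prob()]; misclassification probability is zero.
#'
#' @param features matrix of per-cell feature vectors (`M` rows).
#' @param outcomes vector of `"death"`/`"survival"` (or 1/0).
#' @param params an [nominal_params()] object.
#' @return Log-likelihood over the `M` observations.
#' @export
nominal_loglik <- function(features, outcomes, params) {
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  y <- outcome_to_binary(outcomes)
  stopifnot(nrow(X) == length(y))
  p <- nominal_prob(X, params)
  sum(ifelse(y == 1L, log(p), log1p(-p)))
}

outcome_to_binary <- function(outcomes) {
  if (is.numeric(outcomes)) {
    if (!all(outcomes %in% c(0, 1))) stop("numeric outcomes must be 0/1")
    return(as.integer(outcomes))
  }
  if (!all(outcomes %in% c("death", "survival")))
    stop("outcomes must be 'death' or 'survival'")
  as.integer(outcomes == "death")
}

## --- Gaussian process -------------------------------------------------------

#' Gaussian-process measurement-model parameters
#'
#' An ARD radial-basis kernel with amplitude `sigma_f2` and per-feature
#' weights `beta` defining the inverse-squared length-scale matrix
#' `M = diag(beta)^-2`; larger `|beta_l|` means feature `l` matters more.
#' `sigma_y` is the per-observation noise standard deviation (recycled),
#' floored at 1e-3, and enters only the Gram-matrix diagonal.
#'
#' @param sigma_f2 kernel amplitude (> 0), in squared-fraction units.
#' @param beta nonzero per-feature weights.
#' @param sigma_y per-observation noise sd (scalar or vector).
#' @return An object of class `mm_gp_params`.
#' @export
gp_params <- function(sigma_f2, beta, sigma_y = 0.05) {
  stopifnot(is.numeric(sigma_f2), length(sigma_f2) == 1, sigma_f2 > 0)
  if (any(beta == 0))
    stop("zero GP weights are not allowed; mask the feature out instead")
  structure(list(sigma_f2 = sigma_f2, beta = as.numeric(beta),
                 sigma_y = pmax(as.numeric(sigma_y), 1e-3)),
            class = "mm_gp_params")
}

#' ARD radial-basis kernel
#'
#' `k(xp, xq) = sigma_f2 * exp(-0.5 * sum(((xp - xq) / beta)^2))`.
#' Observation noise is *not* added here; it enters only the Gram-matrix
#' diagonal in [gp_log_marginal()].
#'
#' @param xp,xq equal-length feature vectors.
#' @param params an [gp_params()] object.
#' @return Covariance value.
#' @export
rbf_ard_kernel <- function(xp, xq, params) {
  stopifnot(inherits(params, "mm_gp_params"), length(xp) == length(xq),
            length(xp) == length(params$beta))
  d <- (xp - xq) / params$beta
  params$sigma_f2 * exp(-0.5 * sum(d * d))
}

gp_gram <- function(X, params) {
  n <- nrow(X)
  Xs <- sweep(X, 2, params$beta, "/")
  sq <- rowSums(Xs^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Xs)
  D2[D2 < 0] <- 0
  K <- params$sigma_f2 * exp(-0.5 * D2)
  K + diag(rep_len(params$sigma_y, n)^2, n)
}

## Cholesky with escalating jitter: 1e-8 * trace/n, doubled up to 3 times.
chol_jitter <- function(S) {
  jit <- 1e-8 * sum(diag(S)) / nrow(S)
  for (i in 0:3) {
    R <- tryCatch(chol(S + diag(if (i == 0) 0 else jit * 2^(i - 1), nrow(S))),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  NULL
}

#' Gaussian-process log marginal likelihood
#'
#' Zero-mean GP regression: with Gram matrix `S = K + diag(sigma_y^2)`,
#' returns `-y' S^-1 y / 2 - log|S| / 2 - n log(2 pi) / 2`.  A Cholesky
#' factorization with escalating jitter is used; if the matrix stays
#' non-positive-definite the value is `-Inf` (numerical-failure signal).
#'
#' @param X feature matrix (one row per observation).
#' @param y observed fractional values (centred as supplied; the model mean
#'   is zero).
#' @param params an [gp_params()] object.
#' @return Log marginal likelihood.
#' @export
gp_log_marginal <- function(X, y, params) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) == length(params$beta))
  S <- gp_gram(X, params)
  R <- chol_jitter(S)
  if (is.null(R)) return(-Inf)
  a <- backsolve(R, forwardsolve(t(R), y))
  -0.5 * sum(y * a) - sum(log(diag(R))) - length(y) / 2 * log(2 * pi)
}

#' GP posterior predictive mean
#'
#' Conditions the zero-mean GP on training data `(X, y)` and returns the
#' posterior mean at new feature vectors.
#'
#' @param X_new matrix of query feature vectors.
#' @param X,y training features and values.
#' @param params an [gp_params()] object.
#' @param clamp optional length-2 range to clamp predictions to (use
#'   `c(0, 1)` for fractions); `NULL` for no clamping.
#' @return Vector of posterior means.
#' @export
gp_predict_mean <- function(X_new, X, y, params, clamp = c(0, 1)) {
  X <- as.matrix(X); X_new <- as.matrix(X_new)
  S <- gp_gram(X, params)
  R <- chol_jitter(S)
  if (is.null(R)) infeasible("GP Gram matrix not positive definite")
  a <- backsolve(R, forwardsolve(t(R), y))
  Kstar <- apply(X_new, 1, function(xn)
    apply(X, 1, function(xi) rbf_ard_kernel(xn, xi, params)))
  mu <- drop(crossprod(matrix(Kstar, nrow = nrow(X)), a))
  if (!is.null(clamp)) mu <- pmin(pmax(mu, clamp[1]), clamp[2])
  mu
}

## --- composite --------------------------------------------------------------

#' Composite log-likelihood over a dataset bundle
#'
#' Sums the log-likelihoods of independently modeled datasets (the product
#' rule on the likelihood scale).  Any `-Inf` component makes the total
#' `-Inf`; any non-finite other than `-Inf` is an error.
#'
#' @param logliks numeric vector (or list) of per-dataset log-likelihoods.
#' @return Total log-likelihood.
#' @export
composite_loglik <- function(logliks) {
  ll <- unlist(logliks, use.names = FALSE)
  if (length(ll) == 0) stop("no dataset log-likelihoods supplied")
  if (any(is.nan(ll) | ll == Inf)) stop("non-finite (non -Inf) component")
  if (any(ll == -Inf)) return(-Inf)
  sum(ll)
}
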