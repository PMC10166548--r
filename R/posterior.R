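## Posterior-predictive machinery: credible regions and the area metric,
## ordinal class-probability bands, nominal decision boundaries, feature-
## weight posteriors, density contours of simulated populations, and
## Gaussian-process predictions of fractional cell death.

#' Posterior-predictive credible region
#'
#' Sub-samples `n_draws` parameter vectors from the latter half of the
#' chains, evaluates `fn` (a map from parameter vector to a series over the
#' time grid) for each, and takes the pointwise 0.025 / 0.975 quantiles and
#' the median (type-7 quantiles).  Draws for which `fn` returns `NULL`
#' (infeasible) are dropped.
#'
#' @param chains an `mm_chains` archive (or a matrix of posterior draws).
#' @param fn function of one parameter vector returning a numeric series.
#' @param n_draws number of posterior draws (default 1000).
#' @param grid time grid the series live on (default [sim_grid()]).
#' @param seed optional seed for the sub-sampling.
#' @return An object of class `mm_credible_region`: list with `time`,
#'   `lower`, `median`, `upper` and the number of draws used.
#' @export
credible_region <- function(chains, fn, n_draws = 1000, grid = sim_grid(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- if (is.matrix(chains)) chains else posterior_draws(chains, n_draws)
  sims <- lapply(seq_len(nrow(draws)), function(i) fn(draws[i, ]))
  sims <- sims[!vapply(sims, is.null, TRUE)]
  if (length(sims) == 0) stop("no feasible posterior draws")
  M <- do.call(rbind, sims)
  stopifnot(ncol(M) == length(grid))
  structure(list(
    time = grid,
    lower = apply(M, 2, quantile, 0.025, type = 7),
    median = apply(M, 2, median),
    upper = apply(M, 2, quantile, 0.975, type = 7),
    n_draws = nrow(M)
  ), class = "mm_credible_region")
}

#' @export
print.mm_credible_region <- function(x, ...) {
  cat("95% credible region over", length(x$time), "time points (",
      x$n_draws, "draws ), area =", round(credible_area(x), 2), "\n")
  invisible(x)
}

#' Area of a 95% credible region
#'
#' Sum of the band widths (0.975 minus 0.025 quantile) across the 100
#' equally spaced time points of the standard grid — the certainty metric
#' used throughout (smaller area, higher certainty); units are normalized
#' concentration times time points.
#'
#' @param region an `mm_credible_region` on the standard 100-point grid.
#' @return Nonnegative area.
#' @export
credible_area <- function(region) {
  stopifnot(inherits(region, "mm_credible_region"))
  if (length(region$time) != 100)
    stop("credible areas are defined on the standard 100-point grid")
  sum(region$upper - region$lower)
}

#' Does a band contain a reference trajectory everywhere?
#'
#' @param region an `mm_credible_region`.
#' @param reference numeric series on the same grid.
#' @return `TRUE` if `lower <= reference <= upper` at every time point.
#' @export
region_contains <- function(region, reference) {
  stopifnot(length(reference) == length(region$time))
  all(region$lower <= reference & reference <= region$upper)
}

#' Posterior bands of ordinal class probabilities
#'
#' For a grid of normalized measurand values, computes per-category
#' envelopes (0.025 / 0.5 / 0.975 quantiles across posterior draws of the
#' ordinal measurement-model parameters).
#'
#' @param draws matrix of posterior draws with the slope in the first
#'   column and the offset distances after it (one ordinal block), or a
#'   list of [ordinal_params()].
#' @param x_grid normalized measurand values (default 101 points on [0, 1]).
#' @return List with `x`, and arrays `lower`, `median`, `upper` of
#'   dimension `length(x)` by `J`.
#' @export
ordinal_probability_bands <- function(draws, x_grid = seq(0, 1, length.out = 101)) {
  params_list <- if (is.matrix(draws)) {
    lapply(seq_len(nrow(draws)), function(i)
      ordinal_params(draws[i, 1], draws[i, -1]))
  } else draws
  J <- params_list[[1]]$n_categories
  cube <- vapply(params_list,
                 function(p) ordinal_category_probs(x_grid, p),
                 matrix(0, length(x_grid), J))
  list(
    x = x_grid,
    lower = apply(cube, c(1, 2), quantile, 0.025, type = 7),
    median = apply(cube, c(1, 2), median),
    upper = apply(cube, c(1, 2), quantile, 0.975, type = 7)
  )
}

#' 50%-probability decision boundary in a two-feature plane
#'
#' The locus where the logistic cell-fate model is indifferent,
#' `alpha * (intercept + sum_l w_l x_l) = 0`, restricted to a plane of two
#' plotting features with the remaining features held fixed.  For the
#' linear model this is the line
#' `x_j = -(intercept + offset + w_i x_i) / w_j`.
#'
#' @param params an [nominal_params()] object.
#' @param features indices (or names) of the two plotting features `(i, j)`.
#' @param fixed named values of the remaining features (default 0).
#' @return List with `slope` and `intercept` of `x_j` as a function of
#'   `x_i`; if `w_j = 0` but `w_i != 0`, a vertical line is returned as
#'   `x_i = at`; if both plotting weights are 0 there is no boundary and
#'   the function signals an error.
#' @export
decision_boundary <- function(params, features = c(1, 2), fixed = NULL) {
  stopifnot(inherits(params, "mm_nominal_params"), length(features) == 2)
  w <- params$weights
  if (is.character(features)) features <- match(features, names(w))
  wi <- w[features[1]]; wj <- w[features[2]]
  rest <- setdiff(seq_along(w), features)
  offset <- 0
  if (length(rest)) {
    vals <- setNames(numeric(length(rest)), names(w)[rest])
    if (!is.null(fixed)) vals[names(fixed)] <- fixed
    offset <- sum(w[rest] * vals)
  }
  if (wi == 0 && wj == 0)
    stop("no decision boundary: both plotting features have zero weight")
  if (wj == 0)
    return(list(vertical = TRUE, at = -(params$intercept + offset) / wi))
  list(vertical = FALSE,
       slope = -wi / wj,
       intercept = -(params$intercept + offset) / wj)
}

#' Posterior of effective feature weights
#'
#' The effective weight of a feature is the product of the shared slope and
#' its coefficient, `alpha * w_l` — invariant under the joint sign flip
#' `(alpha, w) -> (-alpha, -w)` that leaves every predicted probability
#' unchanged.  Features are ranked by the absolute value of their median
#' effective weight.
#'
#' @param draws matrix of posterior draws of a nominal block: columns
#'   `alpha`, `intercept`, then one column per feature weight.
#' @param feature_names optional names for the features.
#' @return An object of class `mm_weight_posterior`: list with the draw
#'   matrix `weights` (draws by features) and `ranking` (feature names,
#'   most predictive first).
#' @export
feature_weight_posterior <- function(draws, feature_names = NULL) {
  stopifnot(is.matrix(draws), ncol(draws) >= 3)
  W <- draws[, -(1:2), drop = FALSE] * draws[, 1]
  if (!is.null(feature_names)) colnames(W) <- feature_names
  if (is.null(colnames(W))) colnames(W) <- paste0("feature", seq_len(ncol(W)))
  med <- apply(W, 2, median)
  structure(list(weights = W,
                 median = med,
                 ranking = colnames(W)[order(-abs(med))]),
            class = "mm_weight_posterior")
}

#' @export
print.mm_weight_posterior <- function(x, ...) {
  cat("Effective feature-weight posterior (", nrow(x$weights), "draws )\n")
  for (nm in x$ranking)
    cat(sprintf("  %-20s median %8.3f\n", nm, x$median[nm]))
  invisible(x)
}

#' Posterior predictive sample of mean fractional cell death
#'
#' For each posterior draw of the Gaussian-process measurement-model
#' parameters (and mechanism parameters via pre-computed condition
#' features), conditions the zero-mean GP on the training data and returns
#' the posterior mean at each queried condition, clamped to [0, 1].
#'
#' @param gp_draws list of [gp_params()] (one per posterior draw), or a
#'   single `mm_gp_params` applied to every draw.
#' @param X_train,y_train training features and fractional values.
#' @param X_new per-condition feature matrix for the queried conditions
#'   (features must be registered columns of the training matrix).
#' @return Matrix draws by conditions of predicted mean fractions.
#' @export
predict_fractional_cell_death <- function(gp_draws, X_train, y_train, X_new) {
  if (inherits(gp_draws, "mm_gp_params")) gp_draws <- list(gp_draws)
  X_train <- as.matrix(X_train); X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(X_train))
    stop("queried conditions use features missing from the training registry")
  out <- t(vapply(gp_draws, function(p)
    gp_predict_mean(X_new, X_train, y_train, p, clamp = c(0, 1)),
    numeric(nrow(X_new))))
  out
}

#' 0.05 density contours of simulated feature populations
#'
#' Gaussian-kernel density estimate (Scott's-rule bandwidth) of a cloud of
#' two-feature points, returning the contour lines at the 0.05 density
#' level — the population-summary display used for cell-fate feature
#' planes.
#'
#' @param x,y feature coordinates of the simulated cells.
#' @param level density level (default 0.05).
#' @param n grid resolution.
#' @return List of contour paths (each with `x`, `y`), as from
#'   [grDevices::contourLines()].
#' @export
population_density_contours <- function(x, y, level = 0.05, n = 100) {
  if (!requireNamespace("MASS", quietly = TRUE))
    stop("population_density_contours requires the MASS package")
  scott <- function(v) 3.49 * sd(v) * length(v)^(-1 / 3)
  kd <- MASS::kde2d(x, y, h = c(scott(x), scott(y)) * 2, n = n)
  grDevices::contourLines(kd$x, kd$y, kd$z, levels = level)
}

#' Export a credible region as a tidy data frame
#'
#' @param x an `mm_credible_region`.
#' @param row.names,optional,... S3 compatibility (unused).
#' @return Data frame with columns `time`, `lower`, `median`, `upper`.
#' @export
as.data.frame.mm_credible_region <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(time = x$time, lower = x$lower, median = x$median,
             upper = x$upper)
}
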