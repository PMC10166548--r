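## Feature extraction from simulated dynamics: finite-difference derivatives,
## the three-feature representation used by the nominal cell-fate model, and
## the critical-points representation (with a bounded look-up table) used by
## the Gaussian-process model of fractional cell death.

## Fornberg's algorithm for finite-difference weights on an arbitrary
## stencil; C[, m + 1] are the weights for the m-th derivative at z.
fornberg_weights <- function(z, x, m) {
  n <- length(x)
  C <- matrix(0, n, m + 1)
  C[1, 1] <- 1
  c1 <- 1
  c4 <- x[1] - z
  for (i in 2:n) {
    mn <- min(i, m + 1)
    c2 <- 1
    c5 <- c4
    c4 <- x[i] - z
    for (j in 1:(i - 1)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1) {
        if (mn >= 2) for (k in mn:2)
          C[i, k] <- c1 * ((k - 1) * C[i - 1, k - 1] - c5 * C[i - 1, k]) / c2
        C[i, 1] <- -c1 * c5 * C[i - 1, 1] / c2
      }
      if (mn >= 2) for (k in mn:2)
        C[j, k] <- (c4 * C[j, k] - (k - 1) * C[j, k - 1]) / c3
      C[j, 1] <- c4 * C[j, 1] / c3
    }
    c1 <- c2
  }
  C
}

#' Finite-difference first and second derivatives
#'
#' Second-order approximation of the first derivative (central interior,
#' one-sided at the two boundary points) and fourth-order approximation of
#' the second derivative (5-point central interior, 6-point one-sided near
#' the boundaries; with exactly 5 points the full-grid stencil is used).
#'
#' @param values numeric series on a uniform grid (at least 5 points).
#' @param dt grid spacing (> 0).
#' @return List with elements `first` and `second`, each the same length as
#'   `values`.
#' @export
finite_diff_derivatives <- function(values, dt) {
  n <- length(values)
  if (n < 5) stop("need at least 5 points for the 4th-order stencil")
  stopifnot(dt > 0)
  f <- as.numeric(values)

  d1 <- numeric(n)
  d1[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * dt)
  d1[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * dt)
  d1[n] <- (f[n - 2] - 4 * f[n - 1] + 3 * f[n]) / (2 * dt)

  d2 <- numeric(n)
  if (n >= 6) {
    wL1 <- fornberg_weights(0, 0:5, 2)[, 3]
    wL2 <- fornberg_weights(1, 0:5, 2)[, 3]
    d2[1] <- sum(wL1 * f[1:6]) / dt^2
    d2[2] <- sum(wL2 * f[1:6]) / dt^2
    d2[n - 1] <- sum(rev(wL2) * f[(n - 5):n]) / dt^2
    d2[n] <- sum(rev(wL1) * f[(n - 5):n]) / dt^2
  } else {
    for (i in c(1, 2, n - 1, n))
      d2[i] <- sum(fornberg_weights(i - 1, 0:(n - 1), 2)[, 3] * f) / dt^2
  }
  if (n >= 5) {
    idx <- 3:(n - 2)
    d2[idx] <- (-f[idx - 2] + 16 * f[idx - 1] - 30 * f[idx] +
                  16 * f[idx + 1] - f[idx + 2]) / (12 * dt^2)
  }
  list(first = d1, second = d2)
}

## Derivative magnitudes below this (in normalized units) are treated as
## zero when detecting sign changes, to avoid float-noise critical points.
.deriv_tol <- 1e-10

#' Nominal-model features of a trajectory
#'
#' The three features of the logistic cell-fate model: the time at the
#' maximum rate of change of tBID (earliest time on ties), the natural log
#' of that maximum rate, and the concentration of a designated unrelated
#' non-apoptotic species at that time.
#'
#' @param traj an `mm_trajectory` containing the `tBID` observable.
#' @param unrelated observable name of the unrelated species (default
#'   `"USM2"`).
#' @return Named numeric vector `c(t_max_rate, log_max_rate,
#'   unrelated_signal)`.  A flat tBID trajectory (maximum rate below the
#'   detection threshold) signals an infeasible-parameter condition.
#' @export
extract_nominal_features <- function(traj, unrelated = "USM2") {
  y <- traj_values(traj, "tBID")
  dt <- traj$time[2] - traj$time[1]
  d1 <- finite_diff_derivatives(y, dt)$first
  i <- which.max(d1)                       # which.max takes the first maximum
  if (!is.finite(d1[i]) || d1[i] <= .deriv_tol)
    infeasible("flat tBID trajectory: log of maximum rate undefined")
  pk <- .refine_peak(d1, i)
  tstar <- traj$time[i] + pk$offset * dt
  c(t_max_rate = tstar,
    log_max_rate = log(pk$value),
    unrelated_signal = approx(traj$time, traj_values(traj, unrelated),
                              tstar, rule = 2)$y)
}

## Parabolic refinement of a discrete maximum: fit a parabola through the
## argmax and its neighbours so the peak location and height vary smoothly
## with the underlying parameters (a grid-quantized argmax makes population
## likelihoods piecewise constant, which stalls MCMC mixing).
.refine_peak <- function(d, i) {
  n <- length(d)
  if (i <= 1 || i >= n) return(list(offset = 0, value = d[i]))
  a <- d[i - 1]; b <- d[i]; c <- d[i + 1]
  denom <- a - 2 * b + c
  if (denom >= 0) return(list(offset = 0, value = b))
  x <- min(max(-(c - a) / (2 * denom), -0.5), 0.5)
  list(offset = x, value = b + (c - a) / 2 * x + denom / 2 * x^2)
}

## --- feature registry -------------------------------------------------------

#' Bounded append-only feature look-up table
#'
#' During a calibration, different parameter vectors yield different sets of
#' critical points.  To keep the meaning of each Gaussian-process weight
#' fixed, feature descriptors are assigned columns through an append-only
#' look-up table with a fixed capacity (default 10); re-encountered
#' descriptors reuse their column.
#'
#' @param capacity maximum number of registered features.
#' @return An object of class `mm_feature_registry` (environment-backed, so
#'   it updates in place).
#' @export
feature_registry <- function(capacity = 10) {
  stopifnot(capacity >= 1)
  e <- new.env(parent = emptyenv())
  e$names <- character(0)
  e$capacity <- as.integer(capacity)
  structure(e, class = "mm_feature_registry")
}

#' @export
print.mm_feature_registry <- function(x, ...) {
  cat("Feature registry (", length(x$names), "/", x$capacity, "):\n", sep = "")
  if (length(x$names)) cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Registered feature names, in registration order
#' @param registry an [feature_registry()] object.
#' @return Character vector of descriptors.
#' @export
registry_names <- function(registry) registry$names

register_feature <- function(registry, name) {
  i <- match(name, registry$names)
  if (!is.na(i)) return(i)
  if (length(registry$names) >= registry$capacity)
    stop("feature registry capacity (", registry$capacity, ") exceeded")
  registry$names <- c(registry$names, name)
  length(registry$names)
}

#' Serialize a feature registry to JSON
#' @param registry an [feature_registry()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(list(capacity = registry$capacity,
                            features = registry$names),
                       path, auto_unbox = TRUE)
  invisible(path)
}

## Interpolate the zero crossing of d between grid indices i and i+1.
.zero_cross <- function(t, d, i) {
  if (d[i] == d[i + 1]) return(t[i])
  t[i] - d[i] * (t[i + 1] - t[i]) / (d[i + 1] - d[i])
}

#' Critical-points representation of a trajectory
#'
#' Detects relative maxima and minima (sign changes of the first derivative)
#' and points of inflection (sign changes of the second derivative) of the
#' normalized tBID trajectory, excluding the boundary points.  For each
#' critical point the time and value (plus the truncation rate at
#' inflections) are recorded, together with the overall maximum Bid
#' truncation rate.  New feature descriptors are appended to `registry`;
#' re-extraction is idempotent.
#'
#' @param traj an `mm_trajectory`.
#' @param registry an [feature_registry()] (mutated in place).
#' @param quantity observable to analyze (default `"tBID"`, normalized by its
#'   own maximum).
#' @return An object of class `mm_critical_points`: list with `values`
#'   (named numeric over the registered descriptors present; absent ones 0),
#'   `exists` (named logical per critical-point kind) and the registry.
#' @export
extract_critical_points <- function(traj, registry, quantity = "tBID") {
  stopifnot(inherits(registry, "mm_feature_registry"))
  y <- traj_values(traj, quantity, normalize = TRUE)
  t <- traj$time
  dt <- t[2] - t[1]
  dd <- finite_diff_derivatives(y, dt)
  d1 <- dd$first; d2 <- dd$second
  s1 <- sign(d1) * (abs(d1) > .deriv_tol)
  s2 <- sign(d2) * (abs(d2) > .deriv_tol)

  vals <- c(); reg <- function(name, value) {
    register_feature(registry, name)
    vals[name] <<- value
  }
  n <- length(y)
  interior <- 2:(n - 2)                  # transitions between interior points
  n_max <- n_min <- n_infl <- 0L
  for (i in interior) {
    if (s1[i] > 0 && s1[i + 1] < 0) {
      n_max <- n_max + 1L
      tc <- .zero_cross(t, d1, i)
      reg(paste0("rmax", n_max, "_time"), tc)
      reg(paste0("rmax", n_max, "_value"), approx(t, y, tc)$y)
    }
    if (s1[i] < 0 && s1[i + 1] > 0) {
      n_min <- n_min + 1L
      tc <- .zero_cross(t, d1, i)
      reg(paste0("rmin", n_min, "_time"), tc)
      reg(paste0("rmin", n_min, "_value"), approx(t, y, tc)$y)
    }
    if (s2[i] != 0 && s2[i + 1] != 0 && s2[i] != s2[i + 1]) {
      n_infl <- n_infl + 1L
      tc <- .zero_cross(t, d2, i)
      reg(paste0("infl", n_infl, "_time"), tc)
      reg(paste0("infl", n_infl, "_value"), approx(t, y, tc)$y)
      reg(paste0("infl", n_infl, "_rate"), approx(t, d1, tc)$y)
    }
  }
  reg("max_rate", max(d1))
  structure(list(
    values = vals,
    exists = c(rel_max = n_max > 0, rel_min = n_min > 0, inflection = n_infl > 0),
    registry = registry
  ), class = "mm_critical_points")
}

#' Dense feature vector over a registry
#'
#' @param cp an `mm_critical_points` object (or named numeric vector).
#' @param registry the governing [feature_registry()].
#' @return Numeric vector over all registered descriptors, 0 where a feature
#'   is absent from this trajectory.
#' @export
feature_vector <- function(cp, registry) {
  vals <- if (inherits(cp, "mm_critical_points")) cp$values else cp
  out <- setNames(numeric(length(registry$names)), registry$names)
  present <- intersect(names(vals), registry$names)
  out[present] <- vals[present]
  out
}
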