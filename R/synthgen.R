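## Synthetic-data generation from ground-truth simulations: ordinal
## time courses (with adjacent-category misclassification), nominal
## cell-fate records from heterogeneous populations, half-max-time
## distributions, an emulated fluorescence dataset, and the
## effective-bit-resolution rule that fixes the ordinal category count.

#' Effective bit resolution of a noisy signal
#'
#' Standard effective-resolution derivation for a noisy analogue signal:
#' `SNR = 20 log10(range / (q_0.95 * rms))` with `q_0.95` the unit-normal
#' 0.95 quantile (1.6449), `EBR = (SNR - 1.76) / 6.02`, and the largest
#' usable ordinal category count `j_max = floor(0.7 * 2^EBR)`.  `rms` is the
#' root-mean-square of the noise component (the residual standard
#' deviation).
#'
#' @param signal_range max minus min of the signal (> 0).
#' @param noise_rms rms of the noise component (> 0).
#' @return An object of class `mm_resolution`: list with `snr_db`, `ebr`,
#'   `j_max`.
#' @export
effective_resolution <- function(signal_range, noise_rms) {
  if (!is.numeric(signal_range) || signal_range <= 0)
    stop("signal_range must be positive")
  if (!is.numeric(noise_rms) || noise_rms <= 0)
    stop("noise_rms must be positive")
  q95 <- qnorm(0.95)
  snr <- 20 * log10(signal_range / (q95 * noise_rms))
  ebr <- (snr - 1.76) / 6.02
  structure(list(snr_db = snr, ebr = ebr, j_max = floor(0.7 * 2^ebr)),
            class = "mm_resolution")
}

#' @export
print.mm_resolution <- function(x, ...) {
  cat(sprintf("SNR %.2f dB, EBR %.2f bits, largest usable J = %d\n",
              x$snr_db, x$ebr, x$j_max))
  invisible(x)
}

#' Ground-truth configuration for synthetic experiments
#'
#' Bundles everything the generators need: the reaction network with its
#' fixture ground-truth rate parameters, per-observable ordinal
#' measurement-model parameters, the nominal (cell-fate) measurement model
#' with its feature-normalization reference, the misclassification
#' probability, and the heterogeneity settings.  The ordinal fixtures place
#' category boundaries uniformly on the normalized measurand range: 5 tBID
#' categories (boundaries every 0.2) and 4 cPARP / IC-DISC categories
#' (boundaries every 0.25), with shared slope 50.  All fixture constants are
#' documented package choices, not published values.
#'
#' @param network the mechanism network (default [aearm_network()]).
#' @param cv extrinsic-heterogeneity coefficient of variation.
#' @return An object of class `mm_ground_truth`.
#' @export
ground_truth <- function(network = aearm_network(), cv = 0.20) {
  structure(list(
    network = network,
    cv = cv,
    ordinal = list(
      tBID    = ordinal_params(alpha = 50, theta = rep(0.2, 4)),
      cPARP   = ordinal_params(alpha = 50, theta = rep(0.25, 3)),
      IC_DISC = ordinal_params(alpha = 50, theta = rep(0.25, 3))
    ),
    misclass_p = 0.05,
    nominal = nominal_params(alpha = 3, intercept = 0.1,
                             weights = c(t_max_rate = -0.45,
                                         log_max_rate = 0.3,
                                         unrelated_signal = 0)),
    # standardization constants mapping raw features onto an approximately
    # unit scale (centres/scales frozen from the ground-truth heterogeneous
    # population; see the methods vignette).  Fixture weights are of a size
    # the Laplace(0, 0.1) weight priors plausibly support.
    feature_ref = list(t_center = 6600, t_scale = 1500,
                       log_rate_center = 1.7, log_rate_scale = 0.3,
                       unrelated_center = 3400, unrelated_scale = 700),
    gp = gp_params(sigma_f2 = 0.04,
                   beta = rep(1, 10), sigma_y = 0.05)
  ), class = "mm_ground_truth")
}

#' Sampling times of a synthetic time-course dataset
#'
#' Two counting conventions are supported: `"interval"` places measurements
#' at `k * interval` for `k = 1 .. floor(T/interval)` (matching
#' interval-based dataset sizes such as 112 points at 180 s or 336 at 60 s
#' over the 20160-s window), and `"inclusive"` additionally includes
#' `t = 0` (giving e.g. 14 points at 1500 s).
#'
#' @param interval_s sampling interval (s), at most the window length.
#' @param t_end window end (s).
#' @param counting `"interval"` or `"inclusive"`.
#' @return Numeric vector of times.
#' @export
sample_times <- function(interval_s, t_end = 20160,
                         counting = c("interval", "inclusive")) {
  counting <- match.arg(counting)
  stopifnot(interval_s > 0, interval_s <= t_end)
  k <- seq_len(floor(t_end / interval_s)) * interval_s
  if (counting == "inclusive") k <- c(0, k)
  k
}

#' Emulated fluorescence time-course dataset
#'
#' Simulates the ground-truth trajectory, normalizes each observable by its
#' own maximum, and adds i.i.d. Gaussian noise.  This emulates the
#' statistical structure of reporter-fluorescence time courses (sigmoidal
#' signal plus Gaussian noise); it is not a reconstruction of any published
#' dataset.
#'
#' @param truth an [ground_truth()] configuration.
#' @param observables observables to measure.
#' @param interval_s sampling interval (default 180 s: 112 measurements per
#'   observable under interval counting).
#' @param noise_sd Gaussian noise standard deviation (normalized units).
#' @param counting see [sample_times()].
#' @param seed integer seed.
#' @return Data frame with columns `time_s`, `observable`, `value`, `sd`.
#' @export
generate_fluorescence_dataset <- function(truth, observables = c("tBID", "cPARP"),
                                          interval_s = 180, noise_sd = 0.05,
                                          counting = "interval", seed = NULL) {
  stopifnot(inherits(truth, "mm_ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  times <- sample_times(interval_s, counting = counting)
  traj <- simulate_network(truth$network)
  do.call(rbind, lapply(observables, function(ob) {
    pred <- traj_values(traj, ob, times = times, normalize = TRUE)
    data.frame(time_s = times, observable = ob,
               value = pred + rnorm(length(times), 0, noise_sd),
               sd = noise_sd)
  }))
}

#' Synthetic ordinal time-course dataset
#'
#' Simulates the ground-truth trajectory, maps each observable's normalized
#' values to category probabilities through the fixture ordinal measurement
#' model, draws a category per time point, and corrupts the draw with the
#' adjacent-category misclassification model (5% total, 2.5% per interior
#' neighbour).
#'
#' @param truth an [ground_truth()] configuration.
#' @param observables observables to measure (must have ordinal fixtures).
#' @param interval_s sampling interval (default 60 s: 336 measurements per
#'   observable under interval counting).
#' @param counting see [sample_times()].
#' @param seed integer seed.
#' @param misclassify apply the reporting-error model (default `TRUE`).
#' @return Data frame with columns `time_s`, `observable`, `category`; the
#'   uncorrupted draws are attached as attribute `"true_category"`.
#' @export
generate_ordinal_dataset <- function(truth, observables = c("tBID", "cPARP"),
                                     interval_s = 60, counting = "interval",
                                     seed = NULL, misclassify = TRUE) {
  stopifnot(inherits(truth, "mm_ground_truth"),
            all(observables %in% names(truth$ordinal)))
  if (!is.null(seed)) set.seed(seed)
  times <- sample_times(interval_s, counting = counting)
  traj <- simulate_network(truth$network)
  out <- lapply(observables, function(ob) {
    params <- truth$ordinal[[ob]]
    if (params$n_categories < 2) stop("need at least 2 categories")
    x <- traj_values(traj, ob, times = times, normalize = TRUE)
    probs <- ordinal_category_probs(x, params)
    true_cat <- apply(probs, 1, function(p) sample.int(length(p), 1, prob = p)) - 1L
    cat <- true_cat
    if (misclassify) {
      err <- misclassification_matrix(params$n_categories, truth$misclass_p)
      cat <- vapply(true_cat, function(j)
        sample.int(ncol(err), 1, prob = err[j + 1L, ]) - 1L, integer(1))
    }
    list(df = data.frame(time_s = times, observable = ob, category = cat),
         true = true_cat)
  })
  df <- do.call(rbind, lapply(out, `[[`, "df"))
  attr(df, "true_category") <- unlist(lapply(out, `[[`, "true"))
  df
}

#' Normalize nominal-model features
#'
#' Maps raw features (time in s, natural-log maximum rate, unrelated-species
#' copy number) onto the normalized scale of the logistic cell-fate model
#' using the fixed reference constants of a ground-truth configuration.
#'
#' @param features named vector from [extract_nominal_features()], or a
#'   matrix with those three columns.
#' @param ref the `feature_ref` list of a [ground_truth()] configuration.
#' @return Vector or matrix of normalized features.
#' @export
normalize_nominal_features <- function(features, ref) {
  f <- if (is.matrix(features)) features else matrix(features, nrow = 1,
         dimnames = list(NULL, names(features)))
  out <- cbind(
    t_max_rate = (f[, "t_max_rate"] - ref$t_center) / ref$t_scale,
    log_max_rate = (f[, "log_max_rate"] - ref$log_rate_center) / ref$log_rate_scale,
    unrelated_signal = (f[, "unrelated_signal"] - ref$unrelated_center) / ref$unrelated_scale
  )
  if (is.matrix(features)) out else out[1, ]
}

#' Synthetic nominal (cell death vs survival) dataset
#'
#' Simulates heterogeneous populations at each TRAIL dose from ground-truth
#' parameters, extracts the three nominal-model features per cell, maps them
#' to death probabilities through the fixture logistic model, and draws
#' Bernoulli outcomes (no label noise).  Cells with flat tBID trajectories
#' are replaced by fresh initial-condition draws.
#'
#' @param truth an [ground_truth()] configuration.
#' @param doses_ng_ml TRAIL doses (default 10 and 50 ng/mL).
#' @param n_per_dose cells per dose (default 200: 400 observations total).
#' @param cv heterogeneity coefficient of variation.
#' @param seed integer seed.
#' @return Data frame with columns `cell_id`, `dose_ng_ml`, `outcome`
#'   (`"death"`/`"survival"`); normalized features and model probabilities
#'   are attached as attributes `"features"` and `"prob_death"`.
#' @export
generate_nominal_dataset <- function(truth, doses_ng_ml = c(10, 50),
                                     n_per_dose = 200, cv = truth$cv,
                                     seed = NULL) {
  stopifnot(inherits(truth, "mm_ground_truth"), all(doses_ng_ml > 0))
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); feats <- list(); probs <- list()
  for (dose in doses_ng_ml) {
    got <- 0; tries <- 0
    F <- matrix(NA_real_, n_per_dose, 3)
    while (got < n_per_dose) {
      tries <- tries + 1
      if (tries > 20 * n_per_dose) stop("too many infeasible cells")
      draw <- sample_initial_conditions(truth$network, 1, cv)
      f <- tryCatch({
        tr <- simulate_network(truth$network,
                               initial = c(draw[1, ],
                                           L = ligand_molecules(dose)))
        extract_nominal_features(tr)
      }, mmcal_infeasible = function(e) NULL)
      if (is.null(f)) next
      got <- got + 1
      F[got, ] <- normalize_nominal_features(f, truth$feature_ref)
    }
    colnames(F) <- c("t_max_rate", "log_max_rate", "unrelated_signal")
    p <- nominal_prob(F, truth$nominal)
    y <- rbinom(n_per_dose, 1, p)
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = paste0("d", dose, "_", seq_len(n_per_dose)),
      dose_ng_ml = dose,
      outcome = ifelse(y == 1, "death", "survival")
    )
    feats[[length(feats) + 1]] <- F
    probs[[length(probs) + 1]] <- p
  }
  df <- do.call(rbind, rows)
  attr(df, "features") <- do.call(rbind, feats)
  attr(df, "prob_death") <- unlist(probs)
  df
}

#' Synthetic half-maximal Bid-truncation times
#'
#' For each cell of heterogeneous populations at the given doses, the time
#' at which tBID first reaches half its maximum is computed by linear
#' interpolation and rounded to the nearest 3-minute (180-s) time point.
#' Cells that never reach half-max are excluded with a warning.
#'
#' @inheritParams generate_nominal_dataset
#' @return Data frame with columns `cell_id`, `dose_ng_ml`,
#'   `half_max_time_s` (integer multiples of 180 s).
#' @export
generate_half_max_times <- function(truth, doses_ng_ml = c(10, 50),
                                    n_per_dose = 200, cv = truth$cv,
                                    seed = NULL) {
  stopifnot(inherits(truth, "mm_ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); dropped <- 0
  for (dose in doses_ng_ml) {
    draws <- sample_initial_conditions(truth$network, n_per_dose, cv)
    for (i in seq_len(n_per_dose)) {
      tr <- tryCatch(
        simulate_network(truth$network,
                         initial = c(draws[i, ], L = ligand_molecules(dose))),
        mmcal_infeasible = function(e) NULL
      )
      tm <- if (is.null(tr)) NA_real_ else
        half_max_time(tr$time, traj_values(tr, "tBID"))
      if (is.na(tm)) { dropped <- dropped + 1; next }
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = paste0("d", dose, "_", i), dose_ng_ml = dose,
        half_max_time_s = round(tm / 180) * 180
      )
    }
  }
  if (dropped > 0)
    warning(dropped, " trajectories never reached half-max and were excluded")
  do.call(rbind, rows)
}

#' Time of first half-maximum crossing (linear interpolation)
#'
#' @param time time grid.
#' @param values series reaching its maximum within the grid.
#' @return Crossing time (s), or `NA` if the series never reaches half its
#'   maximum after the first point.
#' @export
half_max_time <- function(time, values) {
  target <- max(values) / 2
  if (max(values) <= 0) return(NA_real_)
  above <- which(values >= target)
  i <- above[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(time[1])
  t0 <- time[i - 1]; t1 <- time[i]
  y0 <- values[i - 1]; y1 <- values[i]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}

#' Write a tidy dataset to CSV
#'
#' @param data data frame from one of the generators.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}
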