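## Assembling a joint calibration: typed datasets, parameter-vector layout
## (free mechanism rates on log10 scale, then each dataset's measurement
## parameters), priors, and the composite log-posterior.

#' Typed calibration datasets
#'
#' Wrap a tidy data frame with its measurement-model configuration:
#' * `dataset_fluorescence(data)` — columns `time_s`, `observable`, `value`,
#'   `sd`; no free measurement parameters.
#' * `dataset_ordinal(data, n_categories, prior_variant, fixed)` — columns
#'   `time_s`, `observable`, `category`; free parameters are a shared slope
#'   and `J - 1` offset distances per observable unless `fixed` supplies an
#'   [ordinal_params()] per observable (pre-parameterized measurement
#'   model, no free parameters).
#' * `dataset_nominal(data, n_cells, fixed)` — columns `cell_id`,
#'   `dose_ng_ml`, `outcome`; free parameters are slope, intercept and three
#'   feature weights unless `fixed` is an [nominal_params()].  During
#'   likelihood evaluation a fixed per-dose sample of heterogeneous initial
#'   conditions (common random numbers, drawn once at problem build) is
#'   re-simulated under the proposed mechanism parameters.
#' * `dataset_fractional(data, features_fn, fixed)` — columns `condition`,
#'   `dose_ng_ml`, `fraction`, `sd`; a Gaussian-process measurement model
#'   over critical-point features.
#'
#' @param data tidy data frame (see above).
#' @param n_categories named integer vector, categories per observable.
#' @param prior_variant ordinal prior family (see [ordinal_priors()]).
#' @param fixed optional pre-set measurement-model parameters.
#' @param n_cells number of cells simulated per dose during each likelihood
#'   evaluation (defaults to the number of observations at that dose).
#' @param cv heterogeneity CV used for the common-random-number draws.
#' @param features_fn function(trajectory) returning the GP feature vector.
#' @param gp_sigma_f2_prior,gp_weight_prior priors for the GP amplitude and
#'   weights.
#' @return A classed dataset object consumed by [calibration_problem()].
#' @name datasets
NULL

#' @rdname datasets
#' @export
dataset_fluorescence <- function(data) {
  stopifnot(all(c("time_s", "observable", "value", "sd") %in% names(data)))
  structure(list(data = data, type = "fluorescence"), class = "mm_dataset")
}

#' @rdname datasets
#' @export
dataset_ordinal <- function(data, n_categories,
                            prior_variant = "exponential", fixed = NULL) {
  stopifnot(all(c("time_s", "observable", "category") %in% names(data)))
  obs <- unique(data$observable)
  stopifnot(all(obs %in% names(n_categories)))
  structure(list(data = data, type = "ordinal", observables = obs,
                 n_categories = n_categories, prior_variant = prior_variant,
                 fixed = fixed),
            class = "mm_dataset")
}

#' @rdname datasets
#' @export
dataset_nominal <- function(data, n_cells = NULL, cv = 0.20, fixed = NULL) {
  stopifnot(all(c("cell_id", "dose_ng_ml", "outcome") %in% names(data)))
  structure(list(data = data, type = "nominal", n_cells = n_cells, cv = cv,
                 fixed = fixed),
            class = "mm_dataset")
}

#' @rdname datasets
#' @export
dataset_fractional <- function(data, features_fn, fixed = NULL) {
  stopifnot(all(c("condition", "fraction") %in% names(data)))
  structure(list(data = data, type = "fractional", features_fn = features_fn,
                 fixed = fixed),
            class = "mm_dataset")
}

#' @export
print.mm_dataset <- function(x, ...) {
  cat("Calibration dataset (", x$type, "): ", nrow(x$data), " observations\n",
      sep = "")
  invisible(x)
}

#' Assemble a joint calibration problem
#'
#' Builds the parameter layout, prior specification and composite
#' log-posterior for a joint calibration of mechanism rate parameters
#' (log10 scale, lognormal-equivalent priors centred on `reference`) and
#' the measurement-model parameters of each dataset.  Simulation failures
#' and flat trajectories make the log-posterior `-Inf` (the proposal is
#' rejected); a calibration run never aborts on an infeasible vector.
#'
#' @param network the mechanism network.
#' @param datasets list of typed datasets (see [datasets]).
#' @param free_rates names of the rate constants to infer; the rest stay
#'   fixed at the network's values.
#' @param reference named vector of prior centres for the free rates
#'   (default: the network's current values).
#' @param rate_prior_sd prior scale on log10 rates (default 1.5).
#' @param feature_ref feature-normalization reference for nominal datasets
#'   (default from [ground_truth()]).
#' @param grid simulation grid.
#' @param ic_seed seed for the fixed heterogeneous initial-condition draws
#'   used by nominal datasets (common random numbers across likelihood
#'   evaluations).
#' @return An object of class `mm_problem` with elements `logpost`,
#'   `priors`, `par_names`, `dim`, `layout`, plus helpers used by the
#'   posterior-prediction machinery.
#' @export
calibration_problem <- function(network, datasets, free_rates,
                                reference = NULL, rate_prior_sd = 1.5,
                                feature_ref = ground_truth()$feature_ref,
                                grid = sim_grid(), ic_seed = 1L) {
  stopifnot(inherits(network, "mm_network"), length(datasets) >= 1)
  if (!all(vapply(datasets, inherits, TRUE, "mm_dataset")))
    stop("datasets must be built with the dataset_* constructors")
  stopifnot(all(free_rates %in% names(network$parameters)))
  if (is.null(reference)) reference <- network$parameters[free_rates]
  stopifnot(all(free_rates %in% names(reference)))

  par_names <- paste0("log10_", free_rates)
  priors <- unname(mechanism_priors(reference[free_rates], rate_prior_sd))
  n_mech <- length(free_rates)
  layout <- list(mechanism = seq_len(n_mech))

  ## measurement-parameter blocks per dataset
  blocks <- list()
  pos <- n_mech
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    if (ds$type == "ordinal" && is.null(ds$fixed)) {
      for (ob in ds$observables) {
        J <- ds$n_categories[[ob]]
        idx <- pos + seq_len(J)
        blocks[[paste0("ordinal", di, ".", ob)]] <- idx
        par_names <- c(par_names, paste0("ord.", ob, ".alpha"),
                       paste0("ord.", ob, ".theta", seq_len(J - 1)))
        priors <- c(priors, ordinal_priors(J, ds$prior_variant))
        pos <- pos + J
      }
    } else if (ds$type == "nominal" && is.null(ds$fixed)) {
      idx <- pos + seq_len(5)
      blocks[[paste0("nominal", di)]] <- idx
      par_names <- c(par_names, "nom.alpha", "nom.intercept",
                     "nom.w.t_max_rate", "nom.w.log_max_rate",
                     "nom.w.unrelated")
      priors <- c(priors, nominal_priors(3))
      pos <- pos + 5
    } else if (ds$type == "fractional" && is.null(ds$fixed)) {
      stop("joint GP-parameter inference requires 'fixed' GP weights here; ",
           "free GP blocks are built by the fractional workflow")
    }
  }
  stopifnot(length(priors) == pos, length(par_names) == pos)

  ## fixed common-random-number IC draws for nominal datasets
  ic_draws <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    if (ds$type != "nominal") next
    per_dose <- split(ds$data, ds$data$dose_ng_ml)
    set.seed(ic_seed + di)
    ic_draws[[di]] <- lapply(per_dose, function(sub) {
      n <- ds$n_cells %||% nrow(sub)
      sample_initial_conditions(network, n, ds$cv)
    })
  }

  needs_traj <- any(vapply(datasets, function(d)
    d$type %in% c("fluorescence", "ordinal"), TRUE))

  loglik_one <- function(ds, di, rates, traj) {
    if (ds$type == "fluorescence") {
      ll <- 0
      for (ob in unique(ds$data$observable)) {
        sub <- ds$data[ds$data$observable == ob, ]
        pred <- traj_values(traj, ob, times = sub$time_s, normalize = TRUE)
        ll <- ll + fluorescence_loglik(pred, sub$value, sub$sd)
      }
      return(ll)
    }
    if (ds$type == "ordinal") {
      ll <- 0
      for (ob in ds$observables) {
        sub <- ds$data[ds$data$observable == ob, ]
        params <- if (!is.null(ds$fixed)) ds$fixed[[ob]] else {
          th <- get("theta_cache", envir = ds_env)[[paste0(di, ".", ob)]]
          th
        }
        x <- traj_values(traj, ob, times = sub$time_s, normalize = TRUE)
        err <- misclassification_matrix(params$n_categories)
        ll <- ll + ordinal_loglik(x, sub$category, params, err)
      }
      return(ll)
    }
    if (ds$type == "nominal") {
      params <- if (!is.null(ds$fixed)) ds$fixed else
        get("theta_cache", envir = ds_env)[[paste0("nom", di)]]
      ll <- 0
      per_dose <- split(ds$data, ds$data$dose_ng_ml)
      for (dn in names(per_dose)) {
        sub <- per_dose[[dn]]
        draws <- ic_draws[[di]][[dn]]
        n <- nrow(draws)
        raw <- population_nominal_features(network, draws,
                                           dose_ng_ml = as.numeric(dn),
                                           parameters = rates, grid = grid)
        F <- normalize_nominal_features(raw, feature_ref)
        ## every observation is used; when fewer cells are simulated than
        ## observed (reduced scale), simulated cells are recycled -- the
        ## outcome-to-cell pairing is arbitrary since the inference
        ## re-simulates its own heterogeneous sample
        y <- outcome_to_binary(sub$outcome)
        idx <- rep_len(seq_len(n), length(y))
        ll <- ll + nominal_loglik(F[idx, , drop = FALSE], y, params)
      }
      return(ll)
    }
    if (ds$type == "fractional") {
      feats <- t(vapply(seq_len(nrow(ds$data)), function(i)
        ds$features_fn(ds$data[i, ], rates), numeric(length(ds$fixed$beta))))
      return(gp_log_marginal(feats, ds$data$fraction, ds$fixed))
    }
    stop("dataset has no configured measurement model")
  }

  ## scratch env holding the measurement params decoded from the current x
  ds_env <- new.env(parent = emptyenv())

  decode <- function(x) {
    cache <- list()
    for (nm in names(blocks)) {
      idx <- blocks[[nm]]
      if (startsWith(nm, "ordinal")) {
        key <- sub("^ordinal", "", nm)
        v <- x[idx]
        if (any(v[-1] <= 0) || v[1] < 0) return(NULL)
        cache[[key]] <- ordinal_params(v[1], v[-1])
      } else if (startsWith(nm, "nominal")) {
        v <- x[idx]
        cache[[paste0("nom", sub("^nominal", "", nm))]] <-
          nominal_params(v[1], v[2], v[3:5])
      }
    }
    cache
  }

  logpost <- function(x) {
    lp <- log_prior(x, priors)
    if (lp == -Inf) return(-Inf)
    cache <- decode(x)
    if (is.null(cache)) return(-Inf)
    assign("theta_cache", cache, envir = ds_env)
    rates <- setNames(10^x[layout$mechanism], free_rates)
    with_infeasible_as_neg_inf({
      traj <- if (needs_traj) simulate_network(network, parameters = rates,
                                               grid = grid) else NULL
      lls <- vapply(seq_along(datasets), function(di)
        loglik_one(datasets[[di]], di, rates, traj), numeric(1))
      lp + composite_loglik(lls)
    })
  }

  structure(list(
    network = network, datasets = datasets, free_rates = free_rates,
    priors = priors, par_names = par_names, dim = pos,
    layout = c(layout, blocks), grid = grid, feature_ref = feature_ref,
    logpost = logpost,
    decode_rates = function(x) setNames(10^x[seq_len(n_mech)], free_rates)
  ), class = "mm_problem")
}

#' @export
print.mm_problem <- function(x, ...) {
  cat("Calibration problem:", x$dim, "free parameters (",
      length(x$free_rates), "mechanism +", x$dim - length(x$free_rates),
      "measurement ) over", length(x$datasets), "dataset(s)\n")
  invisible(x)
}

#' Posterior-predictive simulator for an observable
#'
#' Returns a function mapping a sampled parameter vector to the normalized
#' trajectory of `observable` on the problem's grid — the quantity whose
#' pointwise quantiles form the posterior-predictive credible region.
#'
#' @param problem an `mm_problem`.
#' @param observable observable name (default `"tBID"`).
#' @return `function(x)` returning a numeric series (or `NULL` for
#'   infeasible vectors).
#' @export
predict_observable_fn <- function(problem, observable = "tBID") {
  force(problem); force(observable)
  function(x) {
    rates <- problem$decode_rates(x)
    tryCatch({
      traj <- simulate_network(problem$network, parameters = rates,
                               grid = problem$grid)
      traj_values(traj, observable, normalize = TRUE)
    }, mmcal_infeasible = function(e) NULL)
  }
}
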