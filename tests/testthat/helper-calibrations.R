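# Shared reduced-scale calibrations, computed once per test run and reused
# across test blocks (they are the expensive part of the suite).  Problem
# sizes follow the methods vignette's reduced-scale section; the snooker
# update is enabled for these runs (it is off in the package default).

.mm_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .mm_cache))
    assign(name, force(expr), envir = .mm_cache)
  get(name, envir = .mm_cache)
}

run_reduced_calibration <- function(datasets, free_rates, sampler_seed,
                                    max_steps, burn_in = 1500,
                                    region_draws = 200) {
  prob <- calibration_problem(default_truth$network, datasets,
                              free_rates = free_rates, ic_seed = 5)
  cfg <- sampler_config(burn_in = burn_in, max_steps = max_steps,
                        seed = sampler_seed, check_interval = 500,
                        snooker_prob = 0.1)
  ch <- run_until_converged(prob, cfg)
  reg <- credible_region(ch, predict_observable_fn(prob, "tBID"),
                         n_draws = region_draws, seed = sampler_seed)
  list(problem = prob, chains = ch, region = reg,
       area = credible_area(reg))
}

# the ordinal dataset-size contrast frees the three rates upstream of tBID;
# the synergy runs (which include the weakly informative nominal data) free
# two, keeping their posteriors tractable at desk scale
.rates_size <- c("kc0", "kf1", "kc2")
.rates_synergy <- c("kc0", "kc2")

calib_dense_ordinal <- function() cached("dense", {
  d <- generate_ordinal_dataset(default_truth, "tBID", 300, seed = 31)
  run_reduced_calibration(list(dataset_ordinal(d, c(tBID = 5L))),
                          .rates_size, sampler_seed = 201,
                          max_steps = 40000, burn_in = 3000)
})

calib_sparse_ordinal <- function() cached("sparse", {
  d <- generate_ordinal_dataset(default_truth, "tBID", 5040, seed = 31)
  run_reduced_calibration(list(dataset_ordinal(d, c(tBID = 5L))),
                          .rates_size, sampler_seed = 202,
                          max_steps = 15000)
})

calib_disc_ordinal <- function() cached("disc", {
  d <- generate_ordinal_dataset(default_truth, "IC_DISC", 300, seed = 32)
  run_reduced_calibration(list(dataset_ordinal(d, c(IC_DISC = 4L))),
                          .rates_synergy, sampler_seed = 203,
                          max_steps = 15000)
})

# small nominal dataset for the synergy contrast (one simulated cell per
# observation, no recycling) versus the full 400-observation dataset with a
# recycled 16-cell sample for the feature-selection recovery
nominal_data_small <- function() cached("nominal_data_small",
  generate_nominal_dataset(default_truth, n_per_dose = 16, seed = 22))

nominal_data_full <- function() cached("nominal_data_full",
  generate_nominal_dataset(default_truth, seed = 21))

calib_nominal <- function() cached("nominal", {
  run_reduced_calibration(
    list(dataset_nominal(nominal_data_small(), n_cells = 16, cv = 0.20)),
    .rates_synergy, sampler_seed = 204, max_steps = 8000)
})

calib_combined <- function() cached("combined", {
  d <- generate_ordinal_dataset(default_truth, "IC_DISC", 300, seed = 32)
  run_reduced_calibration(
    list(dataset_nominal(nominal_data_small(), n_cells = 16, cv = 0.20),
         dataset_ordinal(d, c(IC_DISC = 4L))),
    .rates_synergy, sampler_seed = 205, max_steps = 8000)
})

calib_nominal_rank <- function() cached("nominal_rank", {
  run_reduced_calibration(
    list(dataset_nominal(nominal_data_full(), n_cells = 16, cv = 0.20)),
    .rates_synergy, sampler_seed = 207, max_steps = 10000)
})

calib_uniform_prior_ordinal <- function() cached("uniform_prior", {
  d <- generate_ordinal_dataset(default_truth, "tBID", 300, seed = 33)
  run_reduced_calibration(
    list(dataset_ordinal(d, c(tBID = 5L), prior_variant = "uniform")),
    .rates_size, sampler_seed = 206, max_steps = 20000, burn_in = 3000)
})
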