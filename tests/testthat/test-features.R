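test_that("finite differences are exact on low-order polynomials", {
  t <- seq(0, 1, length.out = 20); dt <- t[2] - t[1]
  d <- finite_diff_derivatives(3 + 2 * t, dt)
  expect_equal(d$first, rep(2, 20), tolerance = 1e-10)
  expect_equal(d$second, rep(0, 20), tolerance = 1e-8)
  # the 4th-order second derivative is exact on a cubic
  d3 <- finite_diff_derivatives(t^3, dt)
  expect_equal(d3$second, 6 * t, tolerance = 1e-9)
  expect_error(finite_diff_derivatives(1:4, 0.1), "at least 5")
})

test_that("finite differences converge at the stated orders on sin(t)", {
  t <- seq(0, 2, by = 0.01)
  d <- finite_diff_derivatives(sin(t), 0.01)
  interior <- 4:(length(t) - 3)
  err1 <- max(abs(d$first[interior] - cos(t)[interior]))
  err2 <- max(abs(d$second[interior] + sin(t)[interior]))
  expect_lt(err1, 5 * 0.01^2)
  expect_lt(err2, 5 * 0.01^4)
  # Richardson check: halving dt cuts the interior first-derivative error ~4x
  th <- seq(0, 2, by = 0.005)
  dh <- finite_diff_derivatives(sin(th), 0.005)
  interior_h <- 4:(length(th) - 3)
  err1h <- max(abs(dh$first[interior_h] - cos(th)[interior_h]))
  expect_gt(err1 / err1h, 3.3); expect_lt(err1 / err1h, 4.7)
})

test_that("nominal features recover the analytics of a logistic pulse", {
  # logistic tBID A/(1 + exp(-k (t - tau))): inflection at tau, max slope Ak/4
  grid <- sim_grid()
  A <- 4e4; k <- 1 / 600; tau <- 9000
  y <- A / (1 + exp(-k * (grid - tau)))
  traj <- structure(list(
    time = grid,
    values = cbind(tBid = y, USM2a = rep(1234, 100)),
    observables = cbind(tBID = y, USM2 = rep(1234, 100))
  ), class = "mm_trajectory")
  f <- extract_nominal_features(traj)
  dt <- grid[2] - grid[1]
  expect_lt(abs(f[["t_max_rate"]] - tau), dt)
  expect_equal(f[["log_max_rate"]], log(A * k / 4), tolerance = 0.01)
  expect_equal(f[["unrelated_signal"]], 1234)
})

test_that("flat trajectories are flagged infeasible during feature extraction", {
  grid <- sim_grid()
  flat <- structure(list(
    time = grid,
    values = cbind(tBid = rep(0, 100), USM2a = rep(1, 100)),
    observables = cbind(tBID = rep(0, 100), USM2 = rep(1, 100))
  ), class = "mm_trajectory")
  expect_error(extract_nominal_features(flat), class = "mmcal_infeasible")
})

test_that("tie-breaking on the maximum rate takes the earliest time", {
  grid <- sim_grid(0, 99, 100)
  y <- c(seq(0, 50, length.out = 51), seq(51, 99, length.out = 49))
  traj <- structure(list(
    time = grid, values = cbind(tBid = y, USM2a = rep(1, 100)),
    observables = cbind(tBID = y, USM2 = rep(1, 100))
  ), class = "mm_trajectory")
  f <- extract_nominal_features(traj)
  # the whole ramp has the same slope: the first interior maximum wins
  expect_lte(f[["t_max_rate"]], grid[3])
})

test_that("critical-point extraction matches sign-change enumeration", {
  grid <- sim_grid(0, 1, 100)
  reg <- feature_registry()
  # strictly monotone line: no interior extrema, no inflection
  lin <- structure(list(
    time = grid, values = cbind(tBid = grid, X = grid),
    observables = cbind(tBID = grid)
  ), class = "mm_trajectory")
  cp <- extract_critical_points(lin, reg)
  expect_false(any(cp$exists[c("rel_max", "rel_min")]))
  expect_false(cp$exists[["inflection"]])
  # sigmoid: exactly one inflection, no interior extrema
  sig <- 1 / (1 + exp(-12 * (grid - 0.5)))
  straj <- structure(list(
    time = grid, values = cbind(tBid = sig),
    observables = cbind(tBID = sig)
  ), class = "mm_trajectory")
  reg2 <- feature_registry()
  cp2 <- extract_critical_points(straj, reg2)
  expect_true(cp2$exists[["inflection"]])
  expect_false(cp2$exists[["rel_max"]])
  expect_equal(cp2$values[["infl1_time"]], 0.5, tolerance = 0.02)
  # a sine has interior extrema and inflections
  wav <- 0.5 + 0.4 * sin(2 * pi * grid)
  wtraj <- structure(list(
    time = grid, values = cbind(tBid = wav),
    observables = cbind(tBID = wav)
  ), class = "mm_trajectory")
  reg3 <- feature_registry()
  cp3 <- extract_critical_points(wtraj, reg3)
  expect_true(cp3$exists[["rel_max"]]); expect_true(cp3$exists[["rel_min"]])
  expect_equal(cp3$values[["rmax1_time"]], 0.25, tolerance = 0.02)
})

test_that("the feature registry is append-only, deduplicating and bounded", {
  grid <- sim_grid(0, 1, 100)
  sig <- 1 / (1 + exp(-12 * (grid - 0.5)))
  traj <- structure(list(
    time = grid, values = cbind(tBid = sig), observables = cbind(tBID = sig)
  ), class = "mm_trajectory")
  reg <- feature_registry()
  cp1 <- extract_critical_points(traj, reg)
  names1 <- registry_names(reg)
  cp2 <- extract_critical_points(traj, reg)      # idempotent re-extraction
  expect_identical(registry_names(reg), names1)
  expect_identical(cp1$values, cp2$values)
  # deterministic: identical trajectories give identical feature vectors
  expect_identical(feature_vector(cp1, reg), feature_vector(cp2, reg))
  # overflow beyond capacity errors
  tiny <- feature_registry(capacity = 2)
  expect_error(extract_critical_points(traj, tiny), "capacity")
  # registry serializes to JSON
  path <- tempfile(fileext = ".json")
  write_registry(reg, path)
  expect_identical(unlist(jsonlite::read_json(path)$features), names1)
})

test_that("feature vectors report absent features as zero over the registry", {
  reg <- feature_registry()
  register_names <- c("rmax1_time", "max_rate")
  for (nm in register_names) mmcal:::register_feature(reg, nm)
  fv <- feature_vector(c(max_rate = 0.4), reg)
  expect_equal(unname(fv), c(0, 0.4))
  expect_named(fv, register_names)
})
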