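test_that("credible regions collapse on degenerate posteriors", {
  grid <- sim_grid()
  draws <- matrix(rep(c(0.3, 0.7), each = 50), 50, 2)  # identical draws
  fn <- function(x) x[1] + x[2] * sin(grid / 3000)
  reg <- credible_region(draws, fn, grid = grid)
  expect_equal(reg$lower, reg$upper)
  expect_equal(reg$median, fn(c(0.3, 0.7)))
  expect_equal(credible_area(reg), 0)
})

test_that("pointwise band quantiles match a sort-based oracle", {
  grid <- sim_grid()
  set.seed(88)
  draws <- matrix(rnorm(50 * 2), 50, 2)
  fn <- function(x) x[1] + x[2] * grid / 20160
  reg <- credible_region(draws, fn, grid = grid)
  sims <- t(apply(draws, 1, fn))
  for (tix in c(1, 50, 100)) {
    v <- sort(sims[, tix])
    expect_equal(reg$lower[tix], unname(quantile(v, 0.025, type = 7)))
    expect_equal(reg$upper[tix], unname(quantile(v, 0.975, type = 7)))
    expect_equal(reg$median[tix], median(v))
  }
  expect_true(all(reg$lower <= reg$median & reg$median <= reg$upper))
})

test_that("about 95% of an independent Gaussian draw falls inside the band", {
  grid <- sim_grid()
  set.seed(77)
  draws <- matrix(rnorm(2000), 1000, 2)
  fn <- function(x) x[1] + x[2] * cos(grid / 5000)
  reg <- credible_region(draws, fn, grid = grid)
  inside <- replicate(200, {
    y <- fn(rnorm(2))
    mean(y >= reg$lower & y <= reg$upper)
  })
  expect_gt(mean(inside), 0.90); expect_lt(mean(inside), 0.99)
})

test_that("the credible-area metric sums band widths on the standard grid", {
  grid <- sim_grid()
  reg <- structure(list(time = grid, lower = rep(0.1, 100),
                        median = rep(0.3, 100), upper = rep(0.35, 100),
                        n_draws = 1),
                   class = "mm_credible_region")
  expect_equal(credible_area(reg), 100 * 0.25)
  # element-wise loop oracle on random envelopes
  set.seed(5)
  lo <- runif(100); hi <- lo + runif(100)
  reg2 <- structure(list(time = grid, lower = lo, median = (lo + hi) / 2,
                         upper = hi, n_draws = 1),
                    class = "mm_credible_region")
  acc <- 0; for (i in 1:100) acc <- acc + hi[i] - lo[i]
  expect_equal(credible_area(reg2), acc)
  # off-grid regions are rejected
  bad <- structure(list(time = 1:50, lower = 1:50, median = 1:50,
                        upper = 1:50, n_draws = 1),
                   class = "mm_credible_region")
  expect_error(credible_area(bad), "100-point")
})

test_that("credible area shrinks when the posterior sample tightens", {
  grid <- sim_grid()
  set.seed(41)
  wide <- matrix(rnorm(600, sd = 1), 300, 2)
  tight <- wide / 4
  fn <- function(x) x[1] + x[2] * grid / 20160
  a_wide <- credible_area(credible_region(wide, fn, grid = grid))
  a_tight <- credible_area(credible_region(tight, fn, grid = grid))
  expect_lt(a_tight, a_wide)
})

test_that("ordinal probability bands bracket the generating model", {
  truth_params <- default_truth$ordinal$tBID
  set.seed(3)
  draws <- cbind(
    alpha = truth_params$alpha * exp(rnorm(150, 0, 0.1)),
    t(replicate(150, truth_params$theta * exp(rnorm(4, 0, 0.1))))
  )
  # ensure the exact truth is one of the sampled parameterizations
  draws[1, ] <- c(truth_params$alpha, truth_params$theta)
  bands <- ordinal_probability_bands(draws)
  expect_true(all(bands$lower >= 0 & bands$upper <= 1))
  expect_equal(rowSums(bands$median), rep(1, length(bands$x)), tolerance = 0.05)
  truth_curves <- ordinal_category_probs(bands$x, truth_params)
  expect_true(all(truth_curves >= bands$lower - 1e-9 &
                    truth_curves <= bands$upper + 1e-9))
  # degenerate posterior collapses onto the single model's curves
  point <- ordinal_probability_bands(list(truth_params, truth_params))
  expect_equal(point$lower, truth_curves, tolerance = 1e-12)
  expect_equal(point$upper, truth_curves, tolerance = 1e-12)
})

test_that("decision boundaries sit exactly at 50% probability", {
  p <- nominal_params(alpha = 2, intercept = 0, weights = c(1, -1, 0))
  b <- decision_boundary(p, c(1, 2))
  expect_false(b$vertical)
  expect_equal(b$slope, 1); expect_equal(b$intercept, 0)  # the diagonal
  # boundary points evaluate to probability 0.5
  for (x1 in c(-1, 0, 2)) {
    x2 <- b$intercept + b$slope * x1
    expect_equal(nominal_prob(c(x1, x2, 5), p), 0.5, tolerance = 1e-9)
  }
  # a zero plotting weight makes the boundary independent of that feature
  pz <- nominal_params(2, 0.4, weights = c(0.8, 0, 0))
  bz <- decision_boundary(pz, c(1, 2))
  expect_true(bz$vertical)
  expect_equal(bz$at, -0.5)
  expect_error(decision_boundary(nominal_params(1, 0, c(0, 0, 1)), c(1, 2)),
               "zero weight")
  # held-fixed features shift the boundary through their weighted sum
  p3 <- nominal_params(1, 0.1, weights = c(1, -2, 0.5))
  b3 <- decision_boundary(p3, c(1, 2), fixed = c(feature3 = 0.4))
  x1 <- 0.3; x2 <- b3$intercept + b3$slope * x1
  expect_equal(nominal_prob(c(x1, x2, 0.4), p3), 0.5, tolerance = 1e-9)
})

test_that("effective weights are invariant under the joint sign flip", {
  set.seed(9)
  draws <- cbind(rnorm(50, 2, 0.1), rnorm(50), rnorm(50, -0.4, 0.05),
                 rnorm(50, 0.2, 0.05), rnorm(50, 0, 0.02))
  flipped <- draws
  flipped[, 1] <- -flipped[, 1]
  flipped[, 3:5] <- -flipped[, 3:5]
  w1 <- feature_weight_posterior(draws)
  w2 <- feature_weight_posterior(flipped)
  expect_equal(w1$weights, w2$weights)
  # the flip also leaves the predicted probabilities unchanged
  x <- c(0.3, -0.2, 1)
  p1 <- nominal_prob(x, nominal_params(draws[1, 1], draws[1, 2], draws[1, 3:5]))
  p2 <- nominal_prob(x, nominal_params(-draws[1, 1], -draws[1, 2], -draws[1, 3:5]))
  expect_equal(p1, p2)
  expect_equal(w1$ranking[1], names(which.max(abs(w1$median))))
})

test_that("fractional cell death predictions follow GP conditioning", {
  gp <- gp_params(0.09, beta = c(1, 1), sigma_y = 1e-3)
  set.seed(23)
  X <- matrix(runif(10), 5, 2)
  y <- runif(5, 0.1, 0.9)
  # querying a training condition with vanishing noise returns the value
  pred <- predict_fractional_cell_death(gp, X, y, X[2, , drop = FALSE])
  expect_equal(pred[1, 1], y[2], tolerance = 1e-2)
  # n = 3 dense conditioning oracle
  Xt <- X[1:3, ]; yt <- y[1:3]
  xq <- matrix(c(0.5, 0.5), 1)
  K <- outer(1:3, 1:3, Vectorize(function(i, j)
    rbf_ard_kernel(Xt[i, ], Xt[j, ], gp)))
  oracle <- drop(vapply(1:3, function(i)
    rbf_ard_kernel(xq[1, ], Xt[i, ], gp), 1) %*%
      solve(K + diag(1e-6, 3), yt))
  expect_equal(predict_fractional_cell_death(gp, Xt, yt, xq)[1, 1],
               min(max(oracle, 0), 1), tolerance = 1e-6)
  # predictions are clamped into [0, 1]
  yb <- c(5, -3, 4, 6, -2)
  predb <- predict_fractional_cell_death(gp, X, yb, X)
  expect_true(all(predb >= 0 & predb <= 1))
  expect_error(predict_fractional_cell_death(gp, X, y, matrix(1, 1, 3)),
               "registry")
})

test_that("density contours return closed 0.05-level paths", {
  set.seed(31)
  cl <- population_density_contours(rnorm(400), rnorm(400), level = 0.05)
  expect_gt(length(cl), 0)
  expect_true(all(vapply(cl, function(p) p$level == 0.05, TRUE)))
})
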