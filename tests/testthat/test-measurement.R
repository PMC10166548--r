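test_that("fluorescence log-likelihood matches its definition", {
  expect_equal(fluorescence_loglik(c(1, 2, 3), c(1, 2, 3), 0.1), 0)
  expect_equal(fluorescence_loglik(0.6, 0.5, 0.1), -0.5)
  # 20-point toy equals an element-wise loop
  set.seed(4)
  pred <- runif(20); obs <- runif(20); sig <- runif(20, 0.05, 0.3)
  loop <- 0
  for (i in 1:20) loop <- loop - (pred[i] - obs[i])^2 / (2 * sig[i]^2)
  expect_equal(fluorescence_loglik(pred, obs, sig), loop)
  expect_error(fluorescence_loglik(1, 1, 0), "positive")
})

test_that("ordinal category probabilities form a simplex with ordered boundaries", {
  set.seed(11)
  for (rep in 1:25) {
    J <- sample(2:6, 1)
    p <- ordinal_params(alpha = runif(1, 0, 80), theta = runif(J - 1, 0.01, 0.5))
    x <- runif(7, -0.5, 1.5)
    probs <- ordinal_category_probs(x, p)
    expect_true(all(probs >= 0 & probs <= 1))
    expect_equal(rowSums(probs), rep(1, 7))
    # cumulative probabilities nonincreasing in category index
    cum <- t(apply(probs, 1, function(r) rev(cumsum(rev(r)))))
    expect_true(all(diff(t(cum)) <= 1e-12))
  }
})

test_that("a zero slope makes category probabilities independent of the measurand", {
  p <- ordinal_params(alpha = 0, theta = c(0.2, 0.3))
  probs <- ordinal_category_probs(c(-5, 0, 0.7, 10), p)
  expect_true(all(abs(sweep(probs, 2, probs[1, ])) < 1e-12))
})

test_that("uniform category boundaries put 50% cumulative probability at each 0.2 step", {
  p <- ordinal_params(alpha = 50, theta = rep(0.2, 4))
  for (j in 1:4) {
    x <- j * 0.2
    probs <- ordinal_category_probs(x, p)
    # P(y >= c_j | x = j * 0.2) = 0.5 at the j-th boundary
    expect_equal(sum(probs[1, (j + 1):5]), 0.5, tolerance = 1e-12)
  }
})

test_that("the default misclassification matrix has the exact 95%/2.5% structure", {
  for (J in c(2, 4, 5)) {
    M <- misclassification_matrix(J)
    expect_equal(rowSums(M), rep(1, J))
    expect_true(all(diag(M) == 0.95))
    if (J > 2) {
      expect_equal(M[2, 1], 0.025); expect_equal(M[2, 3], 0.025)
    }
    expect_equal(M[1, 2], 0.05)
    expect_equal(M[J, J - 1], 0.05)
    # non-adjacent entries are zero
    expect_true(all(M[abs(row(M) - col(M)) > 1] == 0))
  }
})

test_that("ordinal log-likelihood marginalizes over the error model", {
  p <- ordinal_params(alpha = 30, theta = c(0.25, 0.25, 0.25))
  x <- c(0.1, 0.4, 0.9)
  cats <- c(0L, 1L, 3L)
  # identity error: equals the sum of log category probabilities
  probs <- ordinal_category_probs(x, p)
  expect_equal(ordinal_loglik(x, cats, p, error = diag(4)),
               sum(log(probs[cbind(1:3, cats + 1)])))
  # explicit enumeration over true categories under the default error model
  err <- misclassification_matrix(4)
  brute <- 0
  for (i in 1:3) {
    marg <- 0
    for (j in 1:4) marg <- marg + err[j, cats[i] + 1] * probs[i, j]
    brute <- brute + log(marg)
  }
  expect_equal(ordinal_loglik(x, cats, p), unname(brute))
  expect_error(ordinal_loglik(x, c(0L, 1L, 4L), p), "categories")
})

test_that("adjacent reported categories never have zero probability under default error", {
  p <- ordinal_params(alpha = 80, theta = rep(0.2, 4))
  # at x = 0 the modal category is 0; reporting category 1 stays finite
  expect_gt(ordinal_loglik(0, 1L, p), -Inf)
})

test_that("the logistic cell-fate model behaves like a logistic regression", {
  p0 <- nominal_params(alpha = 1, intercept = 0, weights = c(0, 0, 0))
  expect_equal(nominal_prob(c(1, 2, 3), p0), 0.5)
  # strictly increasing in a feature with positive alpha * weight
  p1 <- nominal_params(alpha = 2, intercept = 0.1, weights = c(0.5, -0.2, 0))
  xs <- seq(-2, 2, length.out = 9)
  probs <- vapply(xs, function(v) nominal_prob(c(v, 0.3, 7), p1), 1)
  expect_true(all(diff(probs) > 0))
  # random parameterizations match the direct linear-predictor formula
  set.seed(21)
  for (rep in 1:20) {
    pars <- nominal_params(rnorm(1), rnorm(1), rnorm(3))
    x <- rnorm(3)
    eta <- pars$alpha * (pars$intercept + sum(pars$weights * x))
    expect_equal(nominal_prob(x, pars), 1 / (1 + exp(-eta)))
  }
  expect_error(nominal_prob(c(1, 2), p1), "feature count")
})

test_that("nominal log-likelihood is the Bernoulli sum over observations", {
  p0 <- nominal_params(1, 0, c(0, 0, 0))
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(nominal_loglik(X, rep("death", 10), p0), 10 * log(0.5))
  p1 <- nominal_params(2, 0.5, c(0.4, 0, 0))
  x1 <- matrix(c(0.7, 0, 0), 1)
  expect_equal(nominal_loglik(x1, "death", p1), log(nominal_prob(x1[1, ], p1)))
  # 50-record toy equals a per-record loop
  set.seed(33)
  X <- matrix(rnorm(150), 50, 3)
  y <- sample(c("death", "survival"), 50, replace = TRUE)
  loop <- 0
  for (i in 1:50) {
    pi <- nominal_prob(X[i, ], p1)
    loop <- loop + if (y[i] == "death") log(pi) else log(1 - pi)
  }
  expect_equal(nominal_loglik(X, y, p1), loop)
  expect_error(nominal_loglik(X, rep("dead", 50), p1), "outcomes")
})

test_that("the ARD kernel is a symmetric decreasing radial-basis function", {
  gp <- gp_params(sigma_f2 = 0.3, beta = c(1, 2, 0.5))
  x <- c(0.1, -0.4, 2)
  expect_equal(rbf_ard_kernel(x, x, gp), 0.3)
  set.seed(5)
  for (rep in 1:10) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(rbf_ard_kernel(a, b, gp), rbf_ard_kernel(b, a, gp))
  }
  # strictly decreasing in the scaled distance
  ds <- seq(0, 3, length.out = 10)
  ks <- vapply(ds, function(d) rbf_ard_kernel(c(0, 0, 0), c(d, 0, 0), gp), 1)
  expect_true(all(diff(ks) < 0))
  expect_error(gp_params(0.3, beta = c(1, 0, 1)), "zero")
})

test_that("GP log marginal likelihood matches closed forms and a dense oracle", {
  gp <- gp_params(sigma_f2 = 0.25, beta = c(1.5, 0.8), sigma_y = 0.1)
  # n = 1 scalar closed form
  y1 <- 0.37
  expect_equal(gp_log_marginal(matrix(c(0.2, 0.4), 1), y1, gp),
               -0.5 * y1^2 / (0.25 + 0.01) - 0.5 * log(0.25 + 0.01) -
                 0.5 * log(2 * pi))
  # n = 3 dense multivariate-normal oracle
  X <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.3, 0.8), 3, 2)
  y <- c(0.9, 0.5, 0.2)
  K <- outer(1:3, 1:3, Vectorize(function(i, j)
    rbf_ard_kernel(X[i, ], X[j, ], gp)))
  S <- K + diag(0.1^2, 3)
  expect_equal(gp_log_marginal(X, y, gp), mvn_logpdf_oracle(y, S),
               tolerance = 1e-8)
  # amplitude -> 0 limit reduces to independent Gaussian noise
  gp0 <- gp_params(sigma_f2 = 1e-12, beta = c(1.5, 0.8), sigma_y = 0.1)
  iid <- sum(dnorm(y, 0, 0.1, log = TRUE))
  expect_equal(gp_log_marginal(X, y, gp0), iid, tolerance = 1e-6)
})

test_that("GP marginal likelihood is invariant to permuting observations", {
  gp <- gp_params(0.2, beta = c(1, 1), sigma_y = 0.05)
  set.seed(8)
  X <- matrix(runif(10), 5, 2); y <- runif(5)
  perm <- sample(5)
  expect_equal(gp_log_marginal(X, y, gp),
               gp_log_marginal(X[perm, ], y[perm], gp))
})

test_that("GP predictions interpolate training data as noise vanishes", {
  gp <- gp_params(0.2, beta = c(1, 1), sigma_y = 1e-3)  # floor noise
  set.seed(19)
  X <- matrix(runif(8), 4, 2); y <- runif(4, 0.2, 0.8)
  mu <- gp_predict_mean(X, X, y, gp)
  expect_equal(unname(mu), y, tolerance = 1e-3)
  # n = 3 closed-form conditioning oracle at a new point
  Xt <- X[1:3, ]; yt <- y[1:3]
  xq <- matrix(c(0.45, 0.55), 1)
  K <- outer(1:3, 1:3, Vectorize(function(i, j)
    rbf_ard_kernel(Xt[i, ], Xt[j, ], gp)))
  kq <- vapply(1:3, function(i) rbf_ard_kernel(xq[1, ], Xt[i, ], gp), 1)
  oracle <- drop(kq %*% solve(K + diag(1e-6, 3), yt))
  expect_equal(unname(gp_predict_mean(xq, Xt, yt, gp, clamp = NULL)), oracle,
               tolerance = 1e-6)
})

test_that("the composite likelihood is an order-free sum that absorbs -Inf", {
  lls <- c(-12.5, -3.1, -0.4)
  expect_equal(composite_loglik(lls), sum(lls))
  expect_equal(composite_loglik(rev(lls)), composite_loglik(lls))
  expect_equal(composite_loglik(lls[1]), lls[1])
  expect_identical(composite_loglik(c(lls, -Inf)), -Inf)
  expect_error(composite_loglik(numeric(0)), "no dataset")
  # two-dataset toy equals the manual sum of separately computed values
  p <- ordinal_params(30, c(0.3, 0.3))
  ll1 <- ordinal_loglik(c(0.2, 0.8), c(0L, 2L), p)
  ll2 <- fluorescence_loglik(c(0.4, 0.6), c(0.35, 0.66), 0.1)
  expect_equal(composite_loglik(list(ll1, ll2)), ll1 + ll2)
})
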