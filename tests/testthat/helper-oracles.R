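# Independent oracles used across the test files.

# Closed-form solution of the unimolecular chain A -> B -> C with distinct
# rates (Bateman equations); the analytic reference for the ODE integrator.
chain_analytic <- function(a0, k1, k2, times) {
  A <- a0 * exp(-k1 * times)
  B <- a0 * k1 / (k2 - k1) * (exp(-k1 * times) - exp(-k2 * times))
  C <- a0 - A - B
  cbind(A = A, B = B, C = C)
}

chain_network <- function(a0 = 1000, k1 = 2e-3, k2 = 5e-4) {
  reaction_network(
    species = c("A", "B", "C"),
    reactions = list(
      list(reactants = "A", products = "B", rate = "k1"),
      list(reactants = "B", products = "C", rate = "k2")
    ),
    parameters = c(k1 = k1, k2 = k2),
    initial = c(A = a0)
  )
}

# Dense multivariate-normal log-density (mean zero) via solve()/det(),
# independent of the Cholesky path used by the implementation.
mvn_logpdf_oracle <- function(y, S) {
  n <- length(y)
  -0.5 * drop(t(y) %*% solve(S, y)) - 0.5 * log(det(S)) - n / 2 * log(2 * pi)
}

# Textbook potential-scale-reduction factor for a (iterations x chains)
# matrix, written as the formula reads.
psrf_oracle <- function(ch) {
  n <- nrow(ch)
  W <- mean(apply(ch, 2, var))
  B_over_n <- var(colMeans(ch))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

default_truth <- ground_truth()
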