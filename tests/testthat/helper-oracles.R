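# Independent oracles used across the suite.

# Error function, independent of the package's pnorm-based version.
oracle_erf <- function(x) {
  vapply(x, function(z)
    2 / sqrt(pi) * stats::integrate(function(u) exp(-u^2), 0, z,
                                    rel.tol = 1e-12)$value, 0)
}

# Analytic first-order Sobol indices of the Ishigami function with
# a = 7, b = 0.1 on [-pi, pi]^3.
ishigami_analytic <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V <- V1 + V2 + 8 * b^2 * pi^8 / 225
  c(V1 / V, V2 / V, 0)
}

ishigami_fn <- function(X, a = 7, b = 0.1)
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])

# Direct Sobol pick-freeze (Saltelli) estimator of first-order indices
# on unit-cube inputs: an estimator family entirely different from the
# Fourier route.
sobol_pick_freeze <- function(fn, n_params, n = 20000, seed = 99) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n_params), n)
  B <- matrix(stats::runif(n * n_params), n)
  yA <- fn(A)
  yB <- fn(B)
  V <- stats::var(c(yA, yB))
  f0 <- mean(c(yA, yB))
  vapply(seq_len(n_params), function(i) {
    ABi <- B
    ABi[, i] <- A[, i]
    yABi <- fn(ABi)
    mean(yA * yABi - f0^2) / V   # Sobol 1993 / Saltelli estimator
  }, 0)
}

table5_menus <- function() fixture_menus()

scenario_menu1_lunch <- function() meal_scenario(3.2, 9.1, "menu1-lunch")
scenario_menu2_lunch <- function() meal_scenario(49.8, 9.5, "menu2-lunch")

# random-but-reproducible positive state for property loops
random_state <- function(seed) {
  set.seed(seed)
  st <- initial_state(meal_scenario(stats::runif(1, 0, 50),
                                    stats::runif(1, 0, 25)))
  st * stats::runif(length(st), 0.2, 3)
}
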