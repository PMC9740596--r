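test_that("search-curve designs satisfy their geometric invariants", {
  d <- fast_design(78, 2000, seed = 1)
  expect_identical(dim(d$x), c(2000L, 78L))
  expect_true(all(d$x >= 0 & d$x <= 1))
  expect_length(unique(d$omega), 78)
  expect_true(all(d$omega == round(d$omega)))
  expect_true(all(d$omega >= 5 & d$omega <= 159))
  expect_lt(d$max_corr, 1e-2)          # hard bound
  expect_lte(d$max_corr, 3e-3)         # acceptance: the order-1e-3 level
  expect_identical(length(d$s), 2000L)
  expect_equal(diff(d$s)[1], 0.001, tolerance = 1e-12)
})

test_that("designs are reproducible from their seed", {
  d1 <- fast_design(20, 1000, seed = 42)
  d2 <- fast_design(20, 1000, seed = 42)
  expect_identical(d1$omega, d2$omega)
  expect_identical(d1$phi, d2$phi)
  expect_identical(d1$x, d2$x)
})

test_that("a single-parameter curve sweeps the full unit interval", {
  d <- fast_design(1, 2000, seed = 5)
  expect_lt(min(d$x), 0.01)
  expect_gt(max(d$x), 0.99)
  expect_error(fast_design(10, 500, freq_range = c(5, 9), seed = 1),
               "too narrow")
})

test_that("parameter scaling is log-uniform around nominal", {
  d <- fast_design(3, 500, seed = 2)
  nom <- c(a = 2, b = 10, c = 0.5)
  pm <- scale_parameters(d, nom, span_decades = 2)
  expect_identical(colnames(pm), names(nom))
  # endpoints and midpoint of the convention
  x <- d$x[1, 1]
  expect_equal(unname(pm[1, 1]), 2 * 10^(2 * (x - 0.5)), tolerance = 1e-12)
  expect_true(all(pm >= rep(nom / 10, each = 500) - 1e-9))
  expect_true(all(pm <= rep(10 * nom, each = 500) + 1e-9))
  # symmetry of x about 1/2 makes the geometric mean the nominal value
  gm <- exp(colMeans(log(pm)))
  expect_equal(unname(gm), unname(nom), tolerance = 0.05)
  expect_error(scale_parameters(d, c(a = -1, b = 1, c = 1)), "positive")
})

test_that("benchmark indices match analytic values and an independent estimator", {
  d <- fast_design(3, 2000, seed = 1, omega = c(84, 109, 143))
  X <- -pi + 2 * pi * d$x
  y <- ishigami_fn(X)
  S <- fast_indices(y, d)$S[, 1]
  truth <- ishigami_analytic()
  expect_lt(max(abs(S - truth)), 0.02)
  # cross-estimator agreement: Sobol pick-freeze on the same function
  pf <- sobol_pick_freeze(function(U) ishigami_fn(-pi + 2 * pi * U), 3)
  expect_lt(max(abs(S - pf)), 0.05)
})

test_that("linear, constant and single-frequency outputs decompose exactly", {
  d <- fast_design(2, 2000, seed = 4, omega = c(101, 127))
  S <- fast_indices(d$x[, 1] + 2 * d$x[, 2], d)$S[, 1]
  expect_lt(max(abs(S - c(0.2, 0.8))), 0.02)
  expect_identical(max(fast_indices(rep(3.3, 2000), d)$S), 0)
  d3 <- fast_design(3, 2000, seed = 3, omega = c(84, 109, 143))
  y1 <- sin(pi * d3$omega[1] * d3$s + d3$phi[1])
  S1 <- fast_indices(y1, d3)$S[, 1]
  expect_gte(S1[1], 0.99)
  expect_lte(max(S1[-1]), 0.01)
})

test_that("index sums respect the variance budget up to aliasing", {
  d <- fast_design(5, 2000, seed = 6)
  y <- cbind(d$x %*% runif(5), sin(2 * pi * d$x[, 1]) * d$x[, 2])
  fi <- fast_indices(y, d)
  expect_true(all(fi$sum_S <= 1 + 0.05))
  expect_true(all(fi$S >= 0))
  expect_error(fast_indices(rep(1, 100), d), "segment")
  expect_error(fast_indices(c(NA, rep(1, 1999)), d), "finite")
})

# reduced-sample mechanics scans: a 200-segment grid cannot host the full
# frequency band, so these use an explicit consecutive-odd frequency set
# (design quality is tested separately at full scale)
small_design <- function(seed)
  fast_design(78, 200, seed = seed, omega = seq(5, 159, 2), accept_corr = 1)

test_that("a zero-span model scan yields all-zero indices", {
  sc <- meal_scenario(3.2, 9.1)
  r <- fast_sensitivity(sc, t_points = c(10, 50), design = small_design(2),
                        span_decades = 0, seed = 2)
  expect_identical(max(r$indices[["t10"]]$metabolites), 0)
  expect_identical(max(r$indices[["t50"]]$reactions), 0)
  expect_identical(r$n_failed, 0L)
})

test_that("small model scans are seed-reproducible end to end", {
  sc <- meal_scenario(3.2, 9.1)
  r1 <- fast_sensitivity(sc, t_points = 50, design = small_design(7), seed = 7)
  r2 <- fast_sensitivity(sc, t_points = 50, design = small_design(7), seed = 7)
  expect_identical(r1$indices, r2$indices)
  expect_identical(dim(r1$indices[[1]]$metabolites), c(78L, 23L))
  expect_identical(dim(r1$indices[[1]]$reactions), c(78L, 45L))
})

test_that("sensitivity exports write the heatmap-ordered CSVs and sidecar", {
  sc <- meal_scenario(3.2, 9.1)
  r <- fast_sensitivity(sc, t_points = c(10, 50), design = small_design(3),
                        seed = 3)
  dir <- withr::local_tempdir()
  files <- export_fast_result(r, dir, prefix = "chk")
  expect_length(files, 5)   # 2 horizons x 2 families + sidecar
  m <- utils::read.csv(file.path(dir, "chk_metabolites_t010.csv"),
                       row.names = 1)
  expect_identical(rownames(m), fast_parameter_names())
  expect_identical(ncol(m), 23L)
  side <- jsonlite::read_json(file.path(dir, "chk_design.json"))
  expect_identical(side$seed, 3L)
  expect_length(side$omega, 78)
})
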