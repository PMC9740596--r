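test_that("the parameter set has the published structure and values", {
  p <- default_parameters()
  expect_length(p, 81)
  info <- parameter_info()
  expect_identical(nrow(info), 81L)
  expect_identical(sum(info$varied), 78L)
  expect_setequal(info$name[!info$varied], c("alpha_A", "alpha_L", "alpha_M"))
  expect_setequal(fast_parameter_names(), info$name[info$varied])

  expect_identical(p[["beta_L"]], 12)
  expect_identical(p[["k_11"]], 48)
  expect_identical(p[["beta_M"]], 82.5)
  expect_identical(p[["k_dl"]], 3.5e8)       # corrected typo
  expect_identical(p[["k_d"]], 1.733e14)     # printed-as-is
  expect_identical(p[["alpha_L"]], 1.6)
  expect_true(all(p > 0))
})

test_that("overrides replace values and reject unknown names", {
  p <- default_parameters(overrides = c(k_11 = 24, beta_L = 6))
  expect_identical(p[["k_11"]], 24)
  expect_identical(p[["beta_L"]], 6)
  expect_identical(p[["k_22"]], 48)
  expect_error(default_parameters(overrides = c(nonsense = 1)), "unknown")
})

test_that("YAML serialization round-trips bit-exactly", {
  p <- default_parameters(overrides = c(k_9 = 43.583000000000007))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_identical(as.numeric(q), as.numeric(p))
  expect_identical(names(q), names(p))
})

test_that("state defaults match the published starting concentrations", {
  si <- state_info()
  expect_identical(nrow(si), 23L)
  expect_true(all(nzchar(si$unit)))
  def <- stats::setNames(si$default, si$name)
  expect_identical(def[["I"]], 60)
  expect_identical(def[["Y_L"]], 50)
  expect_identical(def[["T_A"]], 500)
  expect_identical(def[["P"]], 0)
  expect_identical(def[["T_CB"]], 0)
  expect_true(all(is.na(def[c("G_B", "T_LB")])))
})

test_that("initial_state applies the scenario and validates it", {
  st <- initial_state(meal_scenario(3.2, 9.1))
  expect_identical(st[["G_B"]], 3.2)
  expect_identical(st[["T_LB"]], 9.1)
  expect_identical(st[["I"]], 60)
  expect_identical(st[["Y_L"]], 50)
  st0 <- initial_state(meal_scenario(0, 0))
  expect_identical(st0[["G_B"]], 0)
  expect_identical(st0[["T_LB"]], 0)
  expect_identical(st0[["T_A"]], 500)
  expect_error(meal_scenario(-1, 5), "non-negative")
  expect_error(initial_state(list(G_B0 = 1)), "T_LB0")
})
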