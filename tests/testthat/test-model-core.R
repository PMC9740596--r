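p_nom <- default_parameters()

test_that("insulin secretion term matches an independent erf oracle", {
  st <- initial_state(meal_scenario(3.2, 9.1))
  expected <- 48 + 48 * oracle_erf((3.2 - 7) / 2.5)   # ~1.517
  v <- reaction_rates(st, p_nom)
  expect_equal(v[["v1"]], expected, tolerance = 1e-10)
  expect_equal(evaluate_rhs(st, p_nom)[["I"]],
               expected - p_nom[["k_d"]] * 60, tolerance = 1e-10)
})

test_that("glycogen saturation factor halves synthesis at the cap", {
  st <- initial_state(meal_scenario(3.2, 9.1))
  st[["Y_L"]] <- p_nom[["l_max"]]
  # at Y_L = l_max the (1 + tanh(.)) factor equals 1 (half its maximum 2):
  # recompute the glycogen balance directly with that factor pinned
  gsyn <- 0.5 * p_nom[["k_yl"]] * st[["I"]] * st[["P_L"]] * 1
  gly <- p_nom[["beta_L"]] / (1 + p_nom[["k_dl"]] * st[["I"]]) *
    st[["Y_L"]] / (st[["Y_L"]] + p_nom[["y_0"]])
  expect_equal(evaluate_rhs(st, p_nom)[["Y_L"]],
               (gsyn - gly) / p_nom[["alpha_L"]], tolerance = 1e-12)
})

test_that("plasma NEFA balance vanishes when its rate constants are zero", {
  p0 <- default_parameters(overrides = c(k_bm = 0, k_bl = 0, k_na = 0,
                                         beta_f = 0, k_a = 0))
  st <- initial_state(meal_scenario(3.2, 9.1))
  expect_identical(evaluate_rhs(st, p0)[["A_B"]], 0)
})

test_that("named reaction rates match scalar oracles", {
  st <- initial_state(meal_scenario(3.2, 9.1))
  st[["T_L"]] <- 40
  v <- reaction_rates(st, p_nom)
  expect_equal(v[["v19"]], 0.1 * 40 / (0.625 + 40), tolerance = 1e-12)
  st0 <- st; st0[["I"]] <- 0
  v0 <- reaction_rates(st0, p_nom)
  expect_identical(v0[["v2"]], 0)                 # k_d * I at I = 0
  expect_equal(v0[["v37"]], 0.117, tolerance = 1e-12)
  expect_equal(v[["v4"]], p_nom[["k_gl"]] * st[["G_L"]], tolerance = 1e-12)
})

test_that("registry structure: 45 reactions, full attribution, factor 3 on TAG->FFA", {
  reg <- reaction_registry()
  ids <- unique(reg$id)
  expect_length(ids, 45)
  expect_setequal(ids, paste0("v", 1:45))
  # every (reaction, state) attribution is unique
  expect_false(anyDuplicated(reg[c("id", "state")]) > 0)
  # each TAG -> 3 FFA conversion carries the stoichiometric factor 3 on
  # its FFA side
  tag_ffa <- c(v16 = "A_L", v18 = "A_L", v19 = "A_L", v32 = "A_M",
               v34 = "A_M", v37 = "A_B", v39 = "A_A", v44 = "A_A",
               v45 = "A_B")
  for (id in names(tag_ffa)) {
    row <- reg[reg$id == id & reg$state == tag_ffa[[id]], ]
    expect_identical(row$coef, 3, info = id)
  }
})

test_that("signed registry fluxes reproduce the balances for random states", {
  for (seed in 1:25) {
    st <- random_state(seed)
    d1 <- evaluate_rhs(st, p_nom)
    d2 <- flux_closure(st, p_nom)
    expect_equal(d2, d1, tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("the right-hand side is deterministic and rejects non-finite input", {
  st <- random_state(7)
  expect_identical(evaluate_rhs(st, p_nom), evaluate_rhs(st, p_nom))
  st[["G_B"]] <- NaN
  expect_error(evaluate_rhs(st, p_nom), "G_B")
  expect_error(reaction_rates(st, p_nom), "G_B")
})

test_that("the unit audit reports the printed dimensional inconsistencies", {
  audit <- unit_audit()
  expect_gt(nrow(audit), 4)
  expect_true(any(grepl("mu_b", audit$issue)))
  expect_true(any(grepl("k_dl", audit$issue) | grepl("k_p6", audit$issue)))
})
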