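p_nom <- default_parameters()
sc <- meal_scenario(3.2, 9.1, "menu1-lunch")

test_that("degenerate grids and parameter sets behave trivially", {
  st <- initial_state(sc)
  tr0 <- integrate_model(p_nom, st, times = 0)
  expect_identical(as.numeric(tr0$state[1, ]), as.numeric(st))
  # all rates zero (volumes kept) -> constant trajectory
  info <- parameter_info()
  zero <- stats::setNames(rep(0, 78), info$name[info$varied])
  pz <- default_parameters(overrides = zero)
  trz <- integrate_model(pz, st, times = seq(0, 100, 20))
  for (i in seq_len(nrow(trz$state)))
    expect_equal(as.numeric(trz$state[i, ]), as.numeric(st),
                 tolerance = 1e-10)
})

test_that("an isolated linear insulin subsystem matches its closed form", {
  # with k_22 = 0 the insulin balance decouples: dI/dt = k_11 - k_d * I
  a <- 2; k <- 0.05
  pl <- default_parameters(overrides = c(k_22 = 0, k_11 = a, k_d = k))
  st <- initial_state(sc)
  tt <- seq(0, 200, 10)
  tr <- integrate_model(pl, st, times = tt)
  closed <- a / k + (st[["I"]] - a / k) * exp(-k * tt)
  expect_equal(as.numeric(tr$state[, "I"]), closed, tolerance = 1e-6)
})

test_that("compiled and reference R right-hand sides integrate identically", {
  tt <- seq(0, 100, 25)
  trC <- integrate_model(p_nom, initial_state(sc), times = tt)
  trR <- integrate_model(p_nom, initial_state(sc), times = tt, engine = "R")
  for (v in colnames(trC$state))
    expect_equal(trC$state[, v], trR$state[, v], tolerance = 1e-6, info = v)
})

test_that("two distinct stiff methods agree at 500 min within 0.5%", {
  tt <- c(0, 100, 250, 500)
  a <- integrate_model(p_nom, initial_state(sc), times = tt, method = "lsoda")
  b <- integrate_model(p_nom, initial_state(sc), times = tt, method = "radau")
  xa <- a$state[length(tt), ]; xb <- b$state[length(tt), ]
  rel <- abs(xa - xb) / pmax(abs(xa), 1e-8)
  expect_lt(max(rel), 0.005)
})

test_that("tightening tolerances tenfold leaves reported values unchanged to 0.1%", {
  tt <- c(0, 10, 100, 500)
  a <- integrate_model(p_nom, initial_state(sc), times = tt)
  b <- integrate_model(p_nom, initial_state(sc), times = tt,
                       rtol = 1e-9, atol = 1e-11)
  rel <- abs(a$state - b$state) / pmax(abs(b$state), 1e-8)
  expect_lt(max(rel), 1e-3)
})

test_that("with export and usage switched off, plasma glucose is conserved", {
  pc <- default_parameters(overrides = c(
    k_gl = 0, k_gl2 = 0, k_gm = 0, k_gm2 = 0, d_ba = 0, mu_1 = 0))
  tr <- integrate_model(pc, initial_state(sc), times = seq(0, 500, 100))
  expect_equal(tr$state[, "G_B"], rep(3.2, 6), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("meal scenario batch runs are tagged, table-faithful and deterministic", {
  menus <- table5_menus()
  trs <- run_meal_scenarios(menus, horizon = 50, dt = 10)
  expect_length(trs, 16)
  grid <- reference_scenarios()
  for (nm in names(trs)) {
    s <- trs[[nm]]$scenario
    ref <- grid[paste0("menu", grid$menu, "-", grid$meal) == nm, ]
    expect_identical(round_half_up(s$G_B0), ref$G_B0, info = nm)
    expect_identical(trs[[nm]]$state[1, "G_B"][[1]], s$G_B0)
  }
  trs2 <- run_meal_scenarios(menus, horizon = 50, dt = 10)
  expect_identical(trs[["menu1-lunch"]]$state, trs2[["menu1-lunch"]]$state)
})

test_that("observables interpolate states and recompute registry rates", {
  tr <- integrate_model(p_nom, initial_state(sc), times = seq(0, 500, 5))
  ob0 <- observables_at(tr, 0)
  expect_equal(ob0$metabolites, initial_state(sc), tolerance = 1e-12,
               ignore_attr = TRUE)
  ob <- observables_at(tr, 102.5)
  st <- ob$metabolites
  expect_equal(ob$reactions[["v19"]],
               p_nom[["v_10"]] * st[["T_L"]] / (p_nom[["k_10"]] + st[["T_L"]]),
               tolerance = 1e-12)
  expect_length(ob$reactions, 45)
  expect_error(observables_at(tr, 501), "span")
})

test_that("a blowing-up solution is reported, not silently clipped", {
  # absurd dephosphorylation rate + a non-adaptive method: overflow
  pb <- default_parameters(overrides = c(k_61 = 1e12, k_p = 1e12))
  expect_error(
    integrate_model(pb, initial_state(sc), times = seq(0, 500, 20),
                    method = "euler"),
    "non-finite|solver failed")
})
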