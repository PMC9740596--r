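test_that("generated menus respect the configured energy and fraction bands", {
  for (seed in 1:20) {
    g <- generate_menu(menu_generator_config(seed = seed))
    expect_length(g$meals, 4)
    expect_gte(g$totals$energy_kcal, 1900)
    expect_lte(g$totals$energy_kcal, 2100)
    fc <- 4 * g$totals$carbohydrate_g / g$totals$energy_kcal
    ff <- 9 * g$totals$fat_g / g$totals$energy_kcal
    expect_gte(fc, 0.05); expect_lte(fc, 0.60)
    expect_gte(ff, 0.20); expect_lte(ff, 0.80)
    expect_lte(fc + ff, 0.95 + 1e-9)
  }
})

test_that("generation is seed-reproducible and supports degenerate splits", {
  a <- generate_menu(menu_generator_config(seed = 11))
  b <- generate_menu(menu_generator_config(seed = 11))
  expect_identical(a$totals, b$totals)
  one <- generate_menu(menu_generator_config(
    energy_kcal = 1800, energy_tol = 0, meal_weights = c(1, 0, 0, 0),
    seed = 4))
  expect_equal(one$meals[[1]]$energy_kcal, 1800, tolerance = 1e-9)
  expect_equal(one$meals[[2]]$energy_kcal, 0, tolerance = 1e-12)
  expect_error(menu_generator_config(carb_range = c(0.5, 0.6),
                                     fat_range = c(0.5, 0.8)),
               "infeasible")
})

test_that("generated carbohydrate fractions cover both dietary regimes", {
  fracs <- vapply(1:200, function(s) {
    g <- generate_menu(menu_generator_config(seed = s))
    4 * g$totals$carbohydrate_g / g$totals$energy_kcal
  }, 0)
  expect_lt(min(fracs), 0.07)
  expect_gt(max(fracs), 0.55)
})

test_that("every generated menu converts to valid non-negative scenarios", {
  for (seed in c(1, 5, 42, 99)) {
    g <- generate_menu(menu_generator_config(seed = seed))
    scs <- menu_to_scenarios(g)
    expect_length(scs, 4)
    for (s in scs) {
      expect_gte(s$G_B0, 0)
      expect_gte(s$T_LB0, 0)
      expect_silent(initial_state(s))
    }
  }
})

test_that("fixture menus agree with the printed per-day rows", {
  menus <- fixture_menus()
  expect_equal(menus[[1]]$totals$carbohydrate_g, 25.1, tolerance = 0.2)
  expect_equal(menus[[1]]$totals$fat_g, 178.9, tolerance = 0.2)
  expect_equal(menus[[1]]$totals$energy_kcal, 2061.7, tolerance = 1)
  expect_equal(menus[[2]]$totals$energy_kcal, 2005.8, tolerance = 1)
  expect_equal(menus[[3]]$totals$energy_kcal, 1995.6, tolerance = 0.1)
  expect_equal(menus[[4]]$totals$carbohydrate_g, 200, tolerance = 0.2)
})
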