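test_that("energy fractions follow Atwater arithmetic", {
  expect_identical(energy_fraction(178.9, "fat", 2061.7), 78.1)
  expect_identical(energy_fraction(238.5, "carbohydrate", 2005.8), 47.6)
  expect_identical(energy_fraction(0, "fat", 2000), 0)
  expect_error(energy_fraction(10, "fiber", 2000), "unknown")
  expect_error(energy_fraction(10, "fat", 0), "positive")
})

test_that("carbohydrate mass maps to plasma glucose by the 1.80 rule", {
  expect_equal(carbs_to_glucose_concentration(80.4), 44.666667,
               tolerance = 1e-6)
  expect_identical(round_half_up(carbs_to_glucose_concentration(80.4)), 44.7)
  expect_identical(round_half_up(carbs_to_glucose_concentration(12.6)), 7.0)
  expect_identical(carbs_to_glucose_concentration(0), 0)
  expect_error(carbs_to_glucose_concentration(-1), "non-negative")
})

test_that("origin-constrained factor fit matches its closed form", {
  # exact synthetic pairs g = 2 * c recover the factor exactly
  conc <- c(1, 2.5, 7, 11)
  expect_identical(fit_conversion_factor(2 * conc, conc), 2)
  grid <- reference_scenarios()
  fat_factor <- fit_conversion_factor(grid$fat_g, grid$T_LB0)
  expect_gt(fat_factor, 3.58); expect_lt(fat_factor, 3.60)
  carb_factor <- fit_conversion_factor(grid$carb_g, grid$G_B0)
  expect_equal(carb_factor, 1.80, tolerance = 0.005)
  expect_error(fit_conversion_factor(c(1, 2), c(0, 0)), "positive")
})

test_that("the published menus reproduce the full initial-condition grid", {
  menus <- table5_menus()
  grid <- reference_scenarios()
  factor <- tag_conversion_factor()
  for (m in menus) {
    scs <- menu_to_scenarios(m, factor)
    for (i in seq_along(scs)) {
      ref <- grid[grid$menu == m$id & grid$meal == m$meals[[i]]$label, ]
      expect_identical(round_half_up(scs[[i]]$G_B0), ref$G_B0,
                       info = scs[[i]]$label)
      expect_lt(abs(scs[[i]]$T_LB0 - ref$T_LB0), 0.1)
    }
  }
  # fitted-factor residuals stay below 0.1 mmol/L per meal
  pred <- grid$fat_g / factor
  expect_lt(max(abs(pred - grid$T_LB0)), 0.1)
})

test_that("menu totals and energy-fraction closure behave as printed", {
  menus <- table5_menus()
  expect_equal(menus[[1]]$totals$energy_kcal, 2061.7, tolerance = 1e-9)
  expect_equal(menus[[3]]$totals$energy_kcal, 1995.6, tolerance = 0.1)
  expect_equal(menus[[2]]$totals$carbohydrate_g, 238.5, tolerance = 0.2)
  # carbohydrate + fat percent stays below 100; the protein remainder is
  # implied, not printed per meal
  for (m in menus) {
    cf <- energy_fraction(m$totals$carbohydrate_g, "carbohydrate",
                          m$totals$energy_kcal) +
      energy_fraction(m$totals$fat_g, "fat", m$totals$energy_kcal)
    expect_lt(cf, 100)
    expect_gt(cf, 50)
  }
})

test_that("derived concentrations are homogeneous in mass", {
  g <- c(3, 17.2, 80)
  expect_equal(carbs_to_glucose_concentration(2 * g),
               2 * carbs_to_glucose_concentration(g))
  expect_equal(fat_to_tag_concentration(2 * g, 3.6),
               2 * fat_to_tag_concentration(g, 3.6))
})

test_that("menu CSV and scenario JSON round-trip", {
  m <- table5_menus()[[2]]
  f <- withr::local_tempfile(fileext = ".csv")
  write_menu_csv(m, f)
  m2 <- read_menu_csv(f, id = 2)
  expect_equal(m2$totals, m$totals)
  expect_identical(vapply(m2$meals, `[[`, "", "label"),
                   vapply(m$meals, `[[`, "", "label"))
  j <- withr::local_tempfile(fileext = ".json")
  write_scenarios_json(menu_to_scenarios(m), j)
  parsed <- jsonlite::read_json(j)
  expect_length(parsed, 4)
  expect_equal(parsed[[1]]$G_B0, carbs_to_glucose_concentration(80.4))
})
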