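# Menus, meals, and the mapping from macronutrient masses to the model's
# initial plasma concentrations.

.atwater <- c(carbohydrate = 4, fat = 9, protein = 4)  # kcal/g

#' Round half away from zero
#'
#' Display rounding used for reported concentrations and percentages
#' (half-up, matching the published tables, unlike R's banker's rounding).
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct a meal
#'
#' @param label one of `"breakfast"`, `"lunch"`, `"snack"`, `"dinner"`.
#' @param carbohydrate_g,fat_g,protein_g macronutrient masses (g).
#' @param energy_kcal meal energy (kcal).
#' @return A list of class `"lipid_meal"`.
#' @export
meal <- function(label, carbohydrate_g, fat_g, protein_g = NA_real_,
                 energy_kcal) {
  stopifnot(carbohydrate_g >= 0, fat_g >= 0, is.na(protein_g) || protein_g >= 0)
  if (energy_kcal <= 0 && (carbohydrate_g > 0 || fat_g > 0 ||
                           isTRUE(protein_g > 0)))
    stop("energy_kcal must be positive when any macronutrient mass is positive")
  structure(list(label = label, carbohydrate_g = carbohydrate_g,
                 fat_g = fat_g, protein_g = protein_g,
                 energy_kcal = energy_kcal), class = "lipid_meal")
}

#' Construct a menu of four meals
#'
#' @param id menu identifier.
#' @param meals list of four [meal()] objects.
#' @param sfa_percent optional daily saturated-fatty-acid share (metadata
#'   only; the model has no SFA-specific term).
#' @return A list of class `"lipid_menu"` with per-day totals.
#' @export
menu <- function(id, meals, sfa_percent = NA_real_) {
  totals <- list(
    carbohydrate_g = sum(vapply(meals, `[[`, 0, "carbohydrate_g")),
    fat_g = sum(vapply(meals, `[[`, 0, "fat_g")),
    energy_kcal = sum(vapply(meals, `[[`, 0, "energy_kcal")))
  structure(list(id = id, meals = meals, totals = totals,
                 sfa_percent = sfa_percent), class = "lipid_menu")
}

#' @export
print.lipid_menu <- function(x, ...) {
  cat("Menu", x$id, "-", length(x$meals), "meals,",
      round_half_up(x$totals$energy_kcal), "kcal/day (",
      round_half_up(x$totals$carbohydrate_g), "g carbohydrate,",
      round_half_up(x$totals$fat_g), "g fat )\n")
  invisible(x)
}

#' Energy fraction of a macronutrient
#'
#' Share of total energy contributed by a macronutrient mass, using
#' Atwater factors 4/9/4 kcal/g for carbohydrate/fat/protein.  Reported
#' rounded to one decimal.
#'
#' @param mass_g macronutrient mass (g).
#' @param macro `"carbohydrate"`, `"fat"` or `"protein"`.
#' @param total_kcal total energy (kcal), > 0.
#' @return Percent of total energy (one decimal).
#' @examples
#' energy_fraction(178.9, "fat", 2061.7)   # 78.1
#' @export
energy_fraction <- function(mass_g, macro, total_kcal) {
  if (total_kcal <= 0) stop("total_kcal must be positive")
  if (!macro %in% names(.atwater))
    stop("unknown macronutrient label: ", macro)
  round_half_up(100 * mass_g * .atwater[[macro]] / total_kcal, 1)
}

#' Initial plasma glucose from meal carbohydrate
#'
#' Maps carbohydrate mass to the scenario's initial plasma glucose using
#' a glucose molar mass of 180 g/mol over a 10 L distribution volume,
#' i.e. `grams / 1.80`.
#'
#' @param carbohydrate_g carbohydrate mass (g).
#' @return Initial plasma glucose G_B0 (mmol/L), unrounded.
#' @examples
#' carbs_to_glucose_concentration(80.4)  # 44.67 -> reported 44.7
#' @export
carbs_to_glucose_concentration <- function(carbohydrate_g) {
  if (any(carbohydrate_g < 0)) stop("carbohydrate mass must be non-negative")
  carbohydrate_g / 1.80
}

#' Initial plasma endogenous TAG from meal fat
#'
#' Maps fat mass to the scenario's initial endogenous lipoprotein TAG by
#' dividing by a grams-per-(mmol/L) conversion factor.  No printed molar
#' mass / distribution volume reproduces the published grid exactly, so
#' the default factor is fitted from the printed mass/concentration pairs
#' (see [fit_conversion_factor()], [tag_conversion_factor()]).
#'
#' @param fat_g fat mass (g).
#' @param factor conversion factor (g per mmol/L), > 0.
#' @return Initial plasma TAG T_LB0 (mmol/L), unrounded.
#' @export
fat_to_tag_concentration <- function(fat_g, factor = tag_conversion_factor()) {
  if (any(fat_g < 0)) stop("fat mass must be non-negative")
  if (factor <= 0) stop("conversion factor must be positive")
  fat_g / factor
}

#' Fit a grams-to-concentration factor through the origin
#'
#' Least-squares slope of mass against concentration constrained through
#' the origin: `f = sum(g*c) / sum(c^2)`, so that `g / f` best predicts
#' the concentrations.
#'
#' @param grams,conc numeric vectors (paired), concentrations > 0 for at
#'   least two pairs.
#' @return The factor (g per mmol/L).
#' @export
fit_conversion_factor <- function(grams, conc) {
  stopifnot(length(grams) == length(conc))
  keep <- conc > 0
  if (sum(keep) < 2) stop("need at least two pairs with positive concentration")
  sum(grams[keep] * conc[keep]) / sum(conc[keep]^2)
}

#' Default fat conversion factor
#'
#' The origin-constrained least-squares factor over the sixteen published
#' (fat mass, initial TAG) pairs, approximately 3.585 g per mmol/L.
#'
#' @return A single number (g per mmol/L).
#' @export
tag_conversion_factor <- function() {
  grid <- reference_scenarios()
  fit_conversion_factor(grid$fat_g, grid$T_LB0)
}

#' The four published menus
#'
#' Per-meal carbohydrate and fat masses with meal energies, exactly as
#' printed, for the four reference meal plans: ketogenic (Menu 1),
#' general population (Menu 2) and two intermediate plans.  Protein mass
#' is not printed per meal and is carried as `NA`.
#'
#' @return List of four `lipid_menu` objects.
#' @export
fixture_menus <- function() {
  m <- function(id, rows, sfa) {
    menu(id, lapply(seq_len(nrow(rows)), function(i)
      meal(rows$label[i], rows$carb[i], rows$fat[i],
           energy_kcal = rows$kcal[i])), sfa_percent = sfa)
  }
  lab <- c("breakfast", "lunch", "snack", "dinner")
  list(
    m(1, data.frame(label = lab, carb = c(2.7, 5.7, 4.1, 12.6),
                    fat = c(82.4, 32.6, 19.5, 44.4),
                    kcal = c(859.2, 408.6, 209.9, 584.0)), 16.2),
    m(2, data.frame(label = lab, carb = c(80.4, 89.7, 29.3, 39.1),
                    fat = c(5.9, 33.9, 15.3, 15.1),
                    kcal = c(421.9, 904.7, 284.1, 395.1)), 1.2),
    m(3, data.frame(label = lab, carb = c(13.9, 25.2, 14.9, 47.9),
                    fat = c(57.7, 27.7, 32.4, 18.2),
                    kcal = c(612.9, 517.3, 403.6, 461.8)), NA),
    m(4, data.frame(label = lab, carb = c(42.5, 77.8, 24.3, 55.4),
                    fat = c(16.7, 52.0, 5.6, 20.8),
                    kcal = c(343.9, 971.2, 164.4, 533.6)), NA)
  )
}

#' Published initial-condition grid
#'
#' The sixteen (menu, meal) scenarios with their printed initial plasma
#' glucose and endogenous TAG concentrations, paired with the printed
#' per-meal carbohydrate and fat masses.
#'
#' @return Data frame with columns `menu`, `meal`, `carb_g`, `fat_g`,
#'   `G_B0`, `T_LB0`.
#' @export
reference_scenarios <- function() {
  lab <- c("breakfast", "lunch", "snack", "dinner")
  data.frame(
    menu = rep(1:4, each = 4),
    meal = rep(lab, 4),
    carb_g = c(2.7, 5.7, 4.1, 12.6,   80.4, 89.7, 29.3, 39.1,
               13.9, 25.2, 14.9, 47.9, 42.5, 77.8, 24.3, 55.4),
    fat_g = c(82.4, 32.6, 19.5, 44.4,  5.9, 33.9, 15.3, 15.1,
              57.7, 27.7, 32.4, 18.2,  16.7, 52.0, 5.6, 20.8),
    G_B0 = c(1.5, 3.2, 2.3, 7.0,   44.7, 49.8, 16.3, 21.7,
             7.7, 14.0, 8.3, 26.6,  23.6, 43.2, 13.5, 30.8),
    T_LB0 = c(23, 9.1, 5.4, 12.4,  1.6, 9.5, 4.3, 4.2,
              16.1, 7.7, 9.0, 5.1,  4.7, 14.5, 1.6, 5.8),
    stringsAsFactors = FALSE
  )
}

#' Convert a menu into four meal scenarios
#'
#' Applies [carbs_to_glucose_concentration()] and
#' [fat_to_tag_concentration()] per meal.
#'
#' @param x a `lipid_menu`.
#' @param factor fat conversion factor (g per mmol/L).
#' @return List of four [meal_scenario()] objects labelled
#'   `"menu<id>-<meal>"`.
#' @export
menu_to_scenarios <- function(x, factor = tag_conversion_factor()) {
  stopifnot(inherits(x, "lipid_menu"))
  lapply(x$meals, function(m)
    meal_scenario(carbs_to_glucose_concentration(m$carbohydrate_g),
                  fat_to_tag_concentration(m$fat_g, factor),
                  label = paste0("menu", x$id, "-", m$label)))
}

#' Read / write menus as CSV
#'
#' Schema: `meal,carbohydrate_g,fat_g,protein_g,energy_kcal`, one row per
#' meal.
#'
#' @param x a `lipid_menu`.
#' @param path file path.
#' @param id menu id to attach on read.
#' @rdname menu_io
#' @export
write_menu_csv <- function(x, path) {
  stopifnot(inherits(x, "lipid_menu"))
  df <- do.call(rbind, lapply(x$meals, function(m)
    data.frame(meal = m$label, carbohydrate_g = m$carbohydrate_g,
               fat_g = m$fat_g, protein_g = m$protein_g,
               energy_kcal = m$energy_kcal)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname menu_io
#' @export
read_menu_csv <- function(path, id = 1) {
  df <- utils::read.csv(path)
  need <- c("meal", "carbohydrate_g", "fat_g", "energy_kcal")
  if (!all(need %in% names(df)))
    stop("menu CSV must have columns: ", paste(need, collapse = ", "))
  menu(id, lapply(seq_len(nrow(df)), function(i)
    meal(df$meal[i], df$carbohydrate_g[i], df$fat_g[i],
         if ("protein_g" %in% names(df)) df$protein_g[i] else NA_real_,
         df$energy_kcal[i])))
}

#' Export meal scenarios as JSON
#'
#' @param scenarios list of [meal_scenario()] objects.
#' @param path file path.
#' @export
write_scenarios_json <- function(scenarios, path) {
  jsonlite::write_json(
    lapply(scenarios, function(s)
      list(label = s$label, G_B0 = s$G_B0, T_LB0 = s$T_LB0)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
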