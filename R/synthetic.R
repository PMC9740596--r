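# Synthetic menu generator: random menus with the macronutrient structure
# the analysis assumes, spanning ketogenic-like to general-population-like
# compositions.

#' Configuration for the synthetic menu generator
#'
#' Defaults mirror the study conditions: four meals per day, total energy
#' 2000 +/- 100 kcal, carbohydrate energy fraction between 5% and 60%
#' (the published span from ketogenic to general-population guidance) and
#' fat fraction between 20% and 80%.  Protein takes the residual energy;
#' at least `min_protein` of energy is reserved for it.
#'
#' @param energy_kcal daily energy target (kcal).
#' @param energy_tol half-width of the energy band (kcal).
#' @param carb_range carbohydrate energy-fraction range.
#' @param fat_range fat energy-fraction range.
#' @param meal_weights energy split over the four meals; defaults to the
#'   mean empirical shares of the published menus.
#' @param min_protein minimum protein energy fraction (default 0.05).
#' @param seed integer seed.
#' @return A list of class `"menu_generator_config"`.
#' @export
menu_generator_config <- function(energy_kcal = 2000, energy_tol = 100,
                                  carb_range = c(0.05, 0.60),
                                  fat_range = c(0.20, 0.80),
                                  meal_weights = NULL,
                                  min_protein = 0.05, seed = 1) {
  stopifnot(energy_kcal > 0, energy_tol >= 0,
            all(carb_range > 0), all(carb_range < 1),
            all(fat_range > 0), all(fat_range < 1),
            diff(carb_range) >= 0, diff(fat_range) >= 0)
  if (carb_range[1] + fat_range[1] > 1 - min_protein)
    stop("infeasible fraction ranges: minimum carbohydrate + fat fractions leave no room for protein")
  if (is.null(meal_weights)) {
    menus <- fixture_menus()
    shares <- sapply(menus, function(m)
      vapply(m$meals, `[[`, 0, "energy_kcal") / m$totals$energy_kcal)
    meal_weights <- rowMeans(shares)
  }
  meal_weights <- meal_weights / sum(meal_weights)
  structure(list(energy_kcal = energy_kcal, energy_tol = energy_tol,
                 carb_range = carb_range, fat_range = fat_range,
                 meal_weights = meal_weights, min_protein = min_protein,
                 seed = seed),
            class = "menu_generator_config")
}

#' Generate a random menu
#'
#' Draws daily energy uniformly inside the tolerance band and
#' carbohydrate/fat energy fractions uniformly inside their configured
#' ranges (rejecting draws that leave less than the reserved protein
#' fraction), splits energy over the four meals by the configured
#' weights, and converts energy to grams with Atwater factors 4/9/4.
#'
#' @param config a [menu_generator_config()].
#' @param id menu identifier for the result.
#' @return A `lipid_menu`.
#' @examples
#' g <- generate_menu(menu_generator_config(seed = 42))
#' g$totals$energy_kcal   # within 2000 +/- 100
#' @export
generate_menu <- function(config = menu_generator_config(), id = "synthetic") {
  stopifnot(inherits(config, "menu_generator_config"))
  set.seed(config$seed)
  energy <- stats::runif(1, config$energy_kcal - config$energy_tol,
                         config$energy_kcal + config$energy_tol)
  repeat {
    fc <- stats::runif(1, config$carb_range[1], config$carb_range[2])
    ff <- stats::runif(1, config$fat_range[1], config$fat_range[2])
    if (fc + ff <= 1 - config$min_protein) break
  }
  fp <- 1 - fc - ff
  labels <- c("breakfast", "lunch", "snack", "dinner")
  meals <- lapply(seq_along(config$meal_weights), function(i) {
    e <- energy * config$meal_weights[i]
    meal(labels[min(i, 4)],
         carbohydrate_g = fc * e / 4,
         fat_g = ff * e / 9,
         protein_g = fp * e / 4,
         energy_kcal = e)
  })
  menu(id, meals)
}
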