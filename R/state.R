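# The 23 model state variables, their units and published starting values.
# Plasma glucose (G_B) and plasma endogenous lipoprotein TAG (T_LB) have no
# fixed default: they are supplied per meal scenario.

.state_table <- data.frame(
  name = c("I",
           "G_L", "P_L", "Y_L", "R_L", "A_L", "S_L", "T_L",
           "G_M", "Y_M", "P_M", "R_M", "A_M", "T_M",
           "P",
           "T_A", "A_A", "L_A", "G_A",
           "T_CB", "A_B", "T_LB", "G_B"),
  unit = c("pmol/L", rep("mmol/L", 22)),
  default = c(60,
              8, 2.06, 50, 0.37, 0.57, 0.0149, 40,
              0.5, 20, 0.133, 0.009, 0.53, 14.8,
              0,
              500, 0.57, 0.17, 2.53,
              0, 0.5, NA, NA),
  description = c(
    "plasma insulin",
    "liver glucose", "liver glucose-6-phosphate", "liver glycogen",
    "liver pyruvate", "liver free fatty acids",
    "liver triacylglyceride secretory pool",
    "liver triacylglyceride storage pool",
    "muscle glucose", "muscle glycogen", "muscle glucose-6-phosphate",
    "muscle pyruvate", "muscle free fatty acids", "muscle triacylglycerides",
    "muscle AMP",
    "adipose triacylglycerides", "adipose free fatty acids",
    "adipose glycerol", "adipose glucose",
    "plasma exogenous (chylomicron) triacylglycerides",
    "plasma non-esterified fatty acids (displayed A_NB)",
    "plasma endogenous lipoprotein triacylglycerides",
    "plasma glucose"),
  stringsAsFactors = FALSE
)

#' State variable metadata
#'
#' The 23 concentrations of the model: symbol, unit, published starting
#' value and description.  `G_B` and `T_LB` defaults are `NA` because they
#' come from the meal scenario.
#'
#' @return A data frame with columns `name`, `unit`, `default`,
#'   `description`.
#' @export
state_info <- function() .state_table

#' Initial state for a meal scenario
#'
#' Combines the published starting concentrations with the scenario's
#' initial plasma glucose and endogenous TAG.  The chylomicron pool
#' `T_CB` and muscle AMP `P` start at zero.
#'
#' @param scenario a `meal_scenario` (see [meal_scenario()]), or any list
#'   with numeric elements `G_B0` and `T_LB0` (mmol/L).
#' @return Named numeric vector of length 23 in balance order.
#' @examples
#' initial_state(meal_scenario(G_B0 = 3.2, T_LB0 = 9.1))
#' @export
initial_state <- function(scenario) {
  if (!all(c("G_B0", "T_LB0") %in% names(scenario)))
    stop("scenario must supply G_B0 and T_LB0")
  g <- as.numeric(scenario[["G_B0"]])
  t <- as.numeric(scenario[["T_LB0"]])
  if (!is.finite(g) || !is.finite(t)) stop("scenario concentrations must be finite")
  if (g < 0 || t < 0) stop("scenario concentrations must be non-negative")
  st <- stats::setNames(.state_table$default, .state_table$name)
  st[["G_B"]] <- g
  st[["T_LB"]] <- t
  st
}

#' Construct a meal scenario
#'
#' A meal scenario carries the two menu-derived initial plasma
#' concentrations that parameterize a simulation.
#'
#' @param G_B0 initial plasma glucose (mmol/L).
#' @param T_LB0 initial plasma endogenous lipoprotein TAG (mmol/L).
#' @param label optional label (e.g. `"menu1-lunch"`).
#' @return A list of class `"meal_scenario"`.
#' @export
meal_scenario <- function(G_B0, T_LB0, label = NULL) {
  stopifnot(is.numeric(G_B0), is.numeric(T_LB0),
            length(G_B0) == 1, length(T_LB0) == 1)
  if (G_B0 < 0 || T_LB0 < 0) stop("scenario concentrations must be non-negative")
  structure(list(G_B0 = G_B0, T_LB0 = T_LB0, label = label),
            class = "meal_scenario")
}

#' @export
print.meal_scenario <- function(x, ...) {
  cat("Meal scenario", if (!is.null(x$label)) paste0("'", x$label, "'") else "",
      ": G_B0 =", x$G_B0, "mmol/L, T_LB0 =", x$T_LB0, "mmol/L\n")
  invisible(x)
}
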