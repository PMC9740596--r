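# The 23 balance equations of the whole-body lipid metabolism model.
#
# This file holds the pure-R reference right-hand side.  The compiled C
# version in src/ (used by the integrator) must agree with it bit-for-bit
# up to floating point; tests enforce that.

#' Error function
#'
#' `erf(x) = 2*pnorm(x*sqrt(2)) - 1`, used by the glucose-stimulated
#' insulin secretion term.
#' @param x numeric.
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Dietary input forcing
#'
#' Describes how a meal enters the model.  In the default `"bolus"` mode a
#' meal is represented purely through elevated initial plasma glucose and
#' TAG concentrations and both input fluxes `S_G(t)` and `S_F(t)` are zero.
#' In `"exponential"` mode the fluxes decay from an initial amplitude,
#' `S_G(t) = glucose_amplitude * exp(-t / alpha_G)` (and analogously for
#' fat with `alpha_F`), with the decay scales taken from the parameter set.
#'
#' @param mode `"bolus"` (default) or `"exponential"`.
#' @param glucose_amplitude,fat_amplitude initial flux amplitudes
#'   (mmol/min), exponential mode only.
#' @param alpha_G,alpha_F decay scales (min); default the nominal
#'   parameter values.
#' @return An object of class `"meal_forcing"` with evaluators `S_G(t)`,
#'   `S_F(t)`.
#' @export
meal_forcing <- function(mode = c("bolus", "exponential"),
                         glucose_amplitude = 0, fat_amplitude = 0,
                         alpha_G = NULL, alpha_F = NULL) {
  mode <- match.arg(mode)
  if (mode == "bolus") {
    glucose_amplitude <- 0
    fat_amplitude <- 0
  }
  if (glucose_amplitude < 0 || fat_amplitude < 0)
    stop("forcing amplitudes must be non-negative")
  par <- default_parameters()
  if (is.null(alpha_G)) alpha_G <- par[["alpha_G"]]
  if (is.null(alpha_F)) alpha_F <- par[["alpha_F"]]
  structure(list(
    mode = mode,
    glucose_amplitude = glucose_amplitude, fat_amplitude = fat_amplitude,
    alpha_G = alpha_G, alpha_F = alpha_F,
    S_G = function(t) if (mode == "bolus") 0 * t else glucose_amplitude * exp(-t / alpha_G),
    S_F = function(t) if (mode == "bolus") 0 * t else fat_amplitude * exp(-t / alpha_F)
  ), class = "meal_forcing")
}

# The composite flux algebra, as quoted expressions.  Single source for
# the R right-hand side, the reaction registry and the SBML kinetic-law
# writer.  Order matters (F_I before vldl).  Glycogenolysis is printed
# with different insulin inhibition on the glycogen side (k_dl) and the
# G6P side (k_p6), and the v_8 esterification flux with different forms
# on its two sides; all kept exactly as printed (see unit_audit()).
.flux_defs <- list(
  glucokinase = quote(v_LG * G_L / (k_LG + G_L)),
  hexokinase_L = quote(v_LH * G_L / (k_LH + G_L) / (1 + k_rep * P_L)),
  hexokinase_M = quote(v_MH * G_M / (k_MH + G_M) / (1 + k_rep * P_M)),
  gsyn_L = quote(0.5 * k_yl * I * P_L * (1 + tanh((l_max - Y_L) / c_0))),
  gly_L_y = quote(beta_L / (1 + k_dl * I) * Y_L / (Y_L + y_0)),
  gly_L_p = quote(beta_L / (1 + k_p6 * I) * Y_L / (Y_L + y_0)),
  gsyn_M = quote(0.5 * k_ym * I * P_M * (1 + tanh((m_max - Y_M) / c_0))),
  gly_M = quote(beta_M / (1 + k_dy * I) * Y_M / (Y_M + y_0)),
  dnl = quote(beta_6 * R_L / (1 + k_p6 * I)),
  v6sec = quote(v_6 * A_L / (k_6 + A_L)),
  v8_tl = quote(v_8 * A_L / (k_8 + A_L)),
  v8_al = quote(v_8 * A_L / (1 + k_5 * I)),
  k7ox = quote(k_7 * A_L / (1 + k_5 * I)),
  tl_rel = quote(v_10 * T_L / (k_10 + T_L)),
  F_I = quote(k_12 * tanh((v_12 - I) / k_13) + k_14),
  vldl = quote(F_I * v_9 * T_L / (k_9 + T_L)),
  secretion = quote(k_11 + k_22 * erf((G_B - v) / c_c)),
  glc_MB = quote((1 + k_gi * I) * (k_gm * G_B - k_gm2 * G_M)),
  glc_AB = quote(d_ba * (1 + k_ga * I) * (G_B - G_A)),
  lipolysis = quote(beta_f / (1 + k_ft * I^2)),
  chylo = quote(k_a * (1 + k_ai * I) * T_CB),
  esterif_A = quote(k_aa * I * A_A * G_A)
)

# Evaluate the flux algebra in an environment holding state, parameters
# and forcing values.
.model_env <- function(state, params, t, forcing) {
  e <- list2env(as.list(c(state, params)))
  e$SG <- forcing$S_G(t)
  e$SF <- forcing$S_F(t)
  e$erf <- erf
  for (nm in names(.flux_defs))
    assign(nm, eval(.flux_defs[[nm]], e), envir = e)
  e
}

#' Right-hand side of the model balances
#'
#' Evaluates the time derivative of all 23 state variables at a given
#' state.  Compartment balances (liver, muscle, adipose) are divided by
#' their tissue volume; plasma and AMP balances are not.
#'
#' @param state named numeric vector of the 23 concentrations (see
#'   [state_info()]).
#' @param params a [default_parameters()] vector.
#' @param t time (min); only relevant with exponential forcing.
#' @param forcing a [meal_forcing()]; default bolus (zero input fluxes).
#' @return Named numeric vector of 23 derivatives (concentration/min).
#' @examples
#' st <- initial_state(meal_scenario(3.2, 9.1))
#' evaluate_rhs(st, default_parameters())
#' @export
evaluate_rhs <- function(state, params = default_parameters(), t = 0,
                         forcing = meal_forcing()) {
  if (!all(is.finite(state))) {
    bad <- names(state)[!is.finite(state)]
    stop("non-finite state component(s): ", paste(bad, collapse = ", "))
  }
  if (!all(is.finite(params)))
    stop("non-finite parameter(s): ",
         paste(names(params)[!is.finite(params)], collapse = ", "))
  e <- .model_env(state, params, t, forcing)
  d <- with(e, c(
    I   = secretion - k_d * I,
    G_L = (SG - k_gl * G_L + k_gl2 * G_B - glucokinase - hexokinase_L +
             k_61 * P_L) / alpha_L,
    P_L = (-gsyn_L + gly_L_p - k_p * I * P_L + k_gp * L_A + dnl +
             glucokinase + hexokinase_L - k_61 * P_L) / alpha_L,
    Y_L = (gsyn_L - gly_L_y) / alpha_L,
    R_L = (k_pp * R_M + 2 * mu_b + k_p * I * P_L - dnl - k_al * I * R_L) /
      alpha_L,
    A_L = (3 * k_cl * T_CB + k_bl * A_B + 3 * k_r * T_LB + k_al * I * R_L -
             3 * v6sec + 3 * tl_rel - 3 * v8_al - k7ox) / alpha_L,
    S_L = (v6sec - k_9a * S_L) / alpha_L,
    T_L = (v8_tl - vldl - tl_rel) / alpha_L,
    G_M = (glc_MB - hexokinase_M) / alpha_M,
    Y_M = (gsyn_M - gly_M) / alpha_M,
    P_M = (hexokinase_M - gsyn_M + gly_M - k_6p * I * P_M) / alpha_M,
    R_M = (k_6p * I * P_M - k_pp * R_M - mu_3 * R_M * I * P) / alpha_M,
    A_M = (-3 * m_s * I * A_M + 3 * m_e + 3 * k_cm * T_CB + k_bm * A_B +
             3 * k_t * T_LB - mu_4 * A_M * P) / alpha_M,
    T_M = (m_s * I * A_M - m_e) / alpha_M,
    P   = mu_amp - mu_4 * A_M * P - mu_3 * R_M * I * P,
    T_A = (esterif_A - lipolysis) / alpha_A,
    A_A = (-3 * esterif_A + 3 * chylo + 3 * k_ba * T_LB + k_na * A_B) /
      alpha_A,
    L_A = (lipolysis - k_gp * L_A) / alpha_A,
    G_A = (glc_AB - esterif_A) / alpha_A,
    T_CB = SF - k_cm * T_CB - k_cl * T_CB - chylo,
    A_B = -k_bm * A_B - k_bl * A_B - k_na * A_B + 3 * lipolysis + 3 * chylo,
    T_LB = vldl + k_9a * S_L - k_r * T_LB - k_t * T_LB - k_ba * T_LB,
    G_B = k_gl * G_L - k_gl2 * G_B - glc_MB - glc_AB - mu_1
  ))
  d
}
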