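# Named registry of the 45 reaction fluxes the balances are composed of.
#
# Each entry carries a canonical rate expression plus the signed,
# stoichiometrically weighted terms it contributes to individual balances.
# Where the printed balances give the *same* physical flux two different
# algebraic forms on its two sides (a handful of printed inconsistencies),
# the terms carry side-specific expressions and the audit flags the pair.
# Expressions are evaluated in the shared flux environment of the model
# right-hand side, so registry and balances cannot drift apart.

.reaction_list <- local({
  rx <- function(id, desc, rate, terms)
    list(id = id, description = desc, rate = rate, terms = terms)
  tm <- function(state, coef, expr) list(state = state, coef = coef, expr = expr)
  list(
    rx("v1", "glucose-stimulated insulin secretion", quote(secretion),
       list(tm("I", +1, quote(secretion)))),
    rx("v2", "insulin degradation", quote(k_d * I),
       list(tm("I", -1, quote(k_d * I)))),
    rx("v3", "glucose input from the diet", quote(SG),
       list(tm("G_L", +1, quote(SG)))),
    rx("v4", "glucose flux from liver to plasma", quote(k_gl * G_L),
       list(tm("G_L", -1, quote(k_gl * G_L)), tm("G_B", +1, quote(k_gl * G_L)))),
    rx("v5", "glucose flux from plasma to liver", quote(k_gl2 * G_B),
       list(tm("G_L", +1, quote(k_gl2 * G_B)), tm("G_B", -1, quote(k_gl2 * G_B)))),
    rx("v6", "liver glucokinase (glucose phosphorylation)", quote(glucokinase),
       list(tm("G_L", -1, quote(glucokinase)), tm("P_L", +1, quote(glucokinase)))),
    rx("v7", "liver hexokinase (G6P-inhibited glucose phosphorylation)",
       quote(hexokinase_L),
       list(tm("G_L", -1, quote(hexokinase_L)), tm("P_L", +1, quote(hexokinase_L)))),
    rx("v8", "liver glucose-6-phosphate dephosphorylation", quote(k_61 * P_L),
       list(tm("G_L", +1, quote(k_61 * P_L)), tm("P_L", -1, quote(k_61 * P_L)))),
    rx("v9", "liver glycogen synthesis/glycogenolysis (reversible)",
       quote(gsyn_L - gly_L_y),
       list(tm("Y_L", +1, quote(gsyn_L - gly_L_y)),
            tm("P_L", -1, quote(gsyn_L - gly_L_p)))),
    rx("v10", "insulin-mediated liver G6P conversion to pyruvate",
       quote(k_p * I * P_L),
       list(tm("P_L", -1, quote(k_p * I * P_L)), tm("R_L", +1, quote(k_p * I * P_L)))),
    rx("v11", "adipose glycerol uptake into liver G6P", quote(k_gp * L_A),
       list(tm("P_L", +1, quote(k_gp * L_A)), tm("L_A", -1, quote(k_gp * L_A)))),
    rx("v12", "liver de novo lipogenesis from pyruvate", quote(dnl),
       list(tm("R_L", -1, quote(dnl)), tm("P_L", +1, quote(dnl)))),
    rx("v13", "muscle-to-liver pyruvate transport", quote(k_pp * R_M),
       list(tm("R_L", +1, quote(k_pp * R_M)), tm("R_M", -1, quote(k_pp * R_M)))),
    rx("v14", "lactate production by red blood cells", quote(mu_b),
       list(tm("R_L", +2, quote(mu_b)))),
    rx("v15", "liver pyruvate conversion to acetyl-CoA / fatty acids",
       quote(k_al * I * R_L),
       list(tm("R_L", -1, quote(k_al * I * R_L)), tm("A_L", +1, quote(k_al * I * R_L)))),
    rx("v16", "uptake of exogenous plasma TAG into liver free fatty acids",
       quote(3 * k_cl * T_CB),
       list(tm("A_L", +3, quote(k_cl * T_CB)), tm("T_CB", -1, quote(k_cl * T_CB)))),
    rx("v17", "free fatty acid transport from plasma to liver", quote(k_bl * A_B),
       list(tm("A_L", +1, quote(k_bl * A_B)), tm("A_B", -1, quote(k_bl * A_B)))),
    rx("v18", "free fatty acid synthesis from plasma endogenous TAG (liver)",
       quote(3 * k_r * T_LB),
       list(tm("A_L", +3, quote(k_r * T_LB)), tm("T_LB", -1, quote(k_r * T_LB)))),
    rx("v19", "liver TAG storage conversion to free fatty acids",
       quote(tl_rel),
       list(tm("A_L", +3, quote(tl_rel)), tm("T_L", -1, quote(tl_rel)))),
    rx("v20", "liver free fatty acid input to TAG secretory pool", quote(v6sec),
       list(tm("A_L", -3, quote(v6sec)), tm("S_L", +1, quote(v6sec)))),
    rx("v21", "liver free fatty acid esterification to storage TAG",
       quote(v8_tl),
       list(tm("T_L", +1, quote(v8_tl)), tm("A_L", -3, quote(v8_al)))),
    rx("v22", "liver free fatty acid oxidation (insulin-inhibited)", quote(k7ox),
       list(tm("A_L", -1, quote(k7ox)))),
    rx("v23", "VLDL release from the secretory pathway", quote(k_9a * S_L),
       list(tm("S_L", -1, quote(k_9a * S_L)), tm("T_LB", +1, quote(k_9a * S_L)))),
    rx("v24", "TAG secretion from liver to plasma (insulin-modified VLDL)",
       quote(vldl),
       list(tm("T_L", -1, quote(vldl)), tm("T_LB", +1, quote(vldl)))),
    rx("v25", "insulin-stimulated glucose transport plasma <-> muscle",
       quote(glc_MB),
       list(tm("G_M", +1, quote(glc_MB)), tm("G_B", -1, quote(glc_MB)))),
    rx("v26", "muscle hexokinase (glucose phosphorylation)", quote(hexokinase_M),
       list(tm("G_M", -1, quote(hexokinase_M)), tm("P_M", +1, quote(hexokinase_M)))),
    rx("v27", "muscle glycogen synthesis/glycogenolysis (reversible)",
       quote(gsyn_M - gly_M),
       list(tm("Y_M", +1, quote(gsyn_M - gly_M)),
            tm("P_M", -1, quote(gsyn_M - gly_M)))),
    rx("v28", "muscle G6P conversion to pyruvate", quote(k_6p * I * P_M),
       list(tm("P_M", -1, quote(k_6p * I * P_M)), tm("R_M", +1, quote(k_6p * I * P_M)))),
    rx("v29", "AMP-dependent muscle pyruvate usage", quote(mu_3 * R_M * I * P),
       list(tm("R_M", -1, quote(mu_3 * R_M * I * P)),
            tm("P", -1, quote(mu_3 * R_M * I * P)))),
    rx("v30", "muscle FFA esterification / TAG breakdown (reversible)",
       quote(m_s * I * A_M - m_e),
       list(tm("T_M", +1, quote(m_s * I * A_M - m_e)),
            tm("A_M", -3, quote(m_s * I * A_M - m_e)))),
    rx("v31", "AMP-dependent muscle free fatty acid usage", quote(mu_4 * A_M * P),
       list(tm("A_M", -1, quote(mu_4 * A_M * P)), tm("P", -1, quote(mu_4 * A_M * P)))),
    rx("v32", "uptake of exogenous plasma TAG into muscle free fatty acids",
       quote(3 * k_cm * T_CB),
       list(tm("A_M", +3, quote(k_cm * T_CB)), tm("T_CB", -1, quote(k_cm * T_CB)))),
    rx("v33", "free fatty acid uptake from plasma into muscle", quote(k_bm * A_B),
       list(tm("A_M", +1, quote(k_bm * A_B)), tm("A_B", -1, quote(k_bm * A_B)))),
    rx("v34", "uptake of plasma endogenous TAG into muscle free fatty acids",
       quote(3 * k_t * T_LB),
       list(tm("A_M", +3, quote(k_t * T_LB)), tm("T_LB", -1, quote(k_t * T_LB)))),
    rx("v35", "AMP creation", quote(mu_amp),
       list(tm("P", +1, quote(mu_amp)))),
    rx("v36", "adipose free fatty acid esterification to TAG", quote(esterif_A),
       list(tm("T_A", +1, quote(esterif_A)), tm("A_A", -3, quote(esterif_A)),
            tm("G_A", -1, quote(esterif_A)))),
    rx("v37", "insulin-inhibited adipose TAG release (lipolysis)", quote(lipolysis),
       list(tm("T_A", -1, quote(lipolysis)), tm("L_A", +1, quote(lipolysis)),
            tm("A_B", +3, quote(lipolysis)))),
    rx("v38", "uptake of plasma exogenous TAG by adipose tissue", quote(chylo),
       list(tm("T_CB", -1, quote(chylo)))),
    rx("v39", "uptake of plasma endogenous TAG into adipose free fatty acids",
       quote(3 * k_ba * T_LB),
       list(tm("A_A", +3, quote(k_ba * T_LB)), tm("T_LB", -1, quote(k_ba * T_LB)))),
    rx("v40", "uptake of plasma free fatty acids into adipose", quote(k_na * A_B),
       list(tm("A_A", +1, quote(k_na * A_B)), tm("A_B", -1, quote(k_na * A_B)))),
    rx("v41", "plasma glucose usage", quote(mu_1),
       list(tm("G_B", -1, quote(mu_1)))),
    rx("v42", "glucose transport between plasma and adipose tissue", quote(glc_AB),
       list(tm("G_A", +1, quote(glc_AB)), tm("G_B", -1, quote(glc_AB)))),
    rx("v43", "fat input from the diet", quote(SF),
       list(tm("T_CB", +1, quote(SF)))),
    rx("v44", "complete uptake of plasma exogenous TAG by adipose tissue",
       quote(3 * chylo),
       list(tm("A_A", +3, quote(chylo)))),
    rx("v45", "adipose chylomicron-derived FFA spillover to plasma",
       quote(3 * chylo),
       list(tm("A_B", +3, quote(chylo))))
  )
})

#' The reaction registry
#'
#' All 45 named reaction fluxes with descriptions and the balances each
#' contributes to.  The reaction ids follow the published naming where
#' reactions are named; the remaining ids are assigned in balance reading
#' order (the full assignment is visible in the returned table).
#'
#' @return A data frame with one row per (reaction, balance term):
#'   columns `id`, `description`, `state`, `coef` (signed stoichiometric
#'   multiplier) and `term` (deparsed expression).
#' @export
reaction_registry <- function() {
  do.call(rbind, lapply(.reaction_list, function(r) {
    do.call(rbind, lapply(r$terms, function(tm)
      data.frame(id = r$id, description = r$description, state = tm$state,
                 coef = tm$coef, term = deparse(tm$expr),
                 stringsAsFactors = FALSE)))
  }))
}

#' Evaluate all 45 reaction rates
#'
#' Computes the canonical rate of every registry reaction at a given
#' state.  Signed sums of the registry's balance terms reproduce
#' [evaluate_rhs()] exactly; see [flux_closure()].
#'
#' @inheritParams evaluate_rhs
#' @return Named numeric vector `v1` ... `v45` (mmol/min; insulin-balance
#'   rates in pmol-equivalents as printed).
#' @examples
#' st <- initial_state(meal_scenario(3.2, 9.1))
#' reaction_rates(st, default_parameters())[["v19"]]
#' @export
reaction_rates <- function(state, params = default_parameters(), t = 0,
                           forcing = meal_forcing()) {
  if (!all(is.finite(state)))
    stop("non-finite state component(s): ",
         paste(names(state)[!is.finite(state)], collapse = ", "))
  e <- .model_env(state, params, t, forcing)
  vapply(.reaction_list, function(r) eval(r$rate, e), 0,
         USE.NAMES = FALSE) -> rates
  stats::setNames(rates, vapply(.reaction_list, `[[`, "", "id"))
}

#' Rebuild the balance right-hand sides from the registry
#'
#' Sums every registry term with its sign and stoichiometric factor per
#' state and divides compartment balances by their tissue volume.  Used as
#' the flux-attribution closure check against [evaluate_rhs()].
#'
#' @inheritParams evaluate_rhs
#' @return Named numeric vector of 23 derivatives.
#' @export
flux_closure <- function(state, params = default_parameters(), t = 0,
                         forcing = meal_forcing()) {
  e <- .model_env(state, params, t, forcing)
  acc <- stats::setNames(numeric(nrow(.state_table)), .state_table$name)
  for (r in .reaction_list)
    for (tm in r$terms)
      acc[[tm$state]] <- acc[[tm$state]] + tm$coef * eval(tm$expr, e)
  vol <- c(rep(params[["alpha_L"]], 7), rep(params[["alpha_M"]], 6))
  names(vol) <- c("G_L", "P_L", "Y_L", "R_L", "A_L", "S_L", "T_L",
                  "G_M", "Y_M", "P_M", "R_M", "A_M", "T_M")
  adipose <- c("T_A", "A_A", "L_A", "G_A")
  acc[names(vol)] <- acc[names(vol)] / vol
  acc[adipose] <- acc[adipose] / params[["alpha_A"]]
  acc
}

#' Dimensional audit of the printed balances
#'
#' The printed model carries several dimensional inconsistencies (units
#' that do not reduce to concentration/min, duplicated terms, and fluxes
#' whose two balance sides differ algebraically).  Following the
#' printed-as-is policy they are implemented verbatim; this audit lists
#' them rather than hiding them.
#'
#' @return A data frame with columns `where`, `issue`.
#' @export
unit_audit <- function() {
  data.frame(
    where = c(
      "insulin balance",
      "liver pyruvate balance",
      "liver glycogen / G6P balances",
      "liver FFA vs storage TAG balances",
      "plasma NEFA balance",
      "parameter k_d",
      "parameter k_r",
      "parameters l_max, m_max, v",
      "insulin-dependent products"),
    issue = c(
      "insulin is carried in pmol/L while secretion constants are printed in mmol/min; no unit conversion appears in the balance",
      "the lactate input mu_b is printed twice; both occurrences kept (stoichiometric factor 2)",
      "glycogenolysis is inhibited by 1/(1+k_p6*I) on the G6P side but 1/(1+k_dl*I) on the glycogen side",
      "the esterification flux v_8 appears as v_8*A_L/(1+k_5*I) in the FFA balance but v_8*A_L/(k_8+A_L) in the storage balance",
      "the lipolysis and chylomicron inflow terms are printed truncated; implemented in the full form used by their counterpart balances",
      "printed as 1.733e14 L/mmol but used as a first-order rate (1/min)",
      "printed unit mmol but used as a first-order rate (L/min-like)",
      "printed in mmol but compared against concentrations (mmol/L)",
      "terms like k_yl*I mix pmol/L insulin with mmol-based constants; magnitudes kept exactly as printed"),
    stringsAsFactors = FALSE
  )
}
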