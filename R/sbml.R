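# Optional SBML Level 3 Version 2 export of the reaction network.
# Hand-assembled XML (via xml2): species = the 23 states in their four
# compartments, reactions = the registry entries with MathML kinetic laws.

# Expand derived flux names into elementary state/parameter algebra.
.expand_expr <- function(e) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(.flux_defs)) return(.expand_expr(.flux_defs[[nm]]))
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- .expand_expr(e[[i]])
    return(e)
  }
  e
}

# R expression -> content MathML node list (as xml2 structure building).
.mathml <- function(e, doc_add) {
  if (is.numeric(e)) {
    doc_add("cn", as.character(e))
  } else if (is.name(e)) {
    doc_add("ci", as.character(e))
  } else if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.mathml(e[[2]], doc_add))
    apply_node <- doc_add("apply")
    add_child <- function(tag, text = NULL) {
      nd <- xml2::xml_add_child(apply_node, tag)
      if (!is.null(text)) xml2::xml_set_text(nd, text)
      nd
    }
    sub_add <- function(tag, text = NULL) add_child(tag, text)
    if (op %in% c("+", "-", "*", "/", "^")) {
      tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                    "/" = "divide", "^" = "power")
      add_child(tag)
      for (i in seq_along(e)[-1]) .mathml(e[[i]], sub_add)
    } else if (op == "tanh") {
      add_child("tanh")
      .mathml(e[[2]], sub_add)
    } else if (op == "erf") {
      cs <- add_child("csymbol", "erf")
      xml2::xml_set_attr(cs, "encoding", "text")
      xml2::xml_set_attr(cs, "definitionURL", "urn:lipidfast:erf")
      .mathml(e[[2]], sub_add)
    } else {
      stop("cannot convert operator to MathML: ", op)
    }
    apply_node
  } else stop("cannot convert to MathML: ", deparse(e))
}

#' Export the model as SBML Level 3 Version 2
#'
#' Writes the reaction network: four compartments (liver, muscle,
#' adipose, plasma) with their volumes, the 23 species with the
#' scenario's initial concentrations, all 81 parameters, and the 45
#' registry reactions with content-MathML kinetic laws (the per-unit
#' flux; stoichiometric factors are carried on the species references).
#' The error function in the insulin secretion law is encoded as a
#' MathML `csymbol` — core SBML has no erf, so interpreting tools must
#' map that symbol.  For the few fluxes the printed balances give two
#' algebraic forms, the kinetic law uses the first-listed side.
#'
#' @param path output file.
#' @param scenario a [meal_scenario()] supplying initial G_B and T_LB.
#' @param params parameter set.
#' @return Invisibly, `path`.
#' @export
export_sbml <- function(path, scenario = meal_scenario(0, 0),
                        params = default_parameters()) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "hepatic_lipid_metabolism")

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  vols <- c(liver = params[["alpha_L"]], muscle = params[["alpha_M"]],
            adipose = params[["alpha_A"]], plasma = 1)
  for (nm in names(vols))
    xml2::xml_add_child(comps, "compartment", id = nm,
                        size = as.character(vols[[nm]]), constant = "true")

  comp_of <- c(I = "plasma",
               G_L = "liver", P_L = "liver", Y_L = "liver", R_L = "liver",
               A_L = "liver", S_L = "liver", T_L = "liver",
               G_M = "muscle", Y_M = "muscle", P_M = "muscle",
               R_M = "muscle", A_M = "muscle", T_M = "muscle",
               P = "muscle",
               T_A = "adipose", A_A = "adipose", L_A = "adipose",
               G_A = "adipose",
               T_CB = "plasma", A_B = "plasma", T_LB = "plasma",
               G_B = "plasma")
  init <- initial_state(scenario)
  spl <- xml2::xml_add_child(model, "listOfSpecies")
  for (nm in names(init))
    xml2::xml_add_child(spl, "species", id = nm,
                        compartment = comp_of[[nm]],
                        initialConcentration = as.character(init[[nm]]),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  pl <- xml2::xml_add_child(model, "listOfParameters")
  for (i in seq_along(params))
    xml2::xml_add_child(pl, "parameter", id = names(params)[i],
                        value = as.character(as.numeric(params[i])),
                        constant = "true")
  for (f in c("SG", "SF"))
    xml2::xml_add_child(pl, "parameter", id = f, value = "0",
                        constant = "true")

  rl <- xml2::xml_add_child(model, "listOfReactions")
  for (r in .reaction_list) {
    rn <- xml2::xml_add_child(rl, "reaction", id = r$id, reversible = "true",
                              name = r$description)
    coefs <- vapply(r$terms, `[[`, 0, "coef")
    reac <- r$terms[coefs < 0]
    prod <- r$terms[coefs > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (tm in reac)
        xml2::xml_add_child(lr, "speciesReference", species = tm$state,
                            stoichiometry = as.character(abs(tm$coef)),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (tm in prod)
        xml2::xml_add_child(lp, "speciesReference", species = tm$state,
                            stoichiometry = as.character(tm$coef),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    expr <- .expand_expr(r$terms[[1]]$expr)
    .mathml(expr, function(tag, text = NULL) {
      nd <- xml2::xml_add_child(math, tag)
      if (!is.null(text)) xml2::xml_set_text(nd, text)
      nd
    })
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
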