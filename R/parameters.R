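# Kinetic parameter set of the four-compartment lipid metabolism model.
#
# One row per printed parameter.  `varied` marks the 78 parameters scanned
# by the FAST design (all but the three compartment volumes).  `provenance`
# records any departure from the printed value.

.param_table <- local({
  p <- function(name, value, unit, desc, varied = TRUE, prov = "printed") {
    data.frame(name = name, value = value, unit = unit, description = desc,
               varied = varied, provenance = prov, stringsAsFactors = FALSE)
  }
  rbind(
    p("alpha_A", 15.60, "L",        "adipose tissue volume", FALSE),
    p("alpha_L",  1.60, "L",        "liver tissue volume", FALSE),
    p("alpha_M", 26.4,  "L",        "skeletal muscle volume", FALSE),
    p("beta_6",  31.6,  "L/min",    "rate of liver de novo lipogenesis from pyruvate"),
    p("beta_G",   1,    "",         "listed with the varied parameter rows but lost from the printed value table; appears in no balance",
      prov = "reconstructed: nominal 1, structurally inert"),
    p("beta_f",   0.117, "mmol/min", "adipose release of triacylglycerides to non-esterified fatty acids"),
    p("beta_L",  12,    "L/min",    "liver glycogenolysis"),
    p("beta_M",  82.5,  "L/min",    "muscle glycogenolysis"),
    p("mu_amp",   1.8,  "",         "basal adenosine monophosphate/diphosphate creation rate"),
    p("mu_b",     0.133, "mmol/min", "lactate production by red blood cells"),
    p("mu_e",     0.420, "mmol/min", "muscle triglyceride breakdown to free fatty acids"),
    p("mu_s",     7.19e6, "L mmol/min", "muscle free fatty acid esterification to triglycerides"),
    p("mu_1",     0.588, "mmol/min", "plasma glucose usage"),
    p("mu_3",     7.839e7, "L mmol/min", "muscle glucose-6-phosphate usage"),
    p("mu_4",   100,    "L/min",    "muscle free fatty acid usage"),
    p("c_0",      0.1,  "mmol/L",   "small parameter (glycogen saturation width)"),
    p("c_c",      2.5,  "mmol/L",   "range of glucose concentrations over which excess insulin secretion occurs"),
    p("d_ba",     0.3,  "mmol/min", "adipose uptake of glucose"),
    p("k_10",     0.625, "mmol/L",  "affinity for hydrolysis of triglycerides to secretory pool"),
    p("k_11",    48,    "mmol/min", "basal insulin secretion rate"),
    p("k_12",     0.2,  "",         "increased fraction of VLDL1 secretion by insulin"),
    p("k_13",    15,    "mmol/L",   "rate at which insulin modifies the VLDL1-to-VLDL2 secretion fraction"),
    p("k_14",     0.6,  "",         "basal VLDL1 secretion fraction"),
    p("k_22",    48,    "mmol/min", "excess insulin secretion rate due to glucose stimulation"),
    p("k_5",      8.23e7, "1/mmol", "flux control coefficient for insulin inhibition of free fatty acid oxidation"),
    p("k_6",      0.3,  "mmol/L",   "affinity for VLDL2 triglyceride secretion through secretory pathway"),
    p("k_61",     4,    "L/min",    "liver glucose dephosphorylation rate"),
    p("k_6p",     6.56e8, "L^2/mmol min", "muscle glucose-6-phosphate to pyruvate conversion rate"),
    p("k_7",      0.759, "L/min",   "maximum rate of free fatty acid oxidation"),
    p("k_8",      0.625, "mmol/L",  "affinity for esterification of free fatty acids to triglycerides"),
    p("k_9",     43.583, "mmol/L",  "affinity of additional bulk lipidation"),
    p("k_9a",     1,    "L/min",    "release of very low-density lipoproteins from secretory pathway"),
    p("k_a",      0.1497, "L/min",  "adipose free fatty acid uptake of chylomicron triglycerides, insulin independent"),
    p("k_aa",     3.11e5, "L^2/mmol min", "adipose free fatty acid esterification to triglycerides"),
    p("k_ai",     2.08e6, "1/mmol", "adipose free fatty acid uptake of chylomicron triglycerides, insulin dependent"),
    p("k_al",     0.00002, "L^2/mmol min", "pyruvate to acetyl coenzyme A conversion rate"),
    p("k_ba",     0.0104, "L/min",  "adipose uptake of endogenous lipoprotein triglycerides"),
    p("k_bl",     0.156, "L/min",   "liver uptake of plasma non-esterified fatty acids"),
    p("k_bm",     0.226, "L/min",   "muscle uptake of plasma non-esterified fatty acids"),
    p("k_cl",     0.0075, "L/min",  "liver free fatty acid uptake of chylomicron triglycerides"),
    p("k_cm",     0.0449, "L/min",  "muscle free fatty acid uptake of chylomicron triglycerides"),
    p("k_d",      1.733e14, "L/mmol", "insulin degradation rate"),
    p("k_dl",     3.5e8, "mmol/L",  "liver glycogenolysis; insulin-inhibited rate",
      prov = "printed 3.5 x 18^8; corrected to 3.5 x 10^8"),
    p("k_dy",     4e8,  "L/mmol",   "muscle glycogenolysis; insulin-inhibited rate"),
    p("k_ft",     1.67e14, "L/mmol", "adipose release of triglyceride to non-esterified fatty acids; insulin-inhibited rate"),
    p("k_ga",     1.67e6, "",       "rate of glucose diffusion between plasma and adipose mediated by GLUT4"),
    p("k_gi",     2.632e8, "mmol/L", "glucose diffusion between plasma and muscles, insulin-mediated"),
    p("k_gl",     0.9277, "mmol/L", "plasma glucose diffusion rate to liver"),
    p("k_gl2",    0.396, "mmol/L",  "liver glucose diffusion rate to blood"),
    p("k_gm",     0.0380, "mmol/L", "plasma glucose diffusion rate to muscle"),
    p("k_gm2",    0.0380, "mmol/L", "muscle glucose diffusion rate to plasma"),
    p("k_gp",     0.311, "L/min",   "glucose-6-phosphate uptake from adipose glycerol"),
    p("k_lp",     0.25, "",         "rate of plasma triglyceride uptake by adipose tissue"),
    p("k_LG",     8.95, "mmol/L",   "Michaelis-Menten constant of glucokinase in liver"),
    p("k_LH",     0.0115, "mmol/L", "Michaelis-Menten constant of hexokinase in liver"),
    p("k_MH",     8.98, "mmol/L",   "Michaelis-Menten constant of hexokinase in muscle"),
    p("k_na",     0.0697, "L/min",  "rate of plasma free fatty acid uptake into adipose free fatty acids"),
    p("k_p",      1.41e7, "mmol/L", "rate of insulin-mediated glucose-6-phosphate to pyruvate"),
    p("k_p6",     6.56e8, "L^2/mmol min", "constant of pyruvate conversion to glucose-6-phosphate"),
    p("k_pp",     0.5,  "",         "rate of muscle pyruvate transport to liver"),
    p("k_r",      0.00058, "mmol",  "rate of endogenously derived lipoprotein triglycerides by liver as free fatty acids"),
    p("k_rep",    2.98, "mmol/L",   "glucose-6-phosphate inhibition constant of hexokinase"),
    p("k_t",      0.00348, "mmol/L", "uptake rate of plasma endogenous triglycerides into muscle free fatty acids"),
    p("k_yl",     1.28e6, "",       "rate of glycogen synthesis stimulated by insulin (liver)"),
    p("k_ym",    21.3641, "mmol/L", "glycogen synthesis rate (muscle)"),
    p("l_max",  400,    "mmol",     "maximum glycogen store of liver"),
    p("m_max",  100,    "mmol",     "maximum glycogen concentration (muscle)"),
    p("v",        7,    "mmol",     "glucose threshold of excess insulin secretion (figure rows: v_min)"),
    p("v_10",     0.1,  "mmol/min", "rate of triglyceride storage conversion to free fatty acids"),
    p("v_12",    40,    "mmol/L",   "constant in triglyceride release into plasma"),
    p("v_6",      0.0158, "mmol/L", "rate of liver free fatty acid input to secretory pool"),
    p("v_8",      0.333, "mmol/min", "rate of free fatty acid input to storage pool"),
    p("v_9",      0.0159, "mmol/L", "rate of triglyceride release into plasma"),
    p("v_LG",    14.3,  "mmol/min", "maximum rate of glucokinase in liver"),
    p("v_LH",     5.57, "mmol/min", "maximum rate of hexokinase in liver"),
    p("v_MH",    54.288, "mmol/min", "muscle hexokinase maximum rate"),
    p("y_0",      0.1,  "",         "range of liver glycogen concentration over which release drops to zero"),
    p("alpha_G",  2,    "mmol",     "rate of glucose change in diet (exponential meal forcing)"),
    p("alpha_F",  2,    "mmol/L",   "rate of fructose change in diet (exponential meal forcing)"),
    p("m_s",      0.8,  "",         "insulin-dependent rate of muscle storage of free fatty acids as triglycerides"),
    p("m_e",      0.9,  "",         "rate of muscle triglyceride breakdown to free fatty acids")
  )
})

# Row order of the published sensitivity heatmaps for the 78 varied
# parameters (aliases: mu_2 -> mu_b, k_6l -> k_61, k_re -> k_rep,
# v_min -> v).
.fast_row_order <- c(
  "beta_G", "beta_6", "beta_f", "beta_L", "beta_M",
  "mu_amp", "mu_e", "mu_s", "mu_1", "mu_b", "mu_3", "mu_4",
  "c_0", "c_c", "d_ba",
  "k_10", "k_11", "k_12", "k_13", "k_14", "k_22",
  "k_5", "k_6", "k_61", "k_6p", "k_7", "k_8", "k_9", "k_9a",
  "k_a", "k_aa", "k_ai", "k_al", "k_ba", "k_bl", "k_bm", "k_cl", "k_cm",
  "k_d", "k_dl", "k_dy", "k_ft", "k_ga", "k_gi",
  "k_gl", "k_gl2", "k_gm", "k_gm2", "k_gp", "k_lp",
  "k_LG", "k_LH", "k_MH",
  "k_na", "k_p", "k_p6", "k_pp", "k_r", "k_rep", "k_t", "k_yl", "k_ym",
  "l_max", "m_max", "v",
  "v_10", "v_12", "v_6", "v_8", "v_9",
  "v_LG", "v_LH", "v_MH",
  "y_0", "alpha_G", "alpha_F", "m_s", "m_e"
)

#' Nominal kinetic parameters of the lipid metabolism model
#'
#' Returns the 81 named kinetic constants of the whole-body hepatic lipid
#' metabolism model at their published nominal values.  Values are kept
#' exactly as printed (including physiologically extreme magnitudes such as
#' the insulin degradation rate); documented corrections and
#' reconstructions are recorded in the `provenance` column of
#' [parameter_info()].
#'
#' @param overrides optional named numeric vector (or list) of parameter
#'   values replacing the nominal ones, e.g. `c(beta_L = 6)`.  Unknown
#'   names are an error.
#' @return A named numeric vector of length 81 with class
#'   `"lipid_parameters"`.
#' @seealso [parameter_info()], [fast_parameter_names()]
#' @examples
#' p <- default_parameters()
#' p[["beta_L"]]   # liver glycogenolysis, L/min
#' p2 <- default_parameters(overrides = c(k_11 = 24))
#' @export
default_parameters <- function(overrides = NULL) {
  par <- stats::setNames(.param_table$value, .param_table$name)
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), names(par))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    par[names(overrides)] <- as.numeric(overrides)
  }
  class(par) <- "lipid_parameters"
  par
}

#' @export
print.lipid_parameters <- function(x, ...) {
  cat("Lipid metabolism model parameters:", length(x), "entries,",
      sum(parameter_info()$varied), "varied in FAST\n")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Parameter metadata
#'
#' Units, plain-language descriptions, the FAST `varied` flag and value
#' provenance for every model parameter.
#'
#' @return A data frame with columns `name`, `value`, `unit`,
#'   `description`, `varied`, `provenance`.
#' @export
parameter_info <- function() .param_table

#' Names of the parameters varied by the FAST design
#'
#' The 78 kinetic constants scanned by the sensitivity design, in the row
#' order of the published heatmaps.  The three compartment volumes are held
#' at nominal.
#'
#' @return Character vector of length 78.
#' @export
fast_parameter_names <- function() .fast_row_order

#' Write / read a parameter set as flat YAML
#'
#' Values are serialized with 17 significant digits so a write-read round
#' trip is bit-exact.  Units and provenance notes travel alongside under a
#' `meta` key.
#'
#' @param params a `lipid_parameters` vector.
#' @param path file path.
#' @rdname parameter_io
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "lipid_parameters"))
  info <- parameter_info()
  out <- list(
    values = as.list(stats::setNames(
      vapply(as.numeric(params), function(v) sprintf("%.17g", v), ""),
      names(params))),
    meta = stats::setNames(
      lapply(seq_len(nrow(info)), function(i)
        list(unit = info$unit[i], provenance = info$provenance[i])),
      info$name)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname parameter_io
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  vals <- vapply(raw$values, function(v) as.numeric(v), 0)
  default_parameters(overrides = vals)
}
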