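# Stiff integration of the model and extraction of observables.

.forcing_parms <- function(forcing) {
  if (forcing$mode == "bolus") c(0, 1, 0, 1)
  else c(forcing$glucose_amplitude, forcing$alpha_G,
         forcing$fat_amplitude, forcing$alpha_F)
}

# Minimal-overhead compiled integration used by the FAST loop.  Returns
# the deSolve matrix with an attribute `attempt` (which cascade stage
# succeeded), or NULL if every stage failed or produced non-finite
# values.
#
# Log-scanning Michaelis constants while states swing negative creates
# repulsive flux singularities (denominator K + X -> 0) that collapse
# lsoda's step size for a sizeable minority of parameter draws; vode's
# step control copes with most of those barriers, and slightly relaxed
# tolerances with radau catch nearly all of the rest.  The cascade keeps
# the primary solver and tolerances for every sample that admits them.
.integrate_raw <- function(parms_vec, init, times, rtol, atol) {
  stages <- list(
    list(method = "lsoda", rtol = rtol, atol = atol, maxsteps = 10000),
    list(method = "vode", rtol = rtol, atol = atol, maxsteps = 10000),
    list(method = "vode", rtol = rtol * 100, atol = atol * 100,
         maxsteps = 50000),
    list(method = "radau", rtol = rtol * 100, atol = atol * 100,
         maxsteps = 50000))
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    log <- utils::capture.output(
      out <- try(suppressWarnings(deSolve::ode(
        y = init, times = times, func = "lipid_derivs",
        parms = parms_vec, dllname = "lipidfast",
        initfunc = "lipid_initmod", method = st$method, rtol = st$rtol,
        atol = st$atol, maxsteps = st$maxsteps)), silent = TRUE))
    if (!inherits(out, "try-error") && nrow(out) == length(times) &&
        all(is.finite(out))) {
      attr(out, "attempt") <- k
      return(out)
    }
  }
  NULL
}

#' Integrate the model for one scenario
#'
#' Solves the 23 balance equations with a stiff-capable variable-order
#' solver.  The printed rate constants span roughly twenty orders of
#' magnitude, so a stiff method and tight tolerances are the default;
#' negative state excursions are reported as a diagnostic, never clipped.
#'
#' @param params a [default_parameters()] vector.
#' @param init named initial state (see [initial_state()]).
#' @param times strictly increasing output grid starting at 0 (min).
#' @param forcing a [meal_forcing()].
#' @param method deSolve method; `"lsoda"` (default), `"bdf"` and
#'   `"radau"` are all stiff-capable.
#' @param rtol,atol solver tolerances.
#' @param engine `"compiled"` (C right-hand side; default) or `"R"` (the
#'   reference implementation in [evaluate_rhs()]).
#' @return A `lipid_trajectory`: list with `times`, `state` (matrix,
#'   time by 23), `params`, `forcing`, `solver` metadata and a
#'   `diagnostics` list (negative excursion summary).
#' @examples
#' tr <- integrate_model(default_parameters(),
#'                       initial_state(meal_scenario(3.2, 9.1)),
#'                       times = seq(0, 500, by = 5))
#' tr$state[tr$times == 500, "G_B"]
#' @export
integrate_model <- function(params, init, times = seq(0, 500, by = 1),
                            forcing = meal_forcing(), method = "lsoda",
                            rtol = 1e-8, atol = 1e-10,
                            engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing and start at 0")
  if (!all(is.finite(init)))
    stop("non-finite initial state component(s): ",
         paste(names(init)[!is.finite(init)], collapse = ", "))
  init <- init[.state_table$name]
  if (length(times) == 1) {
    return(structure(list(
      times = times, state = matrix(init, 1, dimnames = list(NULL, names(init))),
      params = params, forcing = forcing,
      solver = list(method = method, rtol = rtol, atol = atol, engine = engine),
      diagnostics = list(negative_excursions = integer(0))
    ), class = "lipid_trajectory"))
  }
  if (engine == "compiled") {
    parms_vec <- c(as.numeric(params), .forcing_parms(forcing))
    out <- suppressWarnings(deSolve::ode(
      y = init, times = times, func = "lipid_derivs", parms = parms_vec,
      dllname = "lipidfast", initfunc = "lipid_initmod",
      method = method, rtol = rtol, atol = atol, maxsteps = 20000))
  } else {
    rhs <- function(t, y, p) list(evaluate_rhs(y, params, t, forcing))
    out <- suppressWarnings(deSolve::ode(
      y = init, times = times, func = rhs, parms = NULL,
      method = method, rtol = rtol, atol = atol, maxsteps = 20000))
  }
  if (nrow(out) < length(times)) {
    last <- out[nrow(out), ]
    stop(sprintf(
      "solver failed at t = %.4g min; last valid state at t = %.4g (%s)",
      times[nrow(out) + 1], last[1],
      paste(sprintf("%s=%.3g", colnames(out)[-1], last[-1]), collapse = ", ")))
  }
  state <- out[, -1, drop = FALSE]
  if (!all(is.finite(state))) {
    bad <- which(rowSums(!is.finite(state)) > 0)[1]
    stop("non-finite solution values (blow-up) at t = ", out[bad, 1])
  }
  neg <- colSums(state < 0)
  traj <- structure(list(
    times = out[, 1], state = state, params = params, forcing = forcing,
    solver = list(method = method, rtol = rtol, atol = atol, engine = engine),
    diagnostics = list(negative_excursions = neg[neg > 0])
  ), class = "lipid_trajectory")
  traj
}

#' @export
print.lipid_trajectory <- function(x, ...) {
  cat("Lipid metabolism trajectory:", length(x$times), "time points over",
      max(x$times), "min;", ncol(x$state), "states\n")
  cat("solver:", x$solver$method,
      sprintf("(rtol %.0e, atol %.0e, %s engine)\n",
              x$solver$rtol, x$solver$atol, x$solver$engine))
  if (length(x$diagnostics$negative_excursions))
    cat("negative excursions in:",
        paste(names(x$diagnostics$negative_excursions), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.lipid_trajectory <- function(x, vars = c("G_B", "I", "A_B", "T_LB"),
                                  ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in vars)
    graphics::plot(x$times, x$state[, v], type = "l", xlab = "time (min)",
                   ylab = v, main = v, ...)
  invisible(x)
}

#' @export
as.data.frame.lipid_trajectory <- function(x, ...) {
  data.frame(time = rep(x$times, ncol(x$state)),
             variable = rep(colnames(x$state), each = length(x$times)),
             value = as.vector(x$state))
}

#' Simulate all meals of one or more menus
#'
#' Converts each meal into its initial-condition scenario and integrates
#' the model over the horizon.  Returns one trajectory per (menu, meal).
#'
#' @param menus a list of `lipid_menu` objects (e.g. [fixture_menus()]).
#' @param horizon simulation length (min).
#' @param dt output resolution (min).
#' @param ... passed to [integrate_model()].
#' @return Named list of `lipid_trajectory` objects
#'   (`"<menu>-<meal>"`), each tagged with its scenario in `$scenario`.
#' @export
run_meal_scenarios <- function(menus, horizon = 500, dt = 1, ...) {
  if (inherits(menus, "lipid_menu")) menus <- list(menus)
  times <- seq(0, horizon, by = dt)
  params <- default_parameters()
  out <- list()
  for (menu in menus) {
    for (sc in menu_to_scenarios(menu)) {
      tr <- integrate_model(params, initial_state(sc), times, ...)
      tr$scenario <- sc
      out[[sc$label]] <- tr
    }
  }
  out
}

#' Metabolite and reaction observables at one time point
#'
#' Interpolates the 23 state variables at `t_f` from the trajectory grid
#' and evaluates the 45 registry reaction rates on that state.
#'
#' @param trajectory a `lipid_trajectory`.
#' @param t_f time (min), within the trajectory span.
#' @return List with `metabolites` (23 values) and `reactions` (45
#'   values).
#' @export
observables_at <- function(trajectory, t_f) {
  tt <- trajectory$times
  if (t_f < min(tt) || t_f > max(tt))
    stop("t_f outside the trajectory span [", min(tt), ", ", max(tt), "]")
  st <- apply(trajectory$state, 2, function(yc)
    stats::approx(tt, yc, xout = t_f)$y)
  list(metabolites = st,
       reactions = reaction_rates(st, trajectory$params, t = t_f,
                                  forcing = trajectory$forcing))
}
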