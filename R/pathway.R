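#' GAPDH occupancy of a cell state
#'
#' The fraction of GAPDH engaged in processing G3P:
#' `busy / (busy + free)`. High occupancy leaves Rheb free to activate
#' mTORC1; free GAPDH sequesters Rheb.
#'
#' @param state Named count vector.
#' @param model The model (used to resolve the pool names).
#' @return Occupancy in `[0, 1]`.
#' @export
gapdh_occupancy <- function(state, model) {
  pools <- gapdh_pool_names(model)
  if (is.null(pools)) stop("model has no GAPDH free/busy pools")
  tot <- state[[pools["free"]]] + state[[pools["busy"]]]
  if (tot <= 0) stop("total GAPDH is zero; model misconfigured")
  state[[pools["busy"]]] / tot
}

#' mTORC1 activity from GAPDH occupancy and drug inhibition
#'
#' `a = (1 - inhibition) * g(phi)` with `g` monotone non-decreasing,
#' `g(0) = 0`, `g(1) = 1`. Fully occupied GAPDH with no drug gives full
#' activity (Rheb free to bind mTORC1); zero occupancy gives none (Rheb
#' sequestered by idle GAPDH).
#'
#' @param phi GAPDH occupancy in `[0, 1]`.
#' @param inhibition Drug inhibition fraction in `[0, 1]`.
#' @param g Monotone response function, identity by default. The compiled
#'   engine supports the power family `g(phi) = phi^gamma` via the
#'   `mtorc1` gate's `gamma` parameter.
#' @return Activity in `[0, 1]`.
#' @export
mtorc1_activity <- function(phi, inhibition = 0, g = identity) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  if (any(inhibition < 0 | inhibition > 1))
    stop("inhibition must lie in [0, 1]")
  (1 - inhibition) * g(phi)
}

#' Clamp GAPDH availability on a model
#'
#' Fixes the stated fraction of total GAPDH in the 'busy' pool for every
#' step of every subsequent run (the boundary condition used for GA
#' calibration and the sweep experiments). An experiment's own
#' `gapdh_availability` takes precedence when set.
#'
#' @param model The model.
#' @param availability Fraction in `[0, 1]`, or `NA` to remove the clamp.
#' @return The model with the clamp recorded (its initial pools also split
#'   accordingly so the state is consistent at t = 0).
#' @export
apply_gapdh_clamp <- function(model, availability) {
  if (!is.na(availability) && (availability < 0 || availability > 1))
    stop("availability must lie in [0, 1]")
  model$gapdh_clamp <- availability
  if (!is.na(availability)) {
    pools <- gapdh_pool_names(model)
    if (is.null(pools)) stop("model has no GAPDH free/busy pools to clamp")
    i_free <- match(pools["free"], model$species$name)
    i_busy <- match(pools["busy"], model$species$name)
    tot <- model$species$initial[i_free] + model$species$initial[i_busy]
    model$species$initial[i_busy] <- round(availability * tot)
    model$species$initial[i_free] <- tot - model$species$initial[i_busy]
  }
  model
}

#' IRS1/3 degradation rate under mTORC1/S6K feedback
#'
#' The mTORC1/S6K negative-feedback loop accelerates degradation of the
#' insulin receptor substrates: `rate = base_rate * (1 + beta * a)`,
#' monotone increasing in the activity `a`.
#'
#' @param a mTORC1 activity in `[0, 1]`.
#' @param base_rate Basal degradation rate (molecules/ms).
#' @param beta Feedback strength, `>= 0`.
#' @return Degradation rate.
#' @export
s6k_feedback_rate <- function(a, base_rate, beta = 0.5) {
  if (any(a < 0 | a > 1)) stop("activity must lie in [0, 1]")
  if (beta < 0) stop("beta must be >= 0")
  base_rate * (1 + beta * a)
}

#' Instantaneous glucose influx at a state
#'
#' Sum of the basal-permeability route and the GLUT4-facilitated route
#' (all reactions producing intracellular glucose from the extracellular
#' boundary pool), evaluated at the given counts.
#'
#' @param state Named count vector.
#' @param model The model.
#' @param experiment Experiment providing gate values (defaults to a basal,
#'   uninhibited one; influx reactions in the packaged model are ungated).
#' @return Influx in molecules/ms.
#' @export
glucose_influx_rate <- function(state, model,
                                experiment = experiment_spec(duration = 1)) {
  gates <- eval_gates(model, state, experiment)
  influx <- vapply(model$reactions, function(r) {
    if ("glucose_int" %in% r$products$species &&
        identical(r$substrates$species, "glucose_ext"))
      reaction_rate(r, state, gates)
    else 0
  }, numeric(1))
  sum(influx)
}

#' GLUT4 facilitation ratio of glucose influx
#'
#' Ratio of total influx with a given membrane GLUT4 pool to the influx of
#' the GLUT4-free basal route alone. The packaged model is parameterised so
#' the ratio at the fully insulin-stimulated membrane pool is 30.
#'
#' @param model The model.
#' @param membrane_count Membrane-proximal GLUT4 count at which to evaluate
#'   (default: the stimulated level of 195,000).
#' @return Dimensionless ratio.
#' @export
facilitation_ratio <- function(model, membrane_count = 195000) {
  state <- initial_state(model)
  state[["GLUT4_membrane"]] <- membrane_count
  with_glut4 <- glucose_influx_rate(state, model)
  state[["GLUT4_membrane"]] <- 0
  without <- glucose_influx_rate(state, model)
  if (without <= 0) stop("basal influx is zero; cannot form a ratio")
  with_glut4 / without
}

#' Total GLUT4 of a model
#' @param model The model.
#' @return Sum of the conserved GLUT4 pools at t = 0.
#' @export
total_glut4 <- function(model) {
  grp <- model$groups$glut4
  if (is.null(grp)) stop("model has no conserved 'glut4' group")
  sum(initial_state(model)[grp])
}
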