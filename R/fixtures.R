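#' Deterministic reference trajectories of a network
#'
#' Integrates the network's rate laws as ODEs, using the very same
#' `qs_reaction` objects and gate definitions the stochastic engine uses
#' (so oracle and engine cannot drift apart), with deSolve's adaptive
#' integrators. The large-count ensemble mean of the stochastic engine
#' converges to these trajectories.
#'
#' @param model The model.
#' @param times Numeric vector of output times (ms).
#' @param experiment An [experiment_spec()] supplying gate values; the
#'   GAPDH clamp, if set, is enforced throughout.
#' @param coefficients Optional chromosome.
#' @param method deSolve method, `"lsoda"` by default (`"rk4"` gives a
#'   classical fixed-step fourth-order integration).
#' @param ... Further arguments to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return Matrix with a `time` column and one column per species.
#' @export
ode_reference <- function(model, times,
                          experiment = experiment_spec(duration = max(times)),
                          coefficients = NULL, method = "lsoda", ...) {
  model <- set_coefficients(model, coefficients)
  boundary <- model$species$boundary
  clamp <- experiment$gapdh_availability
  if (is.na(clamp)) clamp <- model$gapdh_clamp
  if (!is.na(clamp)) {
    pools <- gapdh_pool_names(model)
    boundary <- boundary | model$species$name %in% pools
  }
  init <- initial_state(model)
  init <- clamp_gapdh(init, model, experiment)
  deriv <- function(t, y, parms) {
    names(y) <- model$species$name
    y <- clamp_gapdh(pmax(y, 0), model, experiment)
    gates <- eval_gates(model, y, experiment)
    dy <- stats::setNames(numeric(length(y)), names(y))
    for (r in model$reactions) {
      rate <- reaction_rate(r, y, gates)
      if (rate <= 0) next
      if (nrow(r$substrates))
        dy[r$substrates$species] <- dy[r$substrates$species] -
          r$substrates$stoich * rate
      if (nrow(r$products))
        dy[r$products$species] <- dy[r$products$species] +
          r$products$stoich * rate
    }
    dy[boundary] <- 0
    list(dy)
  }
  out <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                      method = method, ...)
  class(out) <- "matrix"
  out
}

#' Steady state of the deterministic reference
#'
#' Integrates to `t_end` and returns the final state.
#'
#' @inheritParams ode_reference
#' @param t_end Integration horizon in ms.
#' @return Named state vector.
#' @export
ode_steady_state <- function(model, experiment, t_end = 60000,
                             coefficients = NULL) {
  out <- ode_reference(model, times = c(0, t_end), experiment = experiment,
                       coefficients = coefficients)
  stats::setNames(out[nrow(out), -1], model$species$name)
}

#' Single Michaelis-Menten toy network
#'
#' One reaction `A -> B`; with `km >> s0` the mean of A decays
#' exponentially at rate `vmax / km`, giving a closed-form check.
#'
#' @param vmax,km MM constants.
#' @param s0 Initial A count.
#' @param noise Initial-condition noise fraction (default 0: deterministic
#'   initials, so ensembles probe the transfer dynamics alone).
#' @return A `qs_model`.
#' @export
make_single_mm <- function(vmax = 50, km = 5000, s0 = 10000, noise = 0) {
  build_network(
    species = list(qs_species("A", s0, noise = noise),
                   qs_species("B", 0, noise = noise)),
    reactions = list(qs_reaction("conv", "michaelis_menten",
                                 substrates = "A", products = "B",
                                 vmax = vmax, km = km, tunable = TRUE)),
    groups = list(ab = c("A", "B")),
    name = "single_mm")
}

#' Branching two-coefficient toy network
#'
#' `A -> B` and `A -> C`, both mass-action and tunable. The endpoint split
#' between B and C identifies the coefficient ratio and the consumed total
#' identifies their magnitude, so the pair is recoverable from endpoint
#' data — the workhorse for the GA's parameter-recovery test.
#'
#' @param k1,k2 Base rate constants.
#' @param s0 Initial A count.
#' @return A `qs_model`.
#' @export
make_branching_toy <- function(k1 = 2e-4, k2 = 1e-4, s0 = 10000) {
  build_network(
    species = list(qs_species("A", s0, noise = 0),
                   qs_species("B", 0, noise = 0),
                   qs_species("C", 0, noise = 0)),
    reactions = list(
      qs_reaction("to_b", "mass_action", substrates = "A", products = "B",
                  k = k1, tunable = TRUE),
      qs_reaction("to_c", "mass_action", substrates = "A", products = "C",
                  k = k2, tunable = TRUE)),
    groups = list(abc = c("A", "B", "C")),
    name = "branching_toy")
}
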