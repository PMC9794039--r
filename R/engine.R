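#' Specify a simulation experiment
#'
#' Bundles the boundary conditions and run settings of one in-silico
#' experiment: the insulin level applied at the receptor, the clamped GAPDH
#' availability (the fraction of GAPDH held in the 'busy' pool for the whole
#' run; `NA` lets occupancy emerge from glycolytic flux), the mTORC1
#' inhibition factor (1 = complete drug inhibition), the duration and time
#' step, the ensemble size and the root seed.
#'
#' @param insulin_level Fraction in `[0, 1]`.
#' @param gapdh_availability Fraction in `[0, 1]`, or `NA` for emergent
#'   occupancy.
#' @param mtorc1_inhibition Fraction in `[0, 1]`.
#' @param duration Run length in ms, or `NA` to run until the ensemble-mean
#'   readout is steady (see [run_ensemble()]).
#' @param dt Time increment in ms (default 1).
#' @param n_cells Ensemble size (default 50).
#' @param seed Root seed; all randomness derives from it.
#' @param record_stride Record every this-many steps (default 20).
#' @return A list of class `qs_experiment`.
#' @export
experiment_spec <- function(insulin_level = 0, gapdh_availability = NA,
                            mtorc1_inhibition = 0, duration = NA,
                            dt = 1, n_cells = 50, seed = 1,
                            record_stride = 20L) {
  frac <- function(x, nm) {
    if (!is.na(x) && (x < 0 || x > 1)) stop(nm, " must lie in [0, 1]")
    x
  }
  if (is.na(insulin_level) || is.na(mtorc1_inhibition))
    stop("insulin_level and mtorc1_inhibition must be given")
  if (!is.na(duration) && duration < dt) stop("duration must be >= dt")
  if (dt <= 0) stop("dt must be > 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  structure(list(insulin_level = frac(insulin_level, "insulin_level"),
                 gapdh_availability = frac(gapdh_availability,
                                           "gapdh_availability"),
                 mtorc1_inhibition = frac(mtorc1_inhibition,
                                          "mtorc1_inhibition"),
                 duration = duration, dt = dt, n_cells = as.integer(n_cells),
                 seed = as.integer(seed),
                 record_stride = as.integer(record_stride)),
            class = "qs_experiment")
}

# Evaluate every declared gate at a state. Returns a named numeric vector.
eval_gates <- function(model, counts, experiment) {
  pools <- gapdh_pool_names(model)
  vapply(model$gates, function(g) {
    switch(g$type,
      insulin = experiment$insulin_level,
      drug = 1 - experiment$mtorc1_inhibition,
      mtorc1 = {
        phi <- gapdh_occupancy(counts, model)
        gamma <- if (is.null(g$gamma)) 1 else g$gamma
        (1 - experiment$mtorc1_inhibition) * phi^gamma
      },
      feedback = {
        tot <- sum(counts[g$pool])
        if (tot > 0) 1 + g$beta * counts[[g$species]] / tot else 1
      },
      pool_fraction = {
        tot <- sum(counts[g$den])
        if (tot > 0) sum(counts[g$num]) / tot else 0
      },
      saturating = counts[[g$species]] / (counts[[g$species]] + g$half)
    )
  }, numeric(1))
}

#' Instantaneous rate of a reaction
#'
#' Michaelis-Menten with substrate abundance S returns
#' `coefficient * gate * (kcat * E) * S / (km + S)` (or `vmax` in place of
#' `kcat * E` without an enzyme); mass action returns
#' `coefficient * gate * k * prod(substrate counts)`. The rate is zero
#' whenever any substrate count is zero.
#'
#' @param reaction A [qs_reaction()].
#' @param state Named numeric vector of counts.
#' @param gates Named numeric vector of evaluated gate values
#'   (see `experiment_spec`; defaults to no gating).
#' @return Rate in molecules per ms.
#' @export
reaction_rate <- function(reaction, state, gates = numeric()) {
  gate <- 1
  for (gn in reaction$gates) {
    if (!gn %in% names(gates)) stop("unknown gate: ", gn)
    gate <- gate * gates[[gn]]
  }
  subs <- reaction$substrates
  missing <- setdiff(c(subs$species, reaction$products$species, reaction$enzyme),
                     names(state))
  if (length(missing))
    stop("species absent from state: ", paste(missing, collapse = ", "))
  if (reaction$law == "michaelis_menten") {
    S <- state[[subs$species]]
    if (S <= 0) return(0)
    v <- if (is.null(reaction$enzyme)) reaction$vmax
         else reaction$vmax * state[[reaction$enzyme]]
    reaction$coefficient * gate * v * S / (reaction$km + S)
  } else {
    r <- reaction$coefficient * gate * reaction$k
    if (nrow(subs)) r <- r * prod(state[subs$species]^subs$stoich)
    r
  }
}

#' Per-molecule transfer probability for one time step
#'
#' Converts a rate into the thinning probability applied to the limiting
#' substrate count, clamped so probabilities remain below 1:
#' `min(rate * dt / substrate_count, p_max)` (0 when the count is 0).
#'
#' @param rate Rate in molecules/ms.
#' @param dt Time step in ms.
#' @param substrate_count Limiting substrate count.
#' @param p_max Clamp, strictly inside (0, 1); default 0.99.
#' @return Probability in `[0, p_max]`.
#' @export
step_probability <- function(rate, dt, substrate_count, p_max = 0.99) {
  stopifnot(dt > 0, p_max > 0, p_max < 1)
  if (substrate_count <= 0) return(0)
  min(rate * dt / substrate_count, p_max)
}

#' Advance a cell state by one time step (reference implementation)
#'
#' Pure-R single step with the same semantics as the compiled engine:
#' reactions fire in declared order; each converts a binomial draw with
#' n = limiting substrate count and p = [step_probability()]; counts are
#' updated by stoichiometry and can never go negative because later
#' reactions see the already-updated counts. Zeroth-order synthesis draws
#' Poisson. Boundary species are never changed. Used in tests as a
#' cross-check of the compiled path.
#'
#' @param state Named numeric vector of counts.
#' @param model The model (reaction order is taken from it).
#' @param experiment The experiment (gates, clamp).
#' @param dt Time step in ms.
#' @param p_max Probability clamp.
#' @return The updated named count vector.
#' @export
advance <- function(state, model, experiment, dt = experiment$dt,
                    p_max = 0.99) {
  boundary <- stats::setNames(model$species$boundary, model$species$name)
  state <- clamp_gapdh(state, model, experiment)
  gates <- eval_gates(model, state, experiment)
  for (r in model$reactions) {
    rate <- reaction_rate(r, state, gates)
    if (rate <= 0) next
    if (nrow(r$substrates) == 0L) {
      n <- stats::rpois(1, rate * dt)
    } else {
      n_lim <- min(floor(state[r$substrates$species] / r$substrates$stoich))
      p <- step_probability(rate, dt, n_lim, p_max)
      if (p <= 0) next
      n <- stats::rbinom(1, n_lim, p)
    }
    if (n <= 0) next
    for (i in seq_len(nrow(r$substrates))) {
      sp <- r$substrates$species[i]
      if (!boundary[[sp]]) state[[sp]] <- state[[sp]] - r$substrates$stoich[i] * n
    }
    for (i in seq_len(nrow(r$products))) {
      sp <- r$products$species[i]
      if (!boundary[[sp]]) state[[sp]] <- state[[sp]] + r$products$stoich[i] * n
    }
  }
  state <- clamp_gapdh(state, model, experiment)
  if (any(state < 0)) stop("internal error: negative count")
  state
}

clamp_gapdh <- function(state, model, experiment) {
  phi <- experiment$gapdh_availability
  if (is.na(phi)) phi <- model$gapdh_clamp
  if (is.na(phi)) return(state)
  pools <- gapdh_pool_names(model)
  if (is.null(pools)) stop("model has no GAPDH free/busy pools to clamp")
  tot <- state[[pools["free"]]] + state[[pools["busy"]]]
  state[[pools["busy"]]] <- round(phi * tot)
  state[[pools["free"]]] <- tot - state[[pools["busy"]]]
  state
}

# Encode model + experiment for the compiled engine (0-based indices).
compile_network <- function(model, experiment) {
  idx <- function(x) match(x, model$species$name) - 1L
  gate_names <- names(model$gates)
  gates <- lapply(model$gates, function(g) {
    type <- match(g$type, c("insulin", "drug", "mtorc1", "feedback",
                            "pool_fraction", "saturating")) - 1L
    list(type = type,
         idx = as.integer(idx(c(g$species, g$num))),
         den = as.integer(idx(c(g$pool, g$den))),
         par = as.double(
           if (!is.null(g$beta)) g$beta
           else if (!is.null(g$half)) g$half
           else if (!is.null(g$gamma)) g$gamma
           else 1))
  })
  reactions <- lapply(model$reactions, function(r) {
    list(law = if (r$law == "michaelis_menten") 0L else 1L,
         sub = as.integer(idx(r$substrates$species)),
         sub_st = as.integer(r$substrates$stoich),
         prod = as.integer(idx(r$products$species)),
         prod_st = as.integer(r$products$stoich),
         enz = if (is.null(r$enzyme)) -1L else idx(r$enzyme),
         vmax = as.double(if (is.null(r$vmax)) 0 else r$vmax),
         km = as.double(if (is.null(r$km)) 1 else r$km),
         k = as.double(if (is.null(r$k)) 0 else r$k),
         coef = as.double(r$coefficient),
         gates = as.integer(match(r$gates, gate_names) - 1L))
  })
  pools <- gapdh_pool_names(model)
  clamp <- experiment$gapdh_availability
  if (is.na(clamp)) clamp <- model$gapdh_clamp
  list(reactions = reactions, gates = gates,
       boundary = model$species$boundary,
       clamp = if (is.na(clamp)) -1 else clamp,
       gapdh_free = if (is.null(pools)) 0L else idx(pools["free"]),
       gapdh_busy = if (is.null(pools)) 0L else idx(pools["busy"]))
}

#' Simulate a single cell
#'
#' Runs the compiled discrete-time engine from the model's initial state (or
#' a supplied one) for `duration` ms. Reproducible: the trace is a pure
#' function of the initial state, the model and the seed.
#'
#' @param model The model.
#' @param experiment The [experiment_spec()]; `duration` must be set.
#' @param init Optional named initial count vector (defaults to the model's).
#' @param coefficients Optional chromosome applied via [set_coefficients()].
#' @param seed Seed for this cell (defaults to `experiment$seed`).
#' @param p_max Probability clamp (default 0.99). When any per-step
#'   probability hits the clamp a warning is issued once per run; results
#'   remain valid but a smaller `dt` is advisable.
#' @return A `qs_trace`: list with `times` (ms), `counts`
#'   (time x species matrix), `dt`, `seed`.
#' @export
simulate_cell <- function(model, experiment, init = NULL,
                          coefficients = NULL, seed = experiment$seed,
                          p_max = 0.99) {
  model <- set_coefficients(model, coefficients)
  if (is.na(experiment$duration))
    stop("simulate_cell needs a fixed duration; use run_ensemble for ",
         "steady-state-terminated runs")
  if (is.null(init)) init <- initial_state(model)
  init <- init[model$species$name]
  enc <- compile_network(model, experiment)
  n_steps <- as.integer(ceiling(experiment$duration / experiment$dt))
  set.seed(seed)
  res <- sim_cell_cpp(as.numeric(init), enc$reactions, enc$gates,
                      enc$boundary, experiment$dt, n_steps,
                      experiment$record_stride,
                      experiment$insulin_level, experiment$mtorc1_inhibition,
                      enc$clamp, enc$gapdh_free, enc$gapdh_busy, p_max)
  if (res$clamped)
    warning("per-step probability hit p_max = ", p_max,
            "; consider a smaller dt", call. = FALSE)
  counts <- res$counts[seq_len(res$n_recorded), , drop = FALSE]
  colnames(counts) <- model$species$name
  structure(list(times = res$times[seq_len(res$n_recorded)], counts = counts,
                 dt = experiment$dt, seed = seed),
            class = "qs_trace")
}

#' @export
print.qs_trace <- function(x, ...) {
  cat("<qs_trace> ", length(x$times), " recorded points over ",
      max(x$times), " ms (dt = ", x$dt, " ms, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.qs_trace <- function(x, species = colnames(x$counts), ...) {
  graphics::matplot(x$times, x$counts[, species, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (ms)", ylab = "molecules", ...)
  graphics::legend("topleft", legend = species, lty = 1,
                   col = seq_along(species), cex = 0.7, bty = "n")
  invisible(x)
}

#' Detect steady state in a trace
#'
#' Splits the series into consecutive non-overlapping windows and reports
#' the earliest time at which the windowed mean changes by less than `tol`
#' (relative) from the previous window.
#'
#' @param trace A `qs_trace`, or any list with `times` and a `counts` matrix.
#' @param species Species to test.
#' @param window Window length in ms.
#' @param tol Relative tolerance between consecutive windowed means.
#' @return List with `steady` (logical) and `time` (ms at which the
#'   criterion first held, or `NA`).
#' @export
detect_steady_state <- function(trace, species, window, tol = 0.01) {
  if (!species %in% colnames(trace$counts)) stop("no such species: ", species)
  times <- trace$times
  if (max(times) < 2 * window) stop("trace shorter than two windows")
  x <- trace$counts[, species]
  bins <- floor(times / window)
  m <- tapply(x, bins, mean)
  if (length(m) < 2) return(list(steady = FALSE, time = NA_real_))
  for (i in 2:length(m)) {
    ref <- max(abs(m[i - 1]), .Machine$double.eps)
    if (abs(m[i] - m[i - 1]) / ref < tol)
      return(list(steady = TRUE, time = as.numeric(names(m)[i]) * window))
  }
  list(steady = FALSE, time = NA_real_)
}
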