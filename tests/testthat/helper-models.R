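# Shared fixtures: tiny networks and cached heavyweight runs.

# Two-pool exchange with a conserved group; analytic steady state x/y = k1/k2.
two_pool_model <- function(k1 = 2e-3, k2 = 1e-3, x0 = 6000, y0 = 4000,
                           noise = 0) {
  build_network(
    species = list(qs_species("X", x0, noise = noise),
                   qs_species("Y", y0, noise = noise)),
    reactions = list(
      qs_reaction("fwd", "mass_action", substrates = "X", products = "Y",
                  k = k1),
      qs_reaction("rev", "mass_action", substrates = "Y", products = "X",
                  k = k2)),
    groups = list(xy = c("X", "Y")),
    name = "two_pool")
}

glut4_groups <- function(model) {
  lapply(model$groups, function(g) g)
}

group_totals <- function(counts, model) {
  vapply(model$groups, function(g) sum(counts[g]), numeric(1))
}

# Heavy ensembles shared across acceptance checks, computed once per run.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

basal_ensemble <- function() cached("basal", {
  run_ensemble(default_model(),
               experiment_spec(insulin_level = 0, gapdh_availability = 0,
                               seed = 101))
})

stimulated_ensemble <- function() cached("stim", {
  run_ensemble(default_model(),
               experiment_spec(insulin_level = 1, gapdh_availability = 1,
                               mtorc1_inhibition = 0, seed = 101))
})
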