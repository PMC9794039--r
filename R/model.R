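#' Declare a molecular species queue
#'
#' A species is a non-negative integer queue of molecules. The per-cell
#' initial abundance is perturbed with Gaussian noise of standard deviation
#' `noise * initial` when ensembles are generated (see [perturb_initials()]).
#'
#' @param name Species identifier.
#' @param initial Initial abundance (molecules per cell), non-negative.
#' @param noise Fraction of `initial` used as the Gaussian SD (default 0.10).
#' @param boundary Logical; boundary species are held constant (never
#'   incremented or decremented by reactions), e.g. extracellular glucose.
#' @return A list of class `qs_species`.
#' @export
qs_species <- function(name, initial, noise = 0.10, boundary = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(initial) || length(initial) != 1L || initial < 0)
    stop("species '", name, "': initial abundance must be a non-negative number")
  if (!is.numeric(noise) || noise < 0 || noise > 1)
    stop("species '", name, "': noise fraction must lie in [0, 1]")
  structure(list(name = name, initial = round(initial), noise = noise,
                 boundary = isTRUE(boundary)),
            class = "qs_species")
}

#' Declare a reaction between species queues
#'
#' A reaction moves molecules between queues under either Michaelis-Menten
#' kinetics (`vmax`/`km`, optionally scaled by an enzyme queue via `kcat`)
#' or mass action (`k`). The dimensionless `coefficient` is the linear
#' scaling the genetic algorithm tunes when `tunable = TRUE`; `gates` names
#' multiplicative modifiers declared in the model (e.g. `"insulin_level"`,
#' `"mtorc1_activity"`).
#'
#' @param id Reaction identifier.
#' @param law `"michaelis_menten"` or `"mass_action"`.
#' @param substrates,products Character vectors of species names, or named
#'   integer vectors giving stoichiometries (e.g. `c(G3P = 1, GAPDH_free = 1)`).
#'   Either may be empty (pure synthesis or degradation).
#' @param enzyme Optional catalysing species (not consumed); with an enzyme,
#'   `vmax` is read as a kcat (per enzyme molecule per ms).
#' @param vmax,km Michaelis-Menten maximal rate (molecules/ms, or kcat /ms)
#'   and half-saturation abundance (molecules).
#' @param k Mass-action rate constant.
#' @param coefficient Dimensionless linear scale, default 1.
#' @param tunable Whether the GA may scale this reaction.
#' @param gates Character vector of gate names.
#' @return A list of class `qs_reaction`.
#' @export
qs_reaction <- function(id, law = c("michaelis_menten", "mass_action"),
                        substrates = character(), products = character(),
                        enzyme = NULL, vmax = NULL, km = NULL, k = NULL,
                        coefficient = 1, tunable = FALSE, gates = character()) {
  law <- match.arg(law)
  as_stoich <- function(x, what) {
    if (is.null(x) || length(x) == 0L)
      return(data.frame(species = character(), stoich = integer()))
    if (is.character(x)) x <- stats::setNames(rep(1L, length(x)), x)
    if (is.null(names(x)) || any(!nzchar(names(x))) || any(x < 1))
      stop("reaction '", id, "': malformed ", what)
    data.frame(species = names(x), stoich = as.integer(x))
  }
  substrates <- as_stoich(substrates, "substrates")
  products <- as_stoich(products, "products")
  if (law == "michaelis_menten") {
    if (is.null(vmax) || is.null(km))
      stop("reaction '", id, "': michaelis_menten requires vmax (or kcat) and km")
    if (vmax < 0) stop("reaction '", id, "': vmax must be >= 0")
    if (km <= 0) stop("reaction '", id, "': km must be > 0")
    if (nrow(substrates) != 1L)
      stop("reaction '", id, "': michaelis_menten requires exactly one substrate")
  } else {
    if (is.null(k)) stop("reaction '", id, "': mass_action requires k")
    if (k < 0) stop("reaction '", id, "': k must be >= 0")
    if (!is.null(enzyme)) stop("reaction '", id, "': mass_action takes no enzyme")
  }
  if (coefficient < 0) stop("reaction '", id, "': coefficient must be >= 0")
  structure(list(id = id, law = law, substrates = substrates,
                 products = products, enzyme = enzyme,
                 vmax = vmax, km = km, k = k,
                 coefficient = coefficient, tunable = isTRUE(tunable),
                 gates = as.character(gates)),
            class = "qs_reaction")
}

#' Assemble and validate a pathway model
#'
#' Checks that every species referenced by a reaction, gate or conserved
#' group is declared, that kinetic constants are admissible, and that the
#' GAPDH free/busy pools exist whenever a `mtorc1_activity` gate or an
#' occupancy clamp will be used.
#'
#' @param species List of [qs_species()] objects.
#' @param reactions List of [qs_reaction()] objects (order matters: within a
#'   time step reactions are applied in this order, each capped by the
#'   remaining substrate counts).
#' @param groups Named list of character vectors; each group's total count is
#'   conserved and asserted by the engine's bookkeeping.
#' @param gates Named list of gate definitions; each is a list with a `type`
#'   in `insulin`, `drug`, `mtorc1`, `feedback`, `pool_fraction`, `saturating`
#'   plus its parameters (see the packaged config for examples).
#' @param name Model name.
#' @param cell_volume_pl Cell volume in picolitres, used to convert molar
#'   concentrations to counts when a config supplies `initial_nM`.
#' @return A list of class `qs_model`.
#' @export
build_network <- function(species, reactions, groups = list(),
                          gates = list(), name = "model",
                          cell_volume_pl = 1.0) {
  stopifnot(length(species) > 0)
  sp <- do.call(rbind, lapply(species, function(s) {
    stopifnot(inherits(s, "qs_species"))
    data.frame(name = s$name, initial = s$initial, noise = s$noise,
               boundary = s$boundary)
  }))
  if (anyDuplicated(sp$name))
    stop("duplicated species name: ",
         paste(unique(sp$name[duplicated(sp$name)]), collapse = ", "))
  known <- sp$name

  check_species <- function(x, where) {
    bad <- setdiff(x, known)
    if (length(bad))
      stop(where, ": unknown species ", paste(bad, collapse = ", "))
  }
  for (g in names(groups)) check_species(groups[[g]], paste0("group '", g, "'"))
  for (gn in names(gates)) {
    g <- gates[[gn]]
    if (is.null(g$type) ||
        !g$type %in% c("insulin", "drug", "mtorc1", "feedback",
                       "pool_fraction", "saturating"))
      stop("gate '", gn, "': unknown type '", g$type, "'")
    check_species(c(g$species, g$num, g$den, g$pool), paste0("gate '", gn, "'"))
    if (g$type == "feedback" && (is.null(g$beta) || g$beta < 0))
      stop("gate '", gn, "': feedback requires beta >= 0")
    if (g$type == "saturating" && (is.null(g$half) || g$half <= 0))
      stop("gate '", gn, "': saturating requires half > 0")
  }
  ids <- character()
  for (r in reactions) {
    stopifnot(inherits(r, "qs_reaction"))
    if (r$id %in% ids) stop("duplicated reaction id: ", r$id)
    ids <- c(ids, r$id)
    check_species(c(r$substrates$species, r$products$species, r$enzyme),
                  paste0("reaction '", r$id, "'"))
    bad <- setdiff(r$gates, names(gates))
    if (length(bad))
      stop("reaction '", r$id, "': unknown gate ", paste(bad, collapse = ", "))
  }

  model <- structure(list(name = name, cell_volume_pl = cell_volume_pl,
                          species = sp, reactions = reactions,
                          groups = groups, gates = gates,
                          gapdh_clamp = NA_real_),
                     class = "qs_model")
  uses_mtorc1 <- any(vapply(gates, function(g) g$type == "mtorc1", logical(1)))
  if (uses_mtorc1 && is.null(gapdh_pool_names(model)))
    stop("a 'mtorc1' gate requires GAPDH_free and GAPDH_busy species ",
         "(or a conserved group named 'gapdh' with two members)")
  model
}

# Resolve the (free, busy) GAPDH pool names, preferring a 'gapdh' group.
gapdh_pool_names <- function(model) {
  if (!is.null(model$groups$gapdh) && length(model$groups$gapdh) == 2L) {
    g <- model$groups$gapdh
    free <- grep("free", g, ignore.case = TRUE, value = TRUE)
    busy <- setdiff(g, free)
    if (length(free) == 1L && length(busy) == 1L)
      return(c(free = free, busy = busy))
  }
  if (all(c("GAPDH_free", "GAPDH_busy") %in% model$species$name))
    return(c(free = "GAPDH_free", busy = "GAPDH_busy"))
  NULL
}

#' Initial state of a model
#'
#' @param model A [build_network()] model.
#' @return Named numeric vector of initial counts.
#' @export
initial_state <- function(model) {
  stats::setNames(model$species$initial, model$species$name)
}

#' @export
print.qs_model <- function(x, ...) {
  cat("<qs_model> ", x$name, "\n", sep = "")
  cat("  species:   ", nrow(x$species),
      " (", sum(x$species$boundary), " boundary)\n", sep = "")
  cat("  reactions: ", length(x$reactions),
      " (", sum(vapply(x$reactions, `[[`, logical(1), "tunable")),
      " tunable)\n", sep = "")
  if (length(x$groups))
    cat("  conserved: ", paste(names(x$groups), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Names of the GA-tunable reactions, in declaration order
#' @param model A model.
#' @return Character vector of reaction ids.
#' @export
tunable_reactions <- function(model) {
  ids <- vapply(model$reactions, `[[`, character(1), "id")
  ids[vapply(model$reactions, `[[`, logical(1), "tunable")]
}

#' Apply a chromosome of scaling coefficients to a model
#'
#' @param model A model.
#' @param coefficients Named numeric vector (names = tunable reaction ids) or
#'   an unnamed vector in [tunable_reactions()] order.
#' @return The model with reaction coefficients replaced.
#' @export
set_coefficients <- function(model, coefficients) {
  if (is.null(coefficients)) return(model)
  tun <- tunable_reactions(model)
  if (is.null(names(coefficients))) {
    if (length(coefficients) != length(tun))
      stop("expected ", length(tun), " coefficients, got ", length(coefficients))
    names(coefficients) <- tun
  }
  bad <- setdiff(names(coefficients), tun)
  if (length(bad)) stop("not tunable: ", paste(bad, collapse = ", "))
  if (any(coefficients < 0)) stop("coefficients must be >= 0")
  model$reactions <- lapply(model$reactions, function(r) {
    if (r$id %in% names(coefficients)) r$coefficient <- coefficients[[r$id]]
    r
  })
  model
}
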