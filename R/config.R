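#' Load a pathway model from a YAML or JSON configuration
#'
#' The configuration declares `species:`, `reactions:`, `conserved_groups:`
#' and `gates:` sections (see the packaged `adipocyte_insulin.yaml`).
#' Initial abundances may be given directly in molecules (`initial:`) or as
#' a nanomolar concentration (`initial_nM:`), which is converted to a count
#' using the top-level `cell_volume_pl:` (1 nM in 1 pL is ~602 molecules).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [build_network()] model.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  model_from_list(cfg)
}

#' @rdname load_config
#' @param cfg A configuration as a nested list (the parsed YAML/JSON).
#' @export
model_from_list <- function(cfg) {
  vol <- if (is.null(cfg$cell_volume_pl)) 1.0 else as.numeric(cfg$cell_volume_pl)
  species <- lapply(cfg$species, function(s) {
    if (is.null(s$name)) stop("species entry without a name")
    init <- s[["initial"]]
    if (is.null(init)) {
      if (is.null(s[["initial_nM"]]))
        stop("species '", s$name, "': needs initial or initial_nM")
      init <- nM_to_count(as.numeric(s[["initial_nM"]]), vol)
    }
    qs_species(s$name, as.numeric(init),
               noise = if (is.null(s$noise)) 0.10 else as.numeric(s$noise),
               boundary = isTRUE(s$boundary))
  })
  reactions <- lapply(cfg$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry without an id")
    vmax <- r$vmax
    if (is.null(vmax)) vmax <- r$kcat
    qs_reaction(r$id, law = r$law,
                substrates = stoich_from_cfg(r$substrates),
                products = stoich_from_cfg(r$products),
                enzyme = r$enzyme,
                vmax = null2num(vmax), km = null2num(r$km), k = null2num(r$k),
                coefficient = if (is.null(r$coefficient)) 1
                              else as.numeric(r$coefficient),
                tunable = isTRUE(r$tunable),
                gates = as.character(unlist(r$gates)))
  })
  groups <- lapply(cfg$conserved_groups, function(g) as.character(unlist(g)))
  gates <- lapply(cfg$gates, function(g) {
    g[c("species", "num", "den", "pool")] <-
      lapply(g[c("species", "num", "den", "pool")],
             function(x) if (is.null(x)) NULL else as.character(unlist(x)))
    g
  })
  build_network(species, reactions, groups = groups, gates = gates,
                name = if (is.null(cfg$name)) "model" else cfg$name,
                cell_volume_pl = vol)
}

null2num <- function(x) if (is.null(x)) NULL else as.numeric(x)

stoich_from_cfg <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character())
  x <- unlist(x)
  if (is.null(names(x)) || !any(nzchar(names(x)))) return(as.character(x))
  stats::setNames(as.integer(x), names(x))
}

#' Convert a nanomolar concentration to a molecule count
#'
#' @param nM Concentration in nmol/L.
#' @param cell_volume_pl Cell volume in picolitres.
#' @return Molecule count (rounded).
#' @export
nM_to_count <- function(nM, cell_volume_pl = 1.0) {
  round(nM * 1e-9 * 6.02214076e23 * cell_volume_pl * 1e-12)
}

#' Serialize a model back to a configuration list
#'
#' `model_to_list()` inverts [model_from_list()]; writing the result with
#' [yaml::write_yaml()] and re-loading reproduces an identical network.
#'
#' @param model A model.
#' @return A nested list mirroring the YAML schema.
#' @export
model_to_list <- function(model) {
  list(
    name = model$name,
    cell_volume_pl = model$cell_volume_pl,
    species = lapply(seq_len(nrow(model$species)), function(i) {
      s <- model$species[i, ]
      out <- list(name = s$name, initial = s$initial, noise = s$noise)
      if (s$boundary) out$boundary <- TRUE
      out
    }),
    conserved_groups = model$groups,
    gates = model$gates,
    reactions = lapply(model$reactions, function(r) {
      out <- list(id = r$id, law = r$law)
      if (nrow(r$substrates))
        out$substrates <- stats::setNames(as.list(r$substrates$stoich),
                                          r$substrates$species)
      if (nrow(r$products))
        out$products <- stats::setNames(as.list(r$products$stoich),
                                        r$products$species)
      if (!is.null(r$enzyme)) out$enzyme <- r$enzyme
      if (!is.null(r$vmax)) out[[if (is.null(r$enzyme)) "vmax" else "kcat"]] <- r$vmax
      if (!is.null(r$km)) out$km <- r$km
      if (!is.null(r$k)) out$k <- r$k
      if (r$coefficient != 1) out$coefficient <- r$coefficient
      if (r$tunable) out$tunable <- TRUE
      if (length(r$gates)) out$gates <- as.list(r$gates)
      out
    })
  )
}

#' The packaged adipocyte insulin-response model
#'
#' Loads the default network: insulin receptor activation, IRS1/3, PI3K,
#' PIP2/PIP3, PDK1- and mTORC2-driven Akt activation, AS160-mediated GLUT4
#' mobilization and translocation, glucose influx, a glycolysis fragment
#' with GAPDH, Rheb sequestration, mTORC1/S6K and the negative feedback on
#' IRS1/3.
#'
#' @return A `qs_model`.
#' @export
default_model <- function() {
  load_config(system.file("extdata", "adipocyte_insulin.yaml",
                          package = "qsignal", mustWork = TRUE))
}

#' A stable hash of a model configuration
#'
#' Two independent 45-bit polynomial rolling hashes over the canonical YAML
#' serialization; used in run manifests so outputs can be traced back to the
#' exact configuration.
#'
#' @param model A model.
#' @return Hex string.
#' @export
config_hash <- function(model) {
  txt <- yaml::as.yaml(model_to_list(model))
  bytes <- utf8ToInt(txt)
  roll <- function(mult) {
    h <- 2166136261
    for (b in bytes) h <- (h * mult + b) %% 2^45
    sprintf("%06x%06x", floor(h / 2^24), h %% 2^24)
  }
  paste0(roll(31), roll(131))
}

#' Write a run manifest next to an output file
#'
#' @param model Model used for the run.
#' @param experiment The [experiment_spec()].
#' @param path Output JSON path.
#' @return The manifest, invisibly.
#' @export
write_manifest <- function(model, experiment, path) {
  m <- list(config_hash = config_hash(model),
            model = model$name,
            seed = experiment$seed, dt = experiment$dt,
            duration = experiment$duration, n_cells = experiment$n_cells,
            insulin_level = experiment$insulin_level,
            gapdh_availability = experiment$gapdh_availability,
            mtorc1_inhibition = experiment$mtorc1_inhibition,
            package_version = as.character(utils::packageVersion("qsignal")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(m)
}

#' Write a simulation trace as CSV
#'
#' Header is `time_ms,<species...>`; one row per recorded step.
#'
#' @param trace A `qs_trace`.
#' @param path Output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_ms = trace$times, trace$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
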