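# Per-cell (and per-chunk) seeds derived arithmetically from the root seed,
# so cells are reproducible and independent of execution order.
derive_seed <- function(root, cell, chunk = 0L) {
  as.integer((as.double(root) * 48271 + cell * 9349 + chunk * 6007) %%
               2147483629)
}

#' Draw noisy initial conditions for one cell
#'
#' Each initial count is drawn Gaussian with mean the declared abundance and
#' SD `noise * abundance`, rounded and truncated at zero; boundary species
#' are left untouched. For every conserved group the noise is applied to the
#' group total and to the split among pools: member draws are rescaled to a
#' noisy group total, integer-floored, and the rounding remainder assigned
#' to the largest pool, so group invariants hold exactly in every cell.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param model The model.
#' @return Named count vector.
#' @export
perturb_initials <- function(model) {
  sp <- model$species
  draw <- function(mean, noise) {
    if (noise <= 0 || mean == 0) return(mean)
    max(0, round(stats::rnorm(1, mean, noise * mean)))
  }
  counts <- stats::setNames(numeric(nrow(sp)), sp$name)
  for (i in seq_len(nrow(sp)))
    counts[i] <- if (sp$boundary[i]) sp$initial[i]
                 else draw(sp$initial[i], sp$noise[i])
  for (g in model$groups) {
    t0 <- sum(sp$initial[match(g, sp$name)])
    gnoise <- mean(sp$noise[match(g, sp$name)])
    t1 <- draw(t0, gnoise)
    x <- counts[g]
    if (sum(x) == 0) x <- stats::setNames(rep(1, length(g)), g)
    y <- floor(x * t1 / sum(x))
    rem <- t1 - sum(y)
    y[which.max(x)] <- y[which.max(x)] + rem
    counts[g] <- y
  }
  counts
}

#' Run an ensemble of independent noisy cells
#'
#' Simulates `n_cells` independent cells, each with its own perturbed
#' initial conditions and derived seed, and averages pointwise. When the
#' experiment's `duration` is `NA` the ensemble is advanced in chunks until
#' the ensemble-mean `readout` passes [detect_steady_state()] (or
#' `max_duration` is reached).
#'
#' @param model The model.
#' @param experiment The [experiment_spec()].
#' @param coefficients Optional chromosome applied to the tunable reactions.
#' @param keep_traces Keep per-cell traces (needed for per-cell endpoints).
#' @param readout Species watched by the steady-state rule.
#' @param steady_window,steady_tol Window (ms) and relative tolerance for
#'   the steady-state rule.
#' @param max_duration,chunk Adaptive-run bounds in ms.
#' @return A `qs_ensemble`: `times`, `mean` and `sd` (time x species
#'   matrices), `n_cells`, `traces`, the experiment, and `steady`
#'   (result of the steady-state rule, when adaptive).
#' @export
run_ensemble <- function(model, experiment, coefficients = NULL,
                         keep_traces = TRUE, readout = "GLUT4_membrane",
                         steady_window = 2500, steady_tol = 0.01,
                         max_duration = 60000, chunk = 5000) {
  model <- set_coefficients(model, coefficients)
  n <- experiment$n_cells
  adaptive <- is.na(experiment$duration)
  states <- lapply(seq_len(n), function(i) {
    set.seed(derive_seed(experiment$seed, i, 0L))
    perturb_initials(model)
  })
  traces <- vector("list", n)
  exp1 <- experiment
  chunk_i <- 0L
  steady <- NULL
  repeat {
    chunk_i <- chunk_i + 1L
    exp1$duration <- if (adaptive) chunk else experiment$duration
    for (i in seq_len(n)) {
      tr <- simulate_cell(model, exp1, init = states[[i]],
                          seed = derive_seed(experiment$seed, i, chunk_i))
      states[[i]] <- tr$counts[nrow(tr$counts), ]
      if (is.null(traces[[i]])) {
        traces[[i]] <- tr
      } else {
        off <- max(traces[[i]]$times)
        traces[[i]]$times <- c(traces[[i]]$times, tr$times[-1] + off)
        traces[[i]]$counts <- rbind(traces[[i]]$counts,
                                    tr$counts[-1, , drop = FALSE])
      }
    }
    if (!adaptive) break
    total_t <- max(traces[[1]]$times)
    if (total_t >= 2 * steady_window) {
      mean_now <- ensemble_mean_trace(traces)
      steady <- detect_steady_state(mean_now, readout, steady_window,
                                    steady_tol)
      if (steady$steady || total_t >= max_duration) break
    }
  }
  arr <- simplify2array(lapply(traces, `[[`, "counts"))
  mu <- rowMeans(arr, dims = 2)
  sdv <- if (n > 1)
    sqrt(pmax((rowMeans(arr^2, dims = 2) - mu^2) * n / (n - 1), 0))
  else mu * 0
  structure(list(times = traces[[1]]$times, mean = mu, sd = sdv,
                 n_cells = n, experiment = experiment, steady = steady,
                 traces = if (keep_traces) traces else NULL),
            class = "qs_ensemble")
}

ensemble_mean_trace <- function(traces) {
  arr <- simplify2array(lapply(traces, `[[`, "counts"))
  list(times = traces[[1]]$times, counts = rowMeans(arr, dims = 2))
}

#' Ensemble-mean endpoint of a species
#'
#' The endpoint is the mean of the ensemble-mean trajectory over the final
#' `window` ms of the run (the steady tail).
#'
#' @param ensemble A `qs_ensemble`.
#' @param species Species name (default the membrane-proximal GLUT4 pool).
#' @param window Averaging window in ms.
#' @return Scalar endpoint (molecules).
#' @export
endpoint_mean <- function(ensemble, species = "GLUT4_membrane",
                          window = 2500) {
  sel <- ensemble$times >= max(ensemble$times) - window
  mean(ensemble$mean[sel, species])
}

#' Per-cell endpoints of a species
#'
#' @inheritParams endpoint_mean
#' @return Numeric vector, one endpoint per cell.
#' @export
endpoint_cells <- function(ensemble, species = "GLUT4_membrane",
                           window = 2500) {
  if (is.null(ensemble$traces))
    stop("ensemble was run with keep_traces = FALSE")
  vapply(ensemble$traces, function(tr) {
    sel <- tr$times >= max(tr$times) - window
    mean(tr$counts[sel, species])
  }, numeric(1))
}

#' Per-cell endpoint fractions of each cell's own GLUT4 total
#'
#' Each cell draws its own (conserved) GLUT4 total, so mobilization is
#' compared on the cell's own scale: endpoint membrane GLUT4 divided by
#' that cell's group total.
#'
#' @inheritParams endpoint_mean
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
endpoint_fractions <- function(ensemble, species = "GLUT4_membrane",
                               window = 2500) {
  if (is.null(ensemble$traces))
    stop("ensemble was run with keep_traces = FALSE")
  grp <- c("GLUT4_reserve", "GLUT4_vesicle", "GLUT4_membrane")
  ep <- endpoint_cells(ensemble, species, window)
  tot <- vapply(ensemble$traces,
                function(tr) sum(tr$counts[1, grp]), numeric(1))
  ep / tot
}

#' @export
print.qs_ensemble <- function(x, ...) {
  cat("<qs_ensemble> ", x$n_cells, " cells, ", max(x$times), " ms",
      if (!is.null(x$steady) && isTRUE(x$steady$steady))
        paste0(" (steady at ", x$steady$time, " ms)"),
      "\n", sep = "")
  cat("  GLUT4_membrane endpoint: ",
      round(endpoint_mean(x)), " molecules\n", sep = "")
  invisible(x)
}

#' @export
plot.qs_ensemble <- function(x, species = "GLUT4_membrane", ...) {
  mu <- x$mean[, species]
  s <- x$sd[, species]
  graphics::plot(x$times, mu, type = "l", xlab = "time (ms)",
                 ylab = paste(species, "(molecules)"),
                 ylim = range(mu - s, mu + s), ...)
  graphics::lines(x$times, mu + s, lty = 3)
  graphics::lines(x$times, mu - s, lty = 3)
  invisible(x)
}

#' Write ensemble outputs as CSV files
#'
#' Writes `mean.csv` and `sd.csv` (and optionally one `cell_<i>.csv` per
#' cell) under `dir`, each with header `time_ms,<species...>`.
#'
#' @param ensemble A `qs_ensemble`.
#' @param dir Output directory (created if needed).
#' @param per_cell Also write per-cell traces.
#' @export
write_ensemble_csv <- function(ensemble, dir, per_cell = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f)
    utils::write.csv(data.frame(time_ms = ensemble$times, m,
                                check.names = FALSE),
                     file.path(dir, f), row.names = FALSE)
  wr(ensemble$mean, "mean.csv")
  wr(ensemble$sd, "sd.csv")
  if (per_cell && !is.null(ensemble$traces))
    for (i in seq_along(ensemble$traces))
      wr(ensemble$traces[[i]]$counts, sprintf("cell_%02d.csv", i))
  invisible(dir)
}
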