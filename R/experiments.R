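#' Sweep GLUT4 mobilization over GAPDH availability and mTORC1 inhibition
#'
#' Runs one ensemble per grid point and records the ensemble-mean (and SD)
#' endpoint of the membrane-proximal GLUT4 pool. All grid points share the
#' same root seed (common random numbers), so monotone trends are not
#' masked by between-point seed noise.
#'
#' @param model The model.
#' @param coefficients Optional calibrated chromosome.
#' @param gapdh_levels Availability grid (default the calibration set plus
#'   the held-out 0.2).
#' @param inhibition_levels mTORC1 inhibition grid.
#' @param experiment Base experiment (insulin on by default).
#' @return A `qs_sweep` data frame with columns `gapdh_availability`,
#'   `mtorc1_inhibition`, `glut4_membrane_mean`, `glut4_membrane_sd`,
#'   sorted by (availability, inhibition).
#' @export
sweep_glut4 <- function(model, coefficients = NULL,
                        gapdh_levels = c(0, 0.2, 0.5, 1),
                        inhibition_levels = c(0, 0.25, 0.5, 0.75, 1),
                        experiment = experiment_spec(insulin_level = 1)) {
  grid <- expand.grid(mtorc1_inhibition = sort(inhibition_levels),
                      gapdh_availability = sort(gapdh_levels))
  grid <- grid[order(grid$gapdh_availability, grid$mtorc1_inhibition), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    experiment$gapdh_availability <- grid$gapdh_availability[i]
    experiment$mtorc1_inhibition <- grid$mtorc1_inhibition[i]
    ens <- run_ensemble(model, experiment, coefficients = coefficients)
    ep <- endpoint_cells(ens)
    data.frame(gapdh_availability = grid$gapdh_availability[i],
               mtorc1_inhibition = grid$mtorc1_inhibition[i],
               glut4_membrane_mean = mean(ep),
               glut4_membrane_sd = stats::sd(ep))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qs_sweep", "data.frame")
  attr(out, "n_cells") <- experiment$n_cells
  out
}

#' @export
plot.qs_sweep <- function(x, ...) {
  inh <- sort(unique(x$mtorc1_inhibition))
  cols <- seq_along(inh)
  graphics::plot(range(x$gapdh_availability), range(x$glut4_membrane_mean),
                 type = "n", xlab = "GAPDH availability (clamped occupancy)",
                 ylab = "membrane GLUT4 endpoint (molecules)", ...)
  for (i in seq_along(inh)) {
    sub <- x[x$mtorc1_inhibition == inh[i], ]
    graphics::lines(sub$gapdh_availability, sub$glut4_membrane_mean,
                    type = "b", col = cols[i], pch = 16)
  }
  graphics::legend("topleft", legend = paste0("inhibition ", inh),
                   col = cols, lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Fed and fasted scenario demonstrations with emergent GAPDH occupancy
#'
#' Scenario `"I"` (fed): insulin on and extracellular glucose high, so
#' glycolytic flux keeps GAPDH busy, Rheb stays free, mTORC1 activity rises
#' and membrane GLUT4 climbs. Scenario `"II"` (prolonged fasting): no
#' insulin and low extracellular glucose; the glycogen buffer maintains
#' basal G6P, idle GAPDH sequesters Rheb, mTORC1 activity stays near zero
#' and membrane GLUT4 remains basal. Occupancy is not clamped — it emerges
#' from the glycolysis fragment.
#'
#' @param model The model.
#' @param scenario `"I"` or `"II"`.
#' @param duration Run length in ms.
#' @param n_cells Ensemble size (default 10, enough for a demonstration).
#' @param seed Root seed.
#' @param fasting_glucose_factor Scaling of extracellular glucose in
#'   Scenario II (default 0.2).
#' @return A `qs_scenario`: the ensemble plus derived `phi` (occupancy) and
#'   `activity` time series on the ensemble mean.
#' @export
scenario_demo <- function(model, scenario = c("I", "II"), duration = 20000,
                          n_cells = 10, seed = 1,
                          fasting_glucose_factor = 0.2) {
  scenario <- match.arg(scenario)
  model$gapdh_clamp <- NA_real_
  insulin <- if (scenario == "I") 1 else 0
  if (scenario == "II") {
    i <- match("glucose_ext", model$species$name)
    if (!is.na(i))
      model$species$initial[i] <-
        round(model$species$initial[i] * fasting_glucose_factor)
  }
  ex <- experiment_spec(insulin_level = insulin, gapdh_availability = NA,
                        duration = duration, n_cells = n_cells, seed = seed)
  ens <- run_ensemble(model, ex)
  pools <- gapdh_pool_names(model)
  busy <- ens$mean[, pools["busy"]]
  free <- ens$mean[, pools["free"]]
  phi <- busy / (busy + free)
  structure(list(scenario = scenario, ensemble = ens, times = ens$times,
                 phi = phi,
                 activity = mtorc1_activity(phi, ex$mtorc1_inhibition)),
            class = "qs_scenario")
}

#' @export
print.qs_scenario <- function(x, ...) {
  n <- length(x$times)
  cat("<qs_scenario> Scenario ", x$scenario, ": endpoint occupancy ",
      round(x$phi[n], 3), ", mTORC1 activity ", round(x$activity[n], 3),
      ", membrane GLUT4 ", round(endpoint_mean(x$ensemble)), "\n", sep = "")
  invisible(x)
}

#' @export
plot.qs_scenario <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$times, x$ensemble$mean[, "GLUT4_membrane"], type = "l",
                 xlab = "time (ms)", ylab = "membrane GLUT4", ...)
  graphics::plot(x$times, x$phi, type = "l", ylim = c(0, 1),
                 xlab = "time (ms)", ylab = "occupancy / activity")
  graphics::lines(x$times, x$activity, lty = 2)
  graphics::legend("topright", c(expression(phi), "mTORC1 activity"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
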