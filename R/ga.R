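#' Genetic-algorithm settings
#'
#' Hyperparameters of the calibrator: a population of 10 chromosomes, the
#' two best carried over unchanged each epoch (elitism), uniform crossover
#' of the elites plus log-normal multiplicative mutation. Fitness is
#' evaluated with a fixed seed so selection compares like with like.
#'
#' @param population_size Chromosomes per epoch (default 10).
#' @param elite_count Elites carried over unchanged (default 2).
#' @param epochs Number of breeding epochs.
#' @param mutation_sd Log-scale SD of the multiplicative mutation.
#' @param crossover_rate Fraction of offspring produced by uniform
#'   crossover of the two elites (the rest are mutated elite copies).
#' @param init_sd Log-scale SD of the initial population around 1.
#' @param gapdh_levels GAPDH availability levels used by the default
#'   fitness; 0.2 is deliberately held out for validation.
#' @param tol_band Endpoint tolerance band, as a fraction of the
#'   max-to-min dynamic range, within which a cell counts as having
#'   reached the extreme.
#' @param target_max_fraction Mobilized fraction of a cell's GLUT4 total
#'   that counts as "maximum" at full availability (default 0.5: half the
#'   total pool at the membrane under full stimulation).
#' @param target_min_fraction Basal fraction counting as "minimum" at zero
#'   availability; `NA` (default) takes the model's declared unstimulated
#'   membrane fraction.
#' @param seed Root seed for the GA and for fitness evaluation.
#' @return A list of class `qs_ga_config`.
#' @export
ga_config <- function(population_size = 10, elite_count = 2, epochs = 20,
                      mutation_sd = 0.2, crossover_rate = 0.7,
                      init_sd = 0.5, gapdh_levels = c(0, 0.5, 1),
                      tol_band = 0.05, target_max_fraction = 0.5,
                      target_min_fraction = NA, seed = 1) {
  stopifnot(elite_count < population_size, elite_count >= 1,
            all(gapdh_levels >= 0 & gapdh_levels <= 1),
            crossover_rate >= 0, crossover_rate <= 1, mutation_sd >= 0)
  structure(list(population_size = as.integer(population_size),
                 elite_count = as.integer(elite_count),
                 epochs = as.integer(epochs), mutation_sd = mutation_sd,
                 crossover_rate = crossover_rate, init_sd = init_sd,
                 gapdh_levels = gapdh_levels, tol_band = tol_band,
                 target_max_fraction = target_max_fraction,
                 target_min_fraction = target_min_fraction,
                 seed = as.integer(seed)),
            class = "qs_ga_config")
}

#' Evaluate a chromosome against the GLUT4 endpoint criteria
#'
#' Runs one ensemble per GAPDH availability level with the chromosome's
#' coefficients. Each cell's endpoint is expressed as a fraction of that
#' cell's own (conserved, noisily drawn) GLUT4 total, and scored against
#' the calibration anchors: `n_max`, cells whose fraction at availability
#' 1 is within the tolerance band of the target maximal mobilization
#' (half the pool at the membrane); `n_min`, cells whose fraction at
#' availability 0 is within the band of the basal fraction; and `d_mid`,
#' the distance of the availability-0.5 count of max-reaching cells from
#' the midpoint of the corresponding counts at availabilities 0 and 1.
#' Fitness is `n_max + n_min - d_mid` (monotone in each criterion).
#'
#' @param coefficients Named chromosome vector.
#' @param model The model.
#' @param experiment Base experiment; its `gapdh_availability` is
#'   overridden per level and its seed fixes the evaluation randomness.
#' @param cfg A [ga_config()].
#' @return A list of class `qs_fitness` with the per-level counts and the
#'   scalar `fitness` (`-Inf` on simulation failure).
#' @export
evaluate_chromosome <- function(coefficients, model, experiment, cfg) {
  lv <- sort(cfg$gapdh_levels)
  ep <- tryCatch(
    lapply(lv, function(a) {
      experiment$gapdh_availability <- a
      endpoint_fractions(run_ensemble(model, experiment,
                                      coefficients = coefficients))
    }),
    error = function(e) NULL)
  if (is.null(ep))
    return(structure(list(fitness = -Inf, failed = TRUE),
                     class = "qs_fitness"))
  names(ep) <- as.character(lv)
  lo <- ep[["0"]]
  hi <- ep[[as.character(max(lv))]]
  mid <- ep[[as.character(lv[2])]]
  f_max <- cfg$target_max_fraction
  f_min <- cfg$target_min_fraction
  if (is.na(f_min)) {
    init <- initial_state(model)
    f_min <- init[["GLUT4_membrane"]] /
      sum(init[c("GLUT4_reserve", "GLUT4_vesicle", "GLUT4_membrane")])
  }
  band <- cfg$tol_band * (f_max - f_min)
  n_max <- sum(hi >= f_max - band)
  n_min <- sum(lo <= f_min + band)
  n_max_at0 <- sum(lo >= f_max - band)
  n_mid <- sum(mid >= f_max - band)
  d_mid <- abs(n_mid - (n_max + n_max_at0) / 2)
  structure(list(n_max = n_max, n_min = n_min, n_mid = n_mid,
                 d_mid = d_mid, fitness = n_max + n_min - d_mid,
                 endpoints = ep, failed = FALSE),
            class = "qs_fitness")
}

#' @export
print.qs_fitness <- function(x, ...) {
  if (isTRUE(x$failed)) cat("<qs_fitness> failed (-Inf)\n")
  else cat("<qs_fitness> fitness ", x$fitness, " (n_max ", x$n_max,
           ", n_min ", x$n_min, ", d_mid ", x$d_mid, ")\n", sep = "")
  invisible(x)
}

# Selection, crossover and mutation: elites kept verbatim, offspring from
# uniform crossover of the two best plus log-normal mutation.
next_generation <- function(population, fitness, cfg) {
  ord <- order(fitness, decreasing = TRUE)
  elites <- population[ord[seq_len(cfg$elite_count)]]
  offspring <- lapply(seq_len(cfg$population_size - cfg$elite_count),
                      function(i) {
    child <- if (stats::runif(1) < cfg$crossover_rate) {
      pick <- stats::runif(length(elites[[1]])) < 0.5
      ifelse(pick, elites[[1]], elites[[2]])
    } else {
      elites[[sample.int(length(elites), 1)]]
    }
    child <- child * exp(stats::rnorm(length(child), 0, cfg$mutation_sd))
    stats::setNames(child, names(elites[[1]]))
  })
  c(elites, offspring)
}

#' Calibrate the tunable reaction coefficients with a genetic algorithm
#'
#' Evolves a population of coefficient chromosomes against a fitness (by
#' default [evaluate_chromosome()]'s GLUT4 endpoint criteria). Elites are
#' carried with their fitness, and fitness is evaluated under a fixed seed,
#' so the best-so-far fitness is non-decreasing across epochs and the whole
#' run is reproducible from `cfg$seed`.
#'
#' @param model The model.
#' @param cfg A [ga_config()].
#' @param experiment Base experiment passed to the default fitness.
#' @param fitness_fn Optional replacement fitness: a
#'   `function(coefficients)` returning a scalar (larger is better). Used
#'   e.g. to calibrate toy networks against deterministic endpoints.
#' @return A `qs_calibration`: best chromosome, its fitness, the per-epoch
#'   `history` data frame (`epoch`, `best_fitness`, `mean_fitness`), the
#'   final population and the config. `coef()` extracts the chromosome.
#' @export
calibrate <- function(model, cfg = ga_config(),
                      experiment = experiment_spec(insulin_level = 1,
                                                   seed = cfg$seed),
                      fitness_fn = NULL) {
  tun <- tunable_reactions(model)
  if (!length(tun)) stop("model has no tunable reactions")
  if (is.null(fitness_fn))
    fitness_fn <- function(coefficients)
      evaluate_chromosome(coefficients, model, experiment, cfg)$fitness
  set.seed(cfg$seed)
  population <- lapply(seq_len(cfg$population_size), function(i)
    stats::setNames(exp(stats::rnorm(length(tun), 0, cfg$init_sd)), tun))
  fitness <- vapply(population, fitness_fn, numeric(1))
  history <- data.frame(epoch = 0, best_fitness = max(fitness),
                        mean_fitness = mean(fitness))
  for (e in seq_len(cfg$epochs)) {
    population <- next_generation(population, fitness, cfg)
    keep <- seq_len(cfg$elite_count)  # elites keep their evaluated fitness
    fitness <- c(sort(fitness, decreasing = TRUE)[keep],
                 vapply(population[-keep], fitness_fn, numeric(1)))
    history <- rbind(history,
                     data.frame(epoch = e, best_fitness = max(fitness),
                                mean_fitness = mean(fitness)))
  }
  best <- which.max(fitness)
  structure(list(coefficients = population[[best]],
                 fitness = fitness[best], history = history,
                 population = population, population_fitness = fitness,
                 config = cfg),
            class = "qs_calibration")
}

#' @export
coef.qs_calibration <- function(object, ...) object$coefficients

#' The packaged calibrated chromosome
#'
#' The coefficient vector under which the packaged model reproduces the
#' GLUT4 mobilization endpoints (the kinetic constants in the packaged
#' config already incorporate the calibration, so the shipped chromosome
#' is the identity scaling).
#'
#' @return Named numeric vector over the tunable reactions.
#' @export
calibrated_coefficients <- function() {
  p <- system.file("extdata", "calibrated_coefficients.json",
                   package = "qsignal", mustWork = TRUE)
  unlist(jsonlite::read_json(p))
}

#' @export
print.qs_calibration <- function(x, ...) {
  cat("<qs_calibration> ", nrow(x$history) - 1, " epochs, best fitness ",
      x$fitness, "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.qs_calibration <- function(object, ...) {
  cat("Genetic-algorithm calibration\n")
  cat("  population ", object$config$population_size, ", elites ",
      object$config$elite_count, ", mutation sd ", object$config$mutation_sd,
      "\n", sep = "")
  cat("  best fitness: ", object$fitness, "\n", sep = "")
  cat("  coefficients:\n")
  print(round(object$coefficients, 4))
  invisible(object)
}

#' @export
plot.qs_calibration <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$best_fitness, type = "s",
                 xlab = "epoch", ylab = "fitness", ...)
  graphics::lines(x$history$epoch, x$history$mean_fitness, lty = 2)
  graphics::legend("bottomright", c("best", "population mean"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
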