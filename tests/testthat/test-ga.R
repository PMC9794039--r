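# Cheap deterministic fitness on the branching toy: distance of the
# deterministic endpoints to those generated by a known coefficient vector.
toy_fitness <- local({
  toy <- NULL; target <- NULL
  function(co) {
    if (is.null(toy)) {
      toy <<- make_branching_toy()
      ref <- ode_reference(toy, c(0, 5000),
                           coefficients = c(to_b = 1.6, to_c = 0.7))
      target <<- ref[2, c("B", "C")]
    }
    out <- ode_reference(toy, c(0, 5000), coefficients = co)
    -sum(abs(out[2, c("B", "C")] - target))
  }
})

test_that("selection preserves population size and zero mutation is a fixed point", {
  cfg <- ga_config(population_size = 10, mutation_sd = 0, crossover_rate = 1)
  pop <- replicate(10, c(a = 1.3, b = 0.6), simplify = FALSE)
  set.seed(1)
  nxt <- next_generation(pop, fitness = rep(1, 10), cfg)
  expect_length(nxt, 10)
  for (ch in nxt) expect_equal(ch, c(a = 1.3, b = 0.6))

  cfg2 <- ga_config(population_size = 6, mutation_sd = 0.3)
  pop2 <- pop[1:6]
  set.seed(2)
  for (i in 1:10) {
    pop2 <- next_generation(pop2, fitness = stats::runif(6), cfg2)
    expect_length(pop2, 6)
    expect_true(all(unlist(pop2) > 0))  # log-normal mutation keeps positivity
  }
})

test_that("elite fitness never decreases across epochs", {
  toy <- make_branching_toy()
  cal <- calibrate(toy, ga_config(epochs = 20, mutation_sd = 0.25, seed = 21),
                   fitness_fn = toy_fitness)
  expect_true(all(diff(cal$history$best_fitness) >= 0))
  expect_equal(nrow(cal$history), 21L)

  cal0 <- calibrate(toy, ga_config(epochs = 0, seed = 21),
                    fitness_fn = toy_fitness)
  expect_equal(nrow(cal0$history), 1L)  # best of the initial population
})

test_that("the GA recovers known coefficients on the branching toy", {
  toy <- make_branching_toy()
  cal <- calibrate(toy, ga_config(epochs = 50, mutation_sd = 0.15, seed = 11),
                   fitness_fn = toy_fitness)
  truth <- c(to_b = 1.6, to_c = 0.7)
  expect_true(all(abs(coef(cal) - truth) / truth < 0.20))
})

test_that("chromosome evaluation is deterministic and flags flux-free chromosomes", {
  m <- default_model()
  ex <- experiment_spec(insulin_level = 1, duration = 6000, n_cells = 4,
                        seed = 31)
  cfg <- ga_config(seed = 31)
  ones <- calibrated_coefficients()
  f1 <- evaluate_chromosome(ones, m, ex, cfg)
  f2 <- evaluate_chromosome(ones, m, ex, cfg)
  expect_identical(f1, f2)
  expect_equal(f1$n_min, 4)  # every cell sits at the basal minimum

  zeros <- ones * 0          # no activation flux: no cell can mobilize
  f0 <- evaluate_chromosome(zeros, m, ex, cfg)
  expect_equal(f0$n_max, 0)
  expect_equal(f0$n_min, 4)
})
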