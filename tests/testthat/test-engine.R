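test_that("reaction rates follow the kinetic laws", {
  st <- c(A = 100, B = 0, E = 500)
  mm <- qs_reaction("r", "michaelis_menten", substrates = "A",
                    products = "B", vmax = 10, km = 100)
  expect_equal(reaction_rate(mm, st), 5.0)  # half saturation: Vmax/2
  expect_equal(reaction_rate(mm, c(A = 0, B = 0, E = 0)), 0)

  enz <- qs_reaction("r2", "michaelis_menten", substrates = "A",
                     products = "B", enzyme = "E", vmax = 0.01, km = 2000,
                     coefficient = 0.5)
  expect_equal(reaction_rate(enz, c(A = 6000, B = 0, E = 500)),
               0.5 * (0.01 * 500) * 6000 / 8000)  # = 1.875

  ma <- qs_reaction("r3", "mass_action", substrates = c(A = 1, B = 1),
                    products = character(), k = 1e-4)
  expect_equal(reaction_rate(ma, c(A = 200, B = 50)), 1e-4 * 200 * 50)
  expect_equal(reaction_rate(ma, c(A = 200, B = 0)), 0)
})

test_that("gate references are validated and multiply the rate", {
  mm <- qs_reaction("r", "michaelis_menten", substrates = "A",
                    products = "B", vmax = 10, km = 100, gates = "drive")
  expect_equal(reaction_rate(mm, c(A = 100, B = 0), gates = c(drive = 0.4)),
               2.0)
  expect_error(reaction_rate(mm, c(A = 100, B = 0)), "unknown gate")
  expect_error(qs_reaction("bad", "michaelis_menten", substrates = "A",
                           products = "B", vmax = -1, km = 100), "vmax")
  expect_error(qs_reaction("bad", "michaelis_menten", substrates = "A",
                           products = "B", vmax = 1, km = 0), "km")
})

test_that("step probabilities are thinning probabilities clamped below 1", {
  expect_equal(step_probability(0, 1, 100), 0)
  expect_equal(step_probability(5, 1, 100), 0.05)
  expect_equal(step_probability(500, 1, 100), 0.99)   # clamp at p_max
  expect_equal(step_probability(5, 1, 0), 0)          # empty queue
  for (rate in c(0, 1, 50, 1e4))
    expect_true(step_probability(rate, 1, 123) >= 0 &&
                step_probability(rate, 1, 123) <= 0.99)
})

test_that("advance() leaves a rate-free network unchanged and conserves groups", {
  m <- two_pool_model(k1 = 0, k2 = 0)
  ex <- experiment_spec(duration = 1)
  st <- initial_state(m)
  expect_identical(advance(st, m, ex), st)

  m <- two_pool_model()
  st <- initial_state(m)
  set.seed(1)
  for (i in 1:200) st <- advance(st, m, ex)
  expect_equal(sum(st), 10000)          # conserved pair, exactly
  expect_true(all(st >= 0))
})

test_that("the compiled engine and the R reference step agree draw for draw", {
  m <- two_pool_model()
  ex <- experiment_spec(duration = 1, record_stride = 1L)
  set.seed(42)
  r_step <- advance(initial_state(m), m, ex)
  tr <- simulate_cell(m, ex, seed = 42)
  expect_equal(tr$counts[2, ], r_step)
})

test_that("simulation traces are reproducible, constant for empty networks, and warn on clamping", {
  m <- two_pool_model()
  ex <- experiment_spec(duration = 500, seed = 7)
  t1 <- simulate_cell(m, ex)
  t2 <- simulate_cell(m, ex)
  expect_identical(t1$counts, t2$counts)

  ex1 <- experiment_spec(duration = 1, record_stride = 1L)
  expect_equal(nrow(simulate_cell(m, ex1)$counts), 2L)  # one step only

  m0 <- two_pool_model(k1 = 0, k2 = 0)
  tr <- simulate_cell(m0, experiment_spec(duration = 200))
  expect_true(all(tr$counts[, "X"] == 6000))
  expect_true(all(tr$counts[, "Y"] == 4000))

  mfast <- two_pool_model(k1 = 0.5, k2 = 0)
  expect_warning(simulate_cell(mfast, experiment_spec(duration = 20, dt = 10)),
                 "p_max")
})

test_that("steady-state detection finds plateaus and rejects drifting series", {
  mk <- function(x) list(times = seq_along(x) - 1, counts = cbind(S = x))
  expect_true(detect_steady_state(mk(rep(5, 100)), "S", window = 10)$steady)
  expect_equal(detect_steady_state(mk(rep(5, 100)), "S", window = 10)$time, 10)

  lin <- detect_steady_state(mk(seq_len(100)), "S", window = 10, tol = 0)
  expect_false(lin$steady)

  set.seed(3)
  noisy <- c(seq(0, 100, length.out = 30),
             100 + stats::rnorm(170, 0, 1))  # plateau + 1% noise
  got <- detect_steady_state(mk(noisy), "S", window = 50, tol = 0.01)
  expect_true(got$steady)
  expect_lte(got$time, 100)  # within two windows of the plateau
  expect_error(detect_steady_state(mk(noisy), "nope", window = 50),
               "no such species")
})
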