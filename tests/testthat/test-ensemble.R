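test_that("initial-condition noise has the declared spread and respects bounds", {
  m <- build_network(list(qs_species("A", 1000, noise = 0.10)),
                     reactions = list(), name = "one")
  set.seed(9)
  draws <- replicate(1e4, perturb_initials(m)[["A"]])
  expect_lt(abs(stats::sd(draws) - 100) / 100, 0.05)  # SD within 5% of 100
  expect_lt(abs(mean(draws) - 1000), 5)

  m0 <- build_network(list(qs_species("A", 1000, noise = 0)),
                      reactions = list(), name = "one")
  expect_equal(perturb_initials(m0)[["A"]], 1000)     # no noise, unchanged

  mt <- build_network(list(qs_species("A", 2, noise = 1)),
                      reactions = list(), name = "tiny")
  set.seed(10)
  expect_true(all(replicate(500, perturb_initials(mt)[["A"]]) >= 0))
})

test_that("conserved-group noise keeps group totals exact within each cell", {
  m <- default_model()
  set.seed(11)
  for (i in 1:20) {
    st <- perturb_initials(m)
    tot <- group_totals(st, m)
    # each cell's total is itself a noisy draw, but the split is exact
    expect_true(all(tot == round(tot)))
    expect_true(all(st >= 0))
  }
  # over many cells the mean group total recovers the declared total
  set.seed(12)
  tots <- replicate(400, group_totals(perturb_initials(m), m)["glut4"])
  expect_lt(abs(mean(tots) - 390000) / 390000, 0.02)
})

test_that("a one-cell ensemble is the single trace and seeds reproduce ensembles", {
  m <- two_pool_model(noise = 0.1)
  ex <- experiment_spec(duration = 300, n_cells = 1, seed = 5)
  ens <- run_ensemble(m, ex, readout = "X")
  expect_equal(ens$mean, ens$traces[[1]]$counts)
  expect_true(all(ens$sd == 0))

  ex2 <- experiment_spec(duration = 300, n_cells = 8, seed = 6)
  e1 <- run_ensemble(m, ex2, readout = "X")
  e2 <- run_ensemble(m, ex2, readout = "X")
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$sd, e2$sd)

  # noise-free cells of a rate-free network are identical: SD is zero
  m0 <- two_pool_model(k1 = 0, k2 = 0, noise = 0)
  e0 <- run_ensemble(m0, ex2, readout = "X")
  expect_true(all(e0$sd == 0))
})

test_that("conservation holds exactly along every cell of an ensemble", {
  m <- default_model()
  ex <- experiment_spec(insulin_level = 1, gapdh_availability = 0.5,
                        duration = 1000, n_cells = 4, seed = 13)
  ens <- run_ensemble(m, ex)
  for (tr in ens$traces) {
    t0 <- group_totals(tr$counts[1, ], m)
    for (row in seq_along(tr$times))
      expect_identical(group_totals(tr$counts[row, ], m), t0)
  }
})

test_that("adaptive runs stop once the readout is steady", {
  m <- default_model()
  ex <- experiment_spec(insulin_level = 0, gapdh_availability = 0,
                        n_cells = 5, seed = 14)
  ens <- run_ensemble(m, ex, chunk = 2500, max_duration = 20000)
  expect_true(ens$steady$steady)
  expect_lt(max(ens$times), 20000)  # basal state is already stationary
})
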