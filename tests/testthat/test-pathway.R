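test_that("the packaged network loads with its invariants intact", {
  m <- default_model()
  st <- initial_state(m)
  expect_equal(total_glut4(m), 390000)
  expect_equal(unname(group_totals(st, m)),
               c(390000, 100000, 10000, 6000))
  expect_true(all(st >= 0))
  expect_length(tunable_reactions(m), 7L)
  expect_setequal(names(calibrated_coefficients()), tunable_reactions(m))
})

test_that("schema violations are reported with the offending entry", {
  cfg <- model_to_list(two_pool_model())
  cfg$reactions[[1]] <- list(id = "broken", law = "michaelis_menten",
                             substrates = list("X"), products = list("Y"),
                             vmax = 1)  # km missing
  expect_error(model_from_list(cfg), "broken")

  cfg2 <- model_to_list(two_pool_model())
  cfg2$species <- c(cfg2$species, cfg2$species[1])
  expect_error(model_from_list(cfg2), "duplicated species")

  cfg3 <- model_to_list(two_pool_model())
  cfg3$reactions[[1]]$gates <- list("no_such_gate")
  expect_error(model_from_list(cfg3), "no_such_gate")
})

test_that("a model round-trips through its serialized configuration", {
  m <- default_model()
  m2 <- model_from_list(model_to_list(m))
  expect_identical(yaml::as.yaml(model_to_list(m)),
                   yaml::as.yaml(model_to_list(m2)))
  expect_identical(config_hash(m), config_hash(m2))
})

test_that("GAPDH occupancy is the busy fraction of the conserved pool", {
  m <- default_model()
  st <- initial_state(m)
  st["GAPDH_free"] <- 100; st["GAPDH_busy"] <- 0
  expect_equal(gapdh_occupancy(st, m), 0)
  st["GAPDH_free"] <- 0; st["GAPDH_busy"] <- 100
  expect_equal(gapdh_occupancy(st, m), 1)
  st["GAPDH_free"] <- 50; st["GAPDH_busy"] <- 50
  expect_equal(gapdh_occupancy(st, m), 0.5)
  st["GAPDH_free"] <- 0; st["GAPDH_busy"] <- 0
  expect_error(gapdh_occupancy(st, m), "zero")
})

test_that("mTORC1 activity combines occupancy and drug inhibition", {
  expect_equal(mtorc1_activity(1, 0), 1)   # fed state, no drug
  expect_equal(mtorc1_activity(0, 0), 0)   # idle GAPDH sequesters Rheb
  expect_equal(mtorc1_activity(0.7, 1), 0) # complete inhibition
  expect_equal(mtorc1_activity(0.5, 0.5), 0.25)
  phis <- seq(0, 1, 0.1)
  expect_true(all(diff(mtorc1_activity(phis, 0.3)) >= 0))
  expect_error(mtorc1_activity(1.2, 0), "phi")
  expect_error(mtorc1_activity(0.5, -0.1), "inhibition")
})

test_that("the GAPDH clamp pins occupancy at every recorded step", {
  m <- default_model()
  for (avail in c(0, 0.5, 1)) {
    ex <- experiment_spec(insulin_level = 1, gapdh_availability = avail,
                          duration = 300, seed = 2)
    tr <- simulate_cell(m, ex)
    phi <- tr$counts[, "GAPDH_busy"] /
      (tr$counts[, "GAPDH_busy"] + tr$counts[, "GAPDH_free"])
    expect_true(all(abs(phi - avail) < 1e-4))
  }
  m2 <- apply_gapdh_clamp(m, 0.5)
  st <- initial_state(m2)
  expect_equal(gapdh_occupancy(st, m2), 0.5)
  expect_error(apply_gapdh_clamp(m, 1.5), "availability")
})

test_that("S6K feedback accelerates IRS1/3 degradation monotonically", {
  expect_equal(s6k_feedback_rate(0, 10), 10)
  expect_equal(s6k_feedback_rate(1, 10, beta = 1), 20)
  rates <- s6k_feedback_rate(seq(0, 1, 0.1), 3, beta = 0.5)
  expect_true(all(diff(rates) > 0))
  expect_error(s6k_feedback_rate(0.5, 10, beta = -1), "beta")
  expect_error(s6k_feedback_rate(2, 10), "activity")
})

test_that("glucose influx has a basal route and a 30x GLUT4-facilitated ceiling", {
  m <- default_model()
  st <- initial_state(m)
  st["GLUT4_membrane"] <- 0
  basal <- glucose_influx_rate(st, m)
  expect_equal(basal, 100)           # permeability route alone
  st["glucose_ext"] <- 0
  expect_equal(glucose_influx_rate(st, m), 0)
  expect_equal(facilitation_ratio(m), 30, tolerance = 1e-4)
})
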