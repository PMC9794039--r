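test_that("a one-point sweep reproduces a plain ensemble run", {
  m <- default_model()
  ex <- experiment_spec(insulin_level = 1, duration = 4000, n_cells = 5,
                        seed = 41)
  sw <- sweep_glut4(m, gapdh_levels = 1, inhibition_levels = 0,
                    experiment = ex)
  expect_equal(nrow(sw), 1L)
  ex$gapdh_availability <- 1
  ens <- run_ensemble(m, ex)
  expect_equal(sw$glut4_membrane_mean, mean(endpoint_cells(ens)))
  expect_equal(sw$glut4_membrane_sd, stats::sd(endpoint_cells(ens)))
})

test_that("endpoint mobilization orders with availability and inhibition", {
  m <- default_model()
  ex <- experiment_spec(insulin_level = 1, duration = 6000, n_cells = 8,
                        seed = 42)
  sw <- sweep_glut4(m, gapdh_levels = c(0, 0.5, 1),
                    inhibition_levels = c(0, 0.6), experiment = ex)
  no_drug <- sw[sw$mtorc1_inhibition == 0, ]
  expect_true(all(diff(no_drug$glut4_membrane_mean) > 0))
  full <- sw[sw$gapdh_availability == 1, ]
  expect_true(diff(full$glut4_membrane_mean) < 0)  # drug lowers mobilization
  expect_true(all(sw$glut4_membrane_mean >= 0 &
                  sw$glut4_membrane_mean <= total_glut4(m)))
})

test_that("fed and fasted scenarios separate occupancy, activity and GLUT4", {
  m <- default_model()
  s1 <- scenario_demo(m, "I", duration = 12000, n_cells = 5, seed = 43)
  s2 <- scenario_demo(m, "II", duration = 12000, n_cells = 5, seed = 43)
  expect_true(all(s1$phi >= 0 & s1$phi <= 1))
  expect_true(all(s2$phi >= 0 & s2$phi <= 1))
  n <- length(s1$times)
  expect_gt(s1$activity[n], s2$activity[n])  # fasting inactivates mTORC1
  expect_gt(endpoint_mean(s1$ensemble), endpoint_mean(s2$ensemble))
  # fasted membrane GLUT4 stays within 3 ensemble SDs of the basal level
  ep2 <- endpoint_mean(s2$ensemble)
  sd2 <- stats::sd(endpoint_cells(s2$ensemble))
  expect_lt(abs(ep2 - 18200), 3 * sd2)
})
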