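test_that("the deterministic reference keeps rate-free networks constant", {
  m <- two_pool_model(k1 = 0, k2 = 0)
  out <- ode_reference(m, seq(0, 100, 10))
  expect_true(all(out[, "X"] == 6000))
  expect_true(all(out[, "Y"] == 4000))
})

test_that("a far-from-saturation MM queue decays exponentially", {
  # km >> S: dA/dt = -(vmax/km) A, closed form A(t) = s0 exp(-vmax/km t)
  m <- make_single_mm(vmax = 1e5, km = 1e8, s0 = 10)
  t <- seq(0, 1000, 100)
  out <- ode_reference(m, t, rtol = 1e-10, atol = 1e-10)
  expect_equal(out[, "A"], 10 * exp(-1e-3 * t), tolerance = 1e-6)
  m0 <- make_single_mm(vmax = 0, km = 100, s0 = 500)
  out0 <- ode_reference(m0, c(0, 50))
  expect_true(all(out0[, "A"] == 500))
})

test_that("the packaged model's conserved totals are flat under the reference integrator", {
  m <- default_model()
  out <- ode_reference(m, seq(0, 2000, 500),
                       experiment = experiment_spec(insulin_level = 1,
                                                    gapdh_availability = 0.5,
                                                    duration = 2000))
  for (g in names(m$groups)) {
    tot <- rowSums(out[, m$groups[[g]], drop = FALSE])
    expect_equal(tot, rep(tot[1], length(tot)), tolerance = 1e-6)
  }
})

test_that("engine ensemble means track the deterministic reference on a MM toy", {
  m <- make_single_mm(vmax = 50, km = 5000, s0 = 10000)
  ex <- experiment_spec(duration = 500, n_cells = 300, seed = 51,
                        record_stride = 100L)
  ens <- run_ensemble(m, ex, readout = "B")
  ref <- ode_reference(m, c(0, 500))
  b_mean <- ens$mean[nrow(ens$mean), "B"]
  se <- ens$sd[nrow(ens$sd), "B"] / sqrt(ex$n_cells)
  expect_lt(abs(b_mean - ref[2, "B"]), 3 * se)
})
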