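test_that("atom fraction follows the tracer/ambient pool arithmetic", {
  expect_equal(atom_fraction(8, 2), 0.2)
  expect_equal(atom_fraction(5, 0), 0)
  expect_equal(atom_fraction(1, 1), 0.5)
  expect_error(atom_fraction(0, 0), "undefined")
  expect_error(atom_fraction(-1, 2), "non-negative")
})

test_that("nitrification rate matches direct evaluation and edge contracts", {
  # 15NOx goes from 0 to 0.05 * 12 uM over 24 h at F = 0.2
  r <- nitrification_rate(c(0, 24), c(10, 12), c(0, 0.05), F = 0.2)
  expect_equal(r$value, 125)
  expect_equal(r$estimator_id, "eq1")
  expect_false(r$negative)

  # identical observations: no accumulation
  expect_equal(nitrification_rate(c(0, 24), c(10, 10), c(0.02, 0.02),
                                  F = 0.5)$value, 0)

  # declining label: returned as-is, flagged, warned
  expect_warning(
    r2 <- nitrification_rate(c(0, 24), c(10, 10), c(0.05, 0.02), F = 0.2),
    "negative")
  expect_true(r2$negative)
  expect_lt(r2$value, 0)

  expect_error(nitrification_rate(c(0, 0), c(10, 12), c(0, 0.05), 0.2))
  expect_error(nitrification_rate(c(0, 24), c(10, 12), c(0, 0.05), 0),
               "F must")
  expect_error(nitrification_rate(c(0, 24), c(10, 12), c(0, 1.2), 0.2),
               "r15")
})

test_that("zero-noise simulations are recovered exactly for any rate and F", {
  for (rate in c(10, 100, 517.3)) {
    for (f_pair in list(c(10, 2), c(9, 1), c(5, 5))) {
      cfg <- sim_config(true_nitrification_rate = rate,
                        ambient_nh4 = f_pair[1], added_15nh4 = f_pair[2],
                        noise_cv = 0, sample_times = c(0, 6, 12, 24))
      sim <- simulate_incubation(cfg)
      # endpoints and regression agree with truth for any two sampling times
      est <- nitrification_rate(sim$time_h, sim$nox_umol_L, sim$r15_nox,
                                cfg$F)
      expect_equal(est$value, rate, tolerance = 1e-9)
      reg <- nitrification_rate(sim$time_h, sim$nox_umol_L, sim$r15_nox,
                                cfg$F, method = "regression")
      expect_equal(reg$value, rate, tolerance = 1e-9)
      sub <- sim[c(2, 3), ]
      est2 <- nitrification_rate(sub$time_h, sub$nox_umol_L, sub$r15_nox,
                                 cfg$F)
      expect_equal(est2$value, rate, tolerance = 1e-9)
    }
  }
})

test_that("N2O estimators match hand evaluation of the printed forms", {
  p <- n2o_rate_printed(c(0, 24), c(0, 48), c(0, 12), F = 0.2, volume_L = 4)
  expect_equal(p$value, 8.75)   # (1/0.2)*(2 + 2*0.5/0.2)/4
  a <- n2o_rate_atom_balance(c(0, 24), c(0, 48), c(0, 12), F = 0.2,
                             volume_L = 4)
  expect_equal(a$value, 3.75)   # (48 + 24)/(0.2*24*4)
  expect_equal(n2o_rate_printed(c(0, 24), c(5, 5), c(1, 1), 0.2, 4)$value, 0)
  expect_equal(n2o_rate_atom_balance(c(0, 24), c(5, 5), c(1, 1), 0.2,
                                     4)$value, 0)
  expect_error(n2o_rate_printed(c(0, 24), c(0, 48), c(0, 12), 0.2, 0),
               "volume")
})

test_that("both N2O estimators are linear in the isotopologue increments", {
  t <- c(0, 24)
  for (c_scale in c(0.5, 2, 10)) {
    p1 <- n2o_rate_printed(t, c(0, 48), c(0, 12), 0.2, 4)$value
    p2 <- n2o_rate_printed(t, c(0, 48 * c_scale), c(0, 12 * c_scale),
                           0.2, 4)$value
    expect_equal(p2, c_scale * p1, tolerance = 1e-12)
    a1 <- n2o_rate_atom_balance(t, c(0, 48), c(0, 12), 0.2, 4)$value
    a2 <- n2o_rate_atom_balance(t, c(0, 48 * c_scale), c(0, 12 * c_scale),
                                0.2, 4)$value
    expect_equal(a2, c_scale * a1, tolerance = 1e-12)
  }
})

test_that("printed/atom-balance ratio equals 2 - F under binomial pairing", {
  for (F in c(0.05, 0.1, 0.2, 0.5)) {
    added <- 10 * F / (1 - F)  # ambient 10 -> atom fraction F
    cfg <- sim_config(true_n2o_rate = 8, ambient_nh4 = 10,
                      added_15nh4 = added, noise_cv = 0,
                      pairing_model = "binomial")
    expect_equal(cfg$F, F, tolerance = 1e-12)
    sim <- simulate_incubation(cfg)
    p <- n2o_rate_printed(sim$time_h, sim$n2o45_pmol, sim$n2o46_pmol,
                          cfg$F, cfg$volume)$value
    a <- n2o_rate_atom_balance(sim$time_h, sim$n2o45_pmol, sim$n2o46_pmol,
                               cfg$F, cfg$volume)$value
    expect_equal(p / a, 2 - F, tolerance = 1e-9)
    expect_equal(a, 8, tolerance = 1e-9)  # atom balance is unbiased
  }
})

test_that("percent change signs encode inhibition vs promotion", {
  expect_equal(percent_change(75, 100), -25)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(123, 100), 23)
  expect_error(percent_change(50, 0), "control")
})
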