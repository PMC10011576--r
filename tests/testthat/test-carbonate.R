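test_that("dissociation constants evaluate in published ranges and are deterministic", {
  ks <- carb_constants(25, 35)
  expect_gt(-log10(ks$K1), 5.8); expect_lt(-log10(ks$K1), 6.1)
  expect_gt(-log10(ks$K2), 8.9); expect_lt(-log10(ks$K2), 9.3)
  expect_gt(ks$K1, ks$K2)
  # K1 increases with temperature over the oceanographic range
  expect_gt(carb_constants(25, 35)$K1, carb_constants(5, 35)$K1)
  # determinism
  expect_identical(carb_constants(25, 35), carb_constants(25, 35))
  expect_error(carb_constants(60, 35), "temperature")
  expect_error(carb_constants(25, 60), "salinity")
})

test_that("total boron is linear in salinity with the published S=35 value", {
  expect_equal(total_boron(0), 0)
  b35 <- total_boron(35)
  expect_gt(b35, 410); expect_lt(b35, 420)
  expect_equal(total_boron(17.5), b35 / 2)
})

test_that("speciation identities hold on every returned state", {
  set.seed(42)
  for (i in 1:25) {
    ph <- runif(1, 7, 8.6); dic <- runif(1, 1500, 2400)
    te <- runif(1, 5, 30); sa <- runif(1, 10, 40)
    st <- speciate_from_ph_dic(ph, dic, te, sa)
    expect_equal(st$co2_star + st$hco3 + st$co3, st$dic,
                 tolerance = 1e-6)
    expect_equal(st$hco3 + 2 * st$co3 + st$boh4 + st$oh - st$h, st$ta,
                 tolerance = 1e-6)
    expect_true(all(unlist(st[c("co2_star", "hco3", "co3", "boh4",
                                "oh", "h")]) >= 0))
  }
})

test_that("pH at pK1 splits CO2* and HCO3- equally; zero DIC leaves borate-water TA", {
  ks <- carb_constants(25, 35)
  st <- speciate_from_ph_dic(-log10(ks$K1), 2000, constants = ks)
  expect_equal(st$co2_star, st$hco3, tolerance = 1e-9)
  st0 <- speciate_from_ph_dic(8.1, 0, constants = ks)
  expect_equal(st0$co2_star + st0$hco3 + st0$co3, 0)
  expect_equal(st0$ta, st0$boh4 + st0$oh - st0$h, tolerance = 1e-9)
})

test_that("the three solve directions agree pairwise on a seeded grid", {
  set.seed(7)
  ks <- carb_constants(25, 30)
  for (i in 1:100) {
    ph <- runif(1, 7.2, 8.5); dic <- runif(1, 1600, 2300)
    st <- speciate_from_ph_dic(ph, dic, constants = ks)
    back1 <- solve_ph_from_ta_dic(st$ta, dic, constants = ks)
    expect_equal(back1$ph, ph, tolerance = 1e-6)
    back2 <- solve_from_ta_pco2(st$ta, st$pco2, constants = ks)
    expect_equal(back2$ph, ph, tolerance = 1e-6)
    expect_equal(back2$dic, dic, tolerance = 1e-3)
    expect_equal(back2$pco2, st$pco2, tolerance = 1e-3)
  }
})

test_that("bracketed root finder matches a brute-force grid-search oracle", {
  set.seed(11)
  ks <- carb_constants(18, 32)
  ph_grid <- seq(2, 12, length.out = 1e6)
  for (i in 1:50) {
    ph_true <- runif(1, 7, 8.6); dic <- runif(1, 1500, 2400)
    ta <- speciate_from_ph_dic(ph_true, dic, constants = ks)$ta
    # oracle: pH grid point minimising |TA(ph) - ta|
    ta_grid <- vapply(
      ph_grid[abs(ph_grid - ph_true) < 0.01],
      function(p) speciate_from_ph_dic(p, dic, constants = ks)$ta, numeric(1))
    sub_grid <- ph_grid[abs(ph_grid - ph_true) < 0.01]
    ph_oracle <- sub_grid[which.min(abs(ta_grid - ta))]
    solved <- solve_ph_from_ta_dic(ta, dic, constants = ks)$ph
    expect_equal(solved, ph_oracle, tolerance = 2 * 10 / 1e6)
  }
})

test_that("pCO2 decreases monotonically in pH at fixed DIC", {
  ks <- carb_constants(25, 35)
  phs <- seq(6, 10, by = 0.1)
  pco2 <- vapply(phs, function(p)
    speciate_from_ph_dic(p, 2000, constants = ks)$pco2, numeric(1))
  expect_true(all(diff(pco2) < 0))
})

test_that("doubling pCO2 at fixed TA lowers pH by 0.25-0.35 units at 25 degC", {
  ph400 <- solve_from_ta_pco2(2300, 400, 25, 35)$ph
  ph800 <- solve_from_ta_pco2(2300, 800, 25, 35)$ph
  gap <- ph400 - ph800
  expect_gt(gap, 0.25); expect_lt(gap, 0.35)
  # pH rises monotonically as pCO2 falls toward zero
  pco2s <- c(800, 400, 200, 100, 50)
  phs <- vapply(pco2s, function(p) solve_from_ta_pco2(2300, p, 25, 35)$ph,
                numeric(1))
  expect_true(all(diff(phs) > 0))
})

test_that("infeasible pairs are reported, not fabricated", {
  expect_error(solve_ph_from_ta_dic(1e9, 2000, 25, 35), "no pH")
})

test_that("NBS to seawater scale conversion shifts pH by a small negative offset", {
  d <- ph_nbs_to_sws(8.2, 25, 35) - 8.2
  expect_lt(d, 0)     # SWS pH below NBS pH
  expect_gt(d, -0.2)  # offset magnitude ~0.1
})
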