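dose_np <- d2o_dose(1.6885, 337.7, purity = 1)

test_that("dam curve matches dilution at t = 0 and washes out completely", {
  dose <- d2o_dose(10, 2000, purity = 1)
  rates <- kinetic_rates(0.03, 0.02, 0.02)
  pools <- water_pools(100, 70)
  expect_equal(dam_tracer_concentration(0, dose, rates, pools), 0.1)
  expect_equal(dam_tracer_concentration(24, dose, rates, pools),
               0.1 * exp(-1.2), tolerance = 1e-12)
  expect_lt(dam_tracer_concentration(1e4, dose, rates, pools), 1e-20)
  expect_error(dam_tracer_concentration(-1, dose, rates, pools), "time")
})

test_that("litter curve is zero at injection, non-negative, and unimodal", {
  rates <- kinetic_rates(0.01217, 0.01223, 0.02)
  pools <- water_pools(259.7, 70)
  expect_equal(litter_tracer_concentration(0, dose_np, rates, pools), 0)
  tt <- seq(0, 200, by = 0.5)
  cl <- litter_tracer_concentration(tt, dose_np, rates, pools)
  expect_true(all(cl >= 0))
  peak_grid <- tt[which.max(cl)]
  expect_equal(litter_peak_time(rates), peak_grid, tolerance = 0.5 / peak_grid)
  d <- diff(cl)
  expect_true(all(d[tt[-1] <= peak_grid - 1] > 0))
  expect_true(all(d[tt[-length(tt)] >= peak_grid + 1] < 0))
  expect_error(litter_tracer_concentration(-0.1, dose_np, rates, pools), "time")
})

test_that("closed forms agree with numerical ODE integration to 1e-8 relative", {
  # the reference scenario from the study design
  rates <- kinetic_rates(0.01217, 0.01223, 0.02)
  pools <- water_pools(259.7, 70)
  tt <- c(3, 24, 48, 72, 96)
  ode <- ode_concentrations(tt, dose_np, rates, pools)
  expect_equal(dam_tracer_concentration(tt, dose_np, rates, pools),
               unname(ode$dam), tolerance = 1e-8)
  expect_equal(litter_tracer_concentration(tt, dose_np, rates, pools),
               unname(ode$litter), tolerance = 1e-8)

  # randomized positive parameter sets on a 0-96 h grid
  set.seed(11)
  grid <- seq(0.5, 96, length.out = 40)
  for (i in 1:10) {
    r <- kinetic_rates(runif(1, 0.005, 0.1), runif(1, 0.001, 0.05),
                       runif(1, 0.005, 0.1))
    p <- water_pools(runif(1, 50, 500), runif(1, 20, 300))
    d <- d2o_dose(runif(1, 0.5, 3), 300, purity = 1)
    ode <- ode_concentrations(grid, d, r, p)
    expect_equal(dam_tracer_concentration(grid, d, r, p), unname(ode$dam),
                 tolerance = 1e-8)
    expect_equal(litter_tracer_concentration(grid, d, r, p),
                 unname(ode$litter), tolerance = 1e-8)
  }
})

test_that("degenerate equal-rate case uses the limit form and matches the ODE", {
  rates <- kinetic_rates(0.0122, 0.0122, 0.0244)  # k02 = lambda1 exactly
  pools <- water_pools(260, 70)
  tt <- c(12, 24, 48, 96)
  ode <- ode_concentrations(tt, dose_np, rates, pools)
  expect_equal(litter_tracer_concentration(tt, dose_np, rates, pools),
               unname(ode$litter), tolerance = 1e-8)
  D <- dose_np$purity * dose_np$d2o_mass
  expect_equal(litter_tracer_concentration(48, dose_np, rates, pools),
               D * 0.0122 * 48 * exp(-0.0244 * 48) / 70, tolerance = 1e-12)
  # peak time limit form 1/lambda1
  expect_equal(litter_peak_time(kinetic_rates(0.01, 0.01, 0.02)), 50)
  expect_gt(litter_peak_time(kinetic_rates(0.05, 0.001, 0.09)), 0)
})

test_that("tracer mass is conserved along the flows to 1e-6 relative", {
  rates <- kinetic_rates(0.01217, 0.01223, 0.02)
  tt <- seq(1, 96, by = 5)
  sol <- ode_eliminated(tt, dose_np, rates)
  D <- dose_np$purity * dose_np$d2o_mass
  expect_equal(unname(sol$m1 + sol$m2 + sol$out), rep(D, length(tt)),
               tolerance = 1e-6)
})

test_that("steady-state flows satisfy the balance identities", {
  rates <- kinetic_rates(0.012, 0.01223, 0.03)
  pools <- water_pools(282.1, 200)
  fl <- steady_state_flows(rates, pools)
  expect_equal(fl$r_dam_to_litter, 0.01223 * 282.1)  # 3.4501 g/h
  expect_identical(fl$r_in_dam - fl$r_out_dam - fl$r_dam_to_litter, 0)
  expect_equal(fl$r_in_litter + fl$r_dam_to_litter, fl$r_out_litter)

  # no lactation: milk flow vanishes and dam intake equals dam output
  fl0 <- steady_state_flows(kinetic_rates(0.012, 0, 0.02), pools)
  expect_identical(fl0$r_dam_to_litter, 0)
  expect_identical(fl0$r_in_dam, fl0$r_out_dam)

  # litter storing water (growth) is flagged, not rejected
  expect_warning(
    fl_neg <- steady_state_flows(kinetic_rates(0.012, 0.02, 0.01),
                                 water_pools(282.1, 100)),
    "steady state")
  expect_lt(fl_neg$r_in_litter, 0)
})

test_that("rate and pool constructors enforce their domains", {
  expect_error(kinetic_rates(0, 0.01, 0.02), "> 0")
  expect_error(kinetic_rates(0.01, -0.001, 0.02), ">= 0")
  expect_silent(kinetic_rates(0.01, 0, 0.02))
  expect_error(water_pools(-1, 10), "positive")
  expect_error(d2o_dose(0, 300), "> 0")
  expect_warning(d2o_dose(0.05, 300), "dose rate")  # 0.167 g/g: unit mistake
  expect_equal(lambda_dam(kinetic_rates(0.01217, 0.01223, 0.02)), 0.0244)
})
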