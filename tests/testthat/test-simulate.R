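test_that("IT initial state places the full dose in the target lining fluid", {
  lung <- default_fixture_lung()
  mtr <- fixture_compounds()$MTR
  d <- dose_spec("IT", amount_mg_per_kg = 1, target = "airways")
  y <- initial_state_it(lung, d, mtr)
  expect_equal(unname(y[["aw_lining"]]), 0.25) # 1 mg/kg x 0.25 kg
  expect_equal(sum(y), 0.25)                   # conservation at t = 0
  # probe mode fills the lining at the stated molar concentration
  dp <- dose_spec("IT", conc_mM = 1, target = "both")
  yp <- initial_state_it(lung, dp, mtr)
  v_aw <- lung$compartments$volume[lung$compartments$id == "aw_lining"]
  expect_equal(unname(yp[["aw_lining"]]), 1e-3 * v_aw * mtr$mw)
  expect_gt(yp[["alv_lining"]], 0)
  # screening mode doses one region per run
  db <- dose_spec("IT", amount_mg_per_kg = 1, target = "both")
  expect_error(initial_state_it(lung, db, mtr), "target = 'both'")
})

test_that("IV initial state sets the venous concentration from dose and volume", {
  lung <- default_fixture_lung()
  d <- dose_spec("IV", amount_mg_per_kg = 1)
  y <- initial_state_iv(lung, d)
  expect_equal(unname(y[["ven"]]) / 13.6, 0.25 / 13.6) # C0 ~ 0.01838 mg/ml
  expect_equal(unname(y[["ven"]]) / 13.6, 0.01838, tolerance = 1e-3)
  y2 <- initial_state_iv(lung, dose_spec("IV", amount_mg_per_kg = 2))
  expect_equal(sum(y2), 2 * sum(y)) # linear in dose
  expect_true(all(y[setdiff(names(y), "ven")] == 0))
})

test_that("rate matrix conserves mass and implements clearance exactly", {
  lung <- default_fixture_lung()
  for (cmpd in list(fixture_compounds()$MTR, fixture_compounds()$Hoe,
                    compound("g", "monoprotic_base", logPn = 0, pKa = 9))) {
    A <- build_rate_matrix(lung, cmpd)
    expect_equal(max(abs(colSums(A))), 0, tolerance = 1e-12) # CL = 0
  }
  cfg <- lung$config
  cfg$systemic$CL <- 3
  lungCL <- lung_model(cfg)
  A <- build_rate_matrix(lungCL, fixture_compounds()$MTR)
  set.seed(1)
  y <- runif(nrow(A))
  names(y) <- rownames(A)
  # d(total)/dt = -CL * C_venous, exactly
  expect_equal(sum(A %*% y), -3 * y[["ven"]] / 13.6, tolerance = 1e-12,
               ignore_attr = TRUE)
  # rhs agrees with the matrix and rejects broken states
  expect_equal(rhs(0, y, lungCL, fixture_compounds()$MTR),
               drop(A %*% y), tolerance = 1e-12)
  y[["aw_epi"]] <- NaN
  expect_error(rhs(0, y, lungCL, fixture_compounds()$MTR), "aw_epi")
  expect_error(rhs(0, y[-1], lungCL, fixture_compounds()$MTR),
               "compartment count")
})

test_that("closed simulations conserve total mass to 1e-6 relative", {
  lung <- default_fixture_lung()
  solver <- solver_spec(t_end = 240, n_output = 101)
  d <- dose_spec("IT", conc_mM = 1, target = "both")
  for (cmpd in list(fixture_compounds()$MTR, fixture_compounds()$Hoe)) {
    sim <- simulate_lung(lung, cmpd, d, solver)
    tot <- rowSums(sim$amounts)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
    expect_true(all(diff(sim$times) > 0))
    expect_true(all(sim$amounts >= 0))
  }
})

test_that("trajectories are linear in the dose", {
  lung <- default_fixture_lung()
  mtr <- fixture_compounds()$MTR
  solver <- solver_spec(t_end = 60, n_output = 41)
  s1 <- simulate_lung(lung, mtr,
                      dose_spec("IT", amount_mg_per_kg = 1,
                                target = "airways"), solver)
  s2 <- simulate_lung(lung, mtr,
                      dose_spec("IT", amount_mg_per_kg = 2,
                                target = "airways"), solver)
  expect_equal(s2$amounts, 2 * s1$amounts, tolerance = 1e-8)
})

test_that("stiff trajectories match the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  lung <- default_fixture_lung()
  mtr <- fixture_compounds()$MTR
  d <- dose_spec("IT", amount_mg_per_kg = 1, target = "airways")
  solver <- solver_spec(t_end = 120, n_output = 41)
  sim <- simulate_lung(lung, mtr, d, solver)
  A <- build_rate_matrix(lung, mtr)
  y0 <- initial_state_it(lung, d, mtr)
  for (tt in c(1, 30, 120)) {
    i <- which.min(abs(sim$times - tt))
    oracle <- as.numeric(Matrix::expm(A * sim$times[i]) %*% y0)
    expect_equal(unname(sim$amounts[i, ]), oracle,
                 tolerance = 1e-8)
  }
})

test_that("closed-system equilibrium matches the nested Boltzmann/pH-partition product", {
  lung <- default_fixture_lung()
  d <- dose_spec("IT", conc_mM = 1, target = "both")
  solver <- solver_spec(t_end = 2e5, n_output = 51)
  for (cmpd in list(fixture_compounds()$MTR, fixture_compounds()$Hoe)) {
    sim <- simulate_lung(lung, cmpd, d, solver)
    final <- sim$amounts[nrow(sim$amounts), ]
    conc <- final / lung$compartments$volume[
      match(names(final), lung$compartments$id)]
    oracle <- closed_form_equilibrium(lung, cmpd)
    ratio <- conc / (oracle * conc[["ven"]])
    expect_equal(unname(ratio), rep(1, length(ratio)), tolerance = 1e-3)
  }
})

test_that("fixed-blood steady state solves the clamped linear system", {
  lung <- default_fixture_lung()
  mtr <- fixture_compounds()$MTR
  ss <- steady_state_fixed_blood(lung, mtr, C_blood = 0.01)
  A <- build_rate_matrix(lung, mtr, clamp = c("ven", "art"))
  expect_equal(max(abs(A %*% ss)), 0, tolerance = 1e-10)
  expect_equal(unname(ss[["ven"]]), 0.01 * 13.6)
  # agrees with a long clamped integration
  y0 <- ss * 0
  y0[c("ven", "art")] <- ss[c("ven", "art")]
  sim <- simulate_lung(lung, mtr, dose_spec("IV", amount_mg_per_kg = 1),
                       solver_spec(t_end = 2e5, n_output = 31),
                       clamp = c("ven", "art"), y0 = y0)
  expect_equal(unname(sim$amounts[nrow(sim$amounts), ]), unname(ss),
               tolerance = 1e-5)
})
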