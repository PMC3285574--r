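test_that("screen grid matches the stated ranges and counts", {
  g <- screen_grid()
  expect_equal(length(g$logPn), 61) # -2..4 by 0.1
  expect_equal(length(g$pKa), 46)  # 5..14 by 0.2
  expect_equal(length(g$logPn) * length(g$pKa), 2806)
  expect_error(screen_grid(logPn_step = -1))
})

test_that("a small IT screen returns complete, ordered, deterministic rows", {
  lung <- default_fixture_lung()
  g <- screen_grid(-2, 4, 3, 5, 14, 4.5)  # 3 x 3
  sv <- solver_spec(t_end = 60, n_output = 41)
  r <- run_screen(lung, g, route = "IT", solver = sv)
  expect_equal(nrow(r), 9)
  expect_true(all(is.finite(r$auc_airways) & r$auc_airways >= 0))
  expect_true(all(is.finite(r$auc_ratio)))
  expect_length(attr(r, "failures"), 0)
  # deterministic and order-independent: rerun gives identical values
  r2 <- run_screen(lung, g, route = "IT", solver = sv)
  expect_identical(r$auc_ratio, r2$auc_ratio)
})

test_that("IT contrast increases toward hydrophilic, high-pKa compounds", {
  lung <- default_fixture_lung()
  sv <- solver_spec(t_end = 140, n_output = 81)
  corner <- function(lp, pk) {
    g <- screen_grid(lp, lp + 1e-3, 1, pk, pk + 1e-3, 1)
    run_screen(lung, g, route = "IT", solver = sv)$auc_ratio[1]
  }
  expect_gt(corner(-2, 14), corner(4, 5))
  # airway AUC is monotone non-decreasing in pKa along the hydrophilic edge
  g <- screen_grid(-2, -2 + 1e-3, 1, 5, 14, 1.5)
  slice <- run_screen(lung, g, route = "IT", solver = sv)
  expect_true(all(diff(slice$auc_airways) > -1e-9 * slice$auc_airways[-1]))
})

test_that("IV screening deposits the bulk of lung mass in the alveoli", {
  lung <- default_fixture_lung()
  g <- screen_grid(-2, 4, 3, 5, 14, 4.5)
  r <- run_screen(lung, g, route = "IV",
                  solver = solver_spec(t_end = 60, n_output = 41))
  expect_true(all(r$mass_percent_airways < r$mass_percent_alveoli))
  expect_true(all(r$mass_percent_airways >= 0 &
                    r$mass_percent_airways <= 100))
  expect_true(all(abs(r$mass_percent_airways + r$mass_percent_alveoli -
                        100) < 1e-9))
})

test_that("fold-change classification follows the published bands", {
  expect_equal(classify_fold_change(1.05, "increase"), "unaffected")
  expect_equal(classify_fold_change(1.3, "decrease"), "-")
  expect_equal(classify_fold_change(1.3, "increase"), "+")
  expect_equal(classify_fold_change(1.7, "decrease"), "--")
  expect_equal(classify_fold_change(6, "decrease"), "---")
  # the 2-5 band has no symbol in the source scheme and is flagged
  expect_match(classify_fold_change(3, "increase"), "two-to-five")
  expect_error(classify_fold_change(0.5, "increase"))
})

test_that("exchanging an inert (equal-valued) parameter returns fold 1 exactly", {
  cfg <- load_config()
  cfg$regions$airways$macrophage_volume <- 1e-3
  cfg$regions$alveoli$macrophage_volume <- 1e-3
  lung <- lung_model(cfg)
  swapped <- exchange_parameter(lung, "Macrophage Volume")
  expect_equal(swapped$config, lung$config)
  sv <- solver_spec(t_end = 30, n_output = 21)
  mtr <- fixture_compounds()$MTR
  d <- dose_spec("IT", conc_mM = 1, target = "both")
  a1 <- simulate_lung(lung, mtr, d, sv)$amounts
  a2 <- simulate_lung(swapped, mtr, d, sv)$amounts
  expect_identical(a1, a2)
})

test_that("exchanging every region parameter mirrors the regional metrics", {
  lung <- default_fixture_lung()
  mirrored <- exchange_all_parameters(lung)
  sv <- solver_spec(t_end = 60, n_output = 41)
  mtr <- fixture_compounds()$MTR
  sim_base <- simulate_lung(lung, mtr,
                            dose_spec("IT", conc_mM = 1, target = "alveoli"),
                            sv)
  sim_mirr <- simulate_lung(mirrored, mtr,
                            dose_spec("IT", conc_mM = 1, target = "airways"),
                            sv)
  # the mirrored airways are parameterized as the baseline alveoli, so the
  # airway-dosed mirrored run must reproduce the alveoli-dosed baseline
  expect_equal(region_tissue_concentration(sim_mirr, "airways"),
               region_tissue_concentration(sim_base, "alveoli"),
               tolerance = 1e-8)
  expect_equal(region_tissue_concentration(sim_mirr, "alveoli"),
               region_tissue_concentration(sim_base, "airways"),
               tolerance = 1e-8)
})

test_that("exchange analysis table is complete with a clean baseline row", {
  lung <- default_fixture_lung()
  tab <- parameter_exchange_analysis(lung,
                                     solver = solver_spec(t_end = 60,
                                                          n_output = 41))
  expect_equal(tab$parameter[1], "Baseline")
  expect_equal(tab$fold_airways[1], 1)
  expect_equal(tab$category_airways[1], "unaffected")
  expect_setequal(tab$parameter[-1], exchange_parameter_names())
  expect_true(all(tab$fold_airways >= 1))
})
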