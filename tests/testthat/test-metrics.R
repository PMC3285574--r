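# minimal hand-built result object for metric definition checks
fake_result <- function(times, amounts, volumes, regions) {
  comps <- data.frame(id = colnames(amounts), region = regions,
                      role = "epithelial_cytosol", volume = volumes,
                      stringsAsFactors = FALSE)
  structure(list(times = times, amounts = amounts, compartments = comps),
            class = "pk_sim")
}

test_that("trapezoidal AUC reproduces closed-form integrals", {
  expect_equal(auc_trapezoid(c(0, 10), c(2, 2)), 20)          # rectangle
  expect_equal(auc_trapezoid(c(0, 10), c(0, 10)), 50)         # triangle
  t <- seq(0, 5, length.out = 1000)
  expect_equal(auc_trapezoid(t, exp(-t)), 1 - exp(-5), tolerance = 1e-5)
  expect_error(auc_trapezoid(1, 1), "at least 2")
  # additivity over contiguous intervals is exact
  v <- sin(t) + 2
  k <- 400
  expect_equal(auc_trapezoid(t[1:k], v[1:k]) + auc_trapezoid(t[k:1000], v[k:1000]),
               auc_trapezoid(t, v))
})

test_that("regional tissue concentration is the mass-weighted definition", {
  tm <- c(0, 1)
  am <- rbind(c(2, 0, 0), c(2, 0, 0))
  colnames(am) <- c("a1", "a2", "b1")
  res <- fake_result(tm, am, volumes = c(1, 3, 2),
                     regions = c("airways", "airways", "alveoli"))
  # (2 mg in 1 ml + 0 in 3 ml) / 4 ml = 0.5; empty region reads 0
  expect_equal(region_tissue_concentration(res, "airways"), c(0.5, 0.5))
  expect_equal(region_tissue_concentration(res, "alveoli"), c(0, 0))
  # uniform concentration is recovered exactly (weighted-mean identity)
  am2 <- rbind(c(3, 9, 6), c(3, 9, 6))
  colnames(am2) <- colnames(am)
  res2 <- fake_result(tm, am2, c(1, 3, 2),
                      c("airways", "airways", "alveoli"))
  expect_equal(region_tissue_concentration(res2, "airways"), c(3, 3))
  # invariant to re-partitioning mass among compartments of equal summed
  # volume within the region
  am3 <- rbind(c(9, 3, 6), c(9, 3, 6))
  colnames(am3) <- colnames(am)
  res3 <- fake_result(tm, am3, c(3, 1, 2),
                      c("airways", "airways", "alveoli"))
  expect_equal(region_tissue_concentration(res3, "airways"),
               region_tissue_concentration(res2, "airways"))
})

test_that("mass percents partition the lung and exclude systemic blood", {
  tm <- c(0, 10)
  am <- rbind(c(1, 3, 50), c(2, 2, 50))
  colnames(am) <- c("aw", "alv", "ven")
  res <- fake_result(tm, am, c(1, 1, 14),
                     c("airways", "alveoli", "systemic"))
  expect_equal(mass_percent(res, "airways", 0), 25)
  expect_equal(mass_percent(res, "airways", 0) +
                 mass_percent(res, "alveoli", 0), 100)
  expect_equal(mass_percent(res, "airways", 10), 50) # interpolated endpoint
  am0 <- am; am0[, 1:2] <- 0
  res0 <- fake_result(tm, am0, c(1, 1, 14),
                      c("airways", "alveoli", "systemic"))
  expect_error(mass_percent(res0, "airways", 5), "undefined")
})

test_that("AUC ratio is symmetric and rejects degenerate runs", {
  tm <- seq(0, 10, length.out = 11)
  am <- cbind(aw = exp(-tm), alv = 2 * exp(-tm))
  res <- fake_result(tm, am, c(1, 1), c("airways", "alveoli"))
  r <- auc_ratio(res, res)
  expect_equal(r, 0.5)
  # ratio(a,b) * ratio(b,a) = 1 by construction
  am_sw <- cbind(aw = 2 * exp(-tm), alv = exp(-tm))
  res_sw <- fake_result(tm, am_sw, c(1, 1), c("airways", "alveoli"))
  expect_equal(auc_ratio(res, res) * auc_ratio(res_sw, res_sw), 1)
  am0 <- cbind(aw = exp(-tm), alv = rep(0, 11))
  res0 <- fake_result(tm, am0, c(1, 1), c("airways", "alveoli"))
  expect_error(auc_ratio(res0, res0), "degenerate")
})

test_that("time to steady state matches the exponential closed form", {
  t <- seq(0, 200, by = 0.05)
  expect_equal(time_to_steady_state(t, rep(3, length(t))), 0)
  k <- 0.1
  series <- 5 * (1 - exp(-k * t))
  expect_equal(time_to_steady_state(t, series, fraction = 0.95),
               log(20) / k, tolerance = 0.01)
  # monotone in the fraction
  expect_gte(time_to_steady_state(t, series, fraction = 0.99),
             time_to_steady_state(t, series, fraction = 0.95))
  # a still-rising series has no Tss
  expect_error(time_to_steady_state(seq(0, 10, 0.1), seq(0, 10, 0.1)),
               "not converged")
})

test_that("region_metrics summarizes a real simulation coherently", {
  lung <- default_fixture_lung()
  sim <- simulate_lung(lung, fixture_compounds()$MTR,
                       dose_spec("IT", conc_mM = 1, target = "both"),
                       solver_spec(t_end = 240, n_output = 101))
  rm <- region_metrics(sim)
  expect_equal(nrow(rm), 2)
  expect_true(all(rm$auc > 0))
  expect_equal(sum(rm$mass_percent_end), 100)
  expect_equal(unique(rm$auc_horizon), 240)
})
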