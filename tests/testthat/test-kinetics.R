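test_that("ideal-gas conversion matches hand calculation and is linear", {
  # 10 ppmv in a 120 mL vial at 298.15 K / 101325 Pa
  expect_equal(signif(ppmv_to_nmol(10, 0.120, 298.15, 101325), 4), 49.05)
  expect_equal(ppmv_to_nmol(0), 0)
  expect_equal(ppmv_to_nmol(10, 0.240), 2 * ppmv_to_nmol(10, 0.120))
  expect_error(ppmv_to_nmol(10, 0), "positive")
  # round trip through the inverse
  x <- c(0.5, 3, 10, 400)
  expect_equal(nmol_to_ppmv(ppmv_to_nmol(x)), x, tolerance = 1e-12)
})

test_that("exponential-floor fits recover generating parameters exactly", {
  for (k in c(0.02, 0.1, 0.5)) {
    s <- simulate_gas_series(k, 10, 0.5, seq(0, 24, 2))
    f <- fit_uptake(s)
    expect_equal(f$model, "exponential_floor")
    expect_equal(f$k_per_h, k, tolerance = 1e-6)
    expect_equal(f$ceq_ppmv, 0.5, tolerance = 1e-5)
    expect_equal(f$initial_rate_ppmv_per_h, k * 9.5, tolerance = 1e-5)
  }
})

test_that("degenerate and shallow series are handled and flagged", {
  flat <- gas_series("s", 0:5, rep(10, 6))
  f <- fit_uptake(flat)
  expect_equal(f$k_per_h, 0)
  expect_equal(f$initial_rate_ppmv_per_h, 0)
  expect_equal(f$flag, "constant_series")
  expect_error(fit_uptake(gas_series("s", 0:2, c(10, 9, 8))), "4 time points")
  # nearly-linear shallow decay falls back to the initial slope
  sh <- gas_series("s", 0:5, 10 - 0.01 * (0:5) + c(0, 1e-4, -1e-4, 0, 1e-4, 0))
  fs <- fit_uptake(sh)
  if (fs$model == "linear_initial") {
    expect_equal(fs$initial_rate_ppmv_per_h, 0.01, tolerance = 0.05)
  }
})

test_that("rates are invariant to consistent time-unit rescaling", {
  s_h <- simulate_gas_series(0.3, 10, 0.5, seq(0, 12, 1.5))
  s_d <- gas_series("s", s_h$times_h / 24, s_h$ppmv)
  expect_equal(fit_uptake(s_d)$k_per_h, fit_uptake(s_h)$k_per_h * 24,
               tolerance = 1e-5)
})

test_that("bulk rates chain ppmv/h through vial geometry and controls", {
  s <- simulate_gas_series(0.2, 10, 0.5, seq(0, 24, 2))
  f <- fit_uptake(s)
  br <- bulk_rate(f, s)
  expect_equal(br$rate_nmol_per_g_h,
               ppmv_to_nmol(f$initial_rate_ppmv_per_h) / 5, tolerance = 1e-9)
  # hand chain: 1.9 ppmv/h -> 1.9/10 * 49.049 / 5 g = 1.864
  fh <- desertprod:::uptake_fit(0.2, 10, 0.5, 1, "exponential_floor")
  expect_equal(signif(bulk_rate(fh, s)$rate_nmol_per_g_h, 4), 1.864)
  # blank equal to live zeroes the rate with a flag
  z <- bulk_rate(f, s, blank_fit = f)
  expect_equal(z$rate_nmol_per_g_h, 0)
  expect_true(z$flagged)
})

test_that("heat-killed series carry no biological signal", {
  killed <- simulate_gas_series(0, 10, 0.5, seq(0, 24, 2), noise_sd_ppmv = 0.05,
                                seed = 6, is_control = "heat_killed")
  f <- fit_uptake(killed)
  expect_lt(bulk_rate(f, killed)$rate_nmol_per_g_h, 0.02)
})

test_that("cell-specific normalization is plain unit algebra", {
  expect_equal(cell_specific_rate(1.864, 1e9), 1.864)
  expect_equal(cell_specific_rate(1, 5e8), 2 * cell_specific_rate(1, 1e9))
  expect_error(cell_specific_rate(1, 0), "copies_per_g")
})

test_that("zone fold changes are mean ratios with a paired variant", {
  rates <- data.frame(sample_id = rep(sprintf("s%d", 1:3), 2),
                      zone = rep(c("sub-humid", "hyper-arid"), each = 3),
                      rate = c(0.01, 0.02, 0.03, 2.5, 2.9, 3.12))
  fc <- zone_fold_change(rates, "sub-humid", "hyper-arid")
  expect_equal(fc$fold_of_means, mean(c(2.5, 2.9, 3.12)) / 0.02)
  expect_equal(zone_fold_change(rates, "sub-humid", "sub-humid")$fold_of_means, 1)
  # permutation symmetry
  perm <- rates[sample(nrow(rates)), ]
  expect_equal(zone_fold_change(perm, "sub-humid", "hyper-arid")$fold_of_means,
               fc$fold_of_means)
  paired <- zone_fold_change(rates, "sub-humid", "hyper-arid", paired = TRUE)
  expect_equal(paired$mean_of_ratios, mean(c(250, 145, 104)))
  expect_error(zone_fold_change(rates, "missing", "hyper-arid"), "nonempty")
})

test_that("bootstrap intervals for k cover the truth at near-nominal rate", {
  covered <- vapply(1:60, function(r) {
    s <- simulate_gas_series(0.2, 10, 0.5, seq(0, 24, 2), noise_sd_ppmv = 0.02,
                             noise_type = "proportional", seed = 500 + r)
    ci <- uptake_ci(s, n_boot = 99L, seed = r)
    ci$lower <= 0.2 && 0.2 <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})
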