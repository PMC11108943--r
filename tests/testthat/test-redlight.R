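test_that("red-light C_i inversion matches its algebra and boundary cases", {
  expect_equal(invert_ci_redlight(A = 4, R_d = 1, J_a = 60, Gamma_star = 40),
               40 * 100 / 40)
  expect_equal(invert_ci_redlight(A = -1, R_d = 1, J_a = 60,
                                  Gamma_star = 40), 40)  # G = 0
  expect_error(invert_ci_redlight(A = 14, R_d = 1, J_a = 60,
                                  Gamma_star = 40), "singular")
  expect_error(invert_ci_redlight(A = -2, R_d = 1, J_a = 60,
                                  Gamma_star = 40), "quality")
  # inverse of the forward RuBP rate
  p <- fvcb_params(J = 60, R_d = 1, Gamma_star = 40)
  ci <- c(80, 150, 300)
  A <- net_assimilation(ci, p, rates = "rubp")
  expect_equal(invert_ci_redlight(A, 1, 60, 40), ci, tolerance = 1e-10)
})

test_that("conductance-from-fluxes inverts the ternary equation", {
  expect_equal(leaf_co2_conductance_from_fluxes(2, 0.0005, 400, 100),
               (2 + 0.00025 * 500) / 300, tolerance = 1e-12)
  expect_equal(leaf_co2_conductance_from_fluxes(2, 0, 400, 100), 2 / 300,
               tolerance = 1e-12)
  expect_error(leaf_co2_conductance_from_fluxes(2, 0, 400, 400), "undefined")
  # exact inverse of intercellular_co2 at matching g_tc
  g <- 0.0071
  ci <- intercellular_co2(2, 0.0005, 400, g)
  expect_equal(leaf_co2_conductance_from_fluxes(2, 0.0005, 400, ci), g,
               tolerance = 1e-12)
})

test_that("the water/CO2 conductance system solves and round-trips", {
  s <- solve_gcw(0.01, 0.003375)
  expect_equal(s$g_cw, 0.005)
  expect_equal(s$g_sw, 0.005)
  # limits: pure stomatal and pure cuticular leaves
  expect_equal(solve_gcw(0.02, 0.02 / 1.6)$g_cw, 0, tolerance = 1e-12)
  expect_equal(solve_gcw(0.02, 0.02 / 20)$g_cw, 0.02, tolerance = 1e-12)
  # recombining through the CO2-side composition reproduces g_lc exactly
  for (glw in c(0.008, 0.015, 0.05)) {
    glc <- 0.4 * glw
    s <- solve_gcw(glw, glc)
    expect_equal(leaf_conductance_co2(s$g_sw, s$g_cw), glc,
                 tolerance = 1e-15)
  }
  expect_warning(solve_gcw(0.01, 0.009), "outside")
})

test_that("J and Gamma_star are recovered from a clean companion curve", {
  ci <- seq(60, 800, length.out = 40)
  p <- fvcb_params(J = 60, R_d = 1, Gamma_star = 40)
  curve <- data.frame(Ci = ci, A = net_assimilation(ci, p, rates = "rubp"))
  est <- estimate_j_gammastar(curve, R_d = 1)
  expect_equal(unname(est["J_a"]), 60, tolerance = 1e-6)
  expect_equal(unname(est["Gamma_star"]), 40, tolerance = 1e-6)
  # fitted model passes through -R_d at the compensation point
  expect_equal(est[["J_a"]] * (40 - est[["Gamma_star"]]) /
                 (4 * 40 + 8 * est[["Gamma_star"]]) - 1, -1,
               tolerance = 1e-6)
  high <- curve[curve$Ci > 300, ]
  expect_error(estimate_j_gammastar(high, R_d = 1), "identifiable")
})

test_that("red-light estimation recovers the true cuticular conductance", {
  run <- generate_redlight_run(params = fvcb_params(J = 60, R_d = 1),
                               noise = noise_spec(0, 0))
  # exact boundary-layer removal: machine-precision closure
  est <- estimate_gcw(run, J_a = 60, Gamma_star = 42.75, g_bw = 2.23)
  expect_equal(est$n_used, 42)
  expect_equal(est$mean, 0.0056, tolerance = 1e-6)
  expect_lt(est$sd, 1e-10)
  # boundary layer treated as non-limiting: small, sub-2% bias
  est2 <- estimate_gcw(run, J_a = 60, Gamma_star = 42.75)
  expect_lt(abs(est2$mean - 0.0056) / 0.0056, 0.02)
})

test_that("recovered g_cw spread across noisy leaves matches field precision", {
  means <- vapply(1:5, function(s) {
    run <- generate_redlight_run(noise = noise_spec(0.00415, 0), seed = s)
    estimate_gcw(run, J_a = 60, Gamma_star = 42.75, g_bw = 2.23)$mean
  }, 0)
  expect_gt(sd(means), 2e-4)
  expect_lt(sd(means), 2.5e-3)
  # window averaging: per-record spread shrinks ~ 1/sqrt(42) in the mean
  one <- estimate_gcw(generate_redlight_run(noise = noise_spec(0.00415, 0),
                                            seed = 99),
                      J_a = 60, Gamma_star = 42.75, g_bw = 2.23)
  expect_lt(sd(means), 3 * one$sd / sqrt(42) * 3)
})
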