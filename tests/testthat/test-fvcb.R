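test_that("limiting rates have the standard FvCB forms", {
  p <- fvcb_params()   # V_cmax 50, J 100, Gamma_star 42.75, K_m ~ 710.3
  Km <- michaelis_co2(p)
  expect_equal(Km, 404.9 * (1 + 210 / 278.4))
  expect_equal(rubisco_limited_rate(p$Gamma_star, p), 0)
  expect_equal(rubp_limited_rate(p$Gamma_star, p), 0)
  expect_equal(rubisco_limited_rate(300, p), 50 * 257.25 / (300 + Km),
               tolerance = 1e-12)
  expect_equal(rubp_limited_rate(300, p), 100 * 257.25 / 1542,
               tolerance = 1e-12)
  # asymptotes
  expect_equal(rubisco_limited_rate(1e9, p), 50, tolerance = 1e-6)
  expect_equal(rubp_limited_rate(1e9, p), 25, tolerance = 1e-6)
  expect_equal(tpu_limited_rate(fvcb_params(TPU = 8)), 24)
  expect_equal(tpu_limited_rate(fvcb_params(TPU = 10.52)), 31.56)
  expect_identical(tpu_limited_rate(p), Inf)
})

test_that("net assimilation is the binding minimum less respiration", {
  p <- fvcb_params(R_d = 0)
  expect_equal(net_assimilation(p$Gamma_star, p), 0)
  expect_equal(net_assimilation(300, p), rubisco_limited_rate(300, p))
  expect_equal(limiting_rate(300, p), "Rubisco")
  # TPU-limited case: min(25.07, 21.38, 21) - 1 = 20
  p2 <- fvcb_params(V_cmax = 50, J = 100, TPU = 7, R_d = 1)
  expect_equal(net_assimilation(800, p2), 20, tolerance = 1e-3)
  expect_equal(limiting_rate(800, p2), "TPU")
})

test_that("limitation transitions match closed forms and numeric intersections", {
  p <- fvcb_params(V_cmax = 50, J = 100)
  t1 <- transition_ci(p, "first")
  expect_equal(t1, (100 * michaelis_co2(p) - 8 * 42.75 * 50) / (200 - 100),
               tolerance = 1e-12)
  expect_equal(t1, 539.32, tolerance = 1e-4)
  # independent cross-check: root of A_c - A_j
  num <- uniroot(function(ci) rubisco_limited_rate(ci, p) -
                   rubp_limited_rate(ci, p), c(100, 2000), tol = 1e-10)$root
  expect_equal(t1, num, tolerance = 1e-6)

  p2 <- fvcb_params(J = 100, TPU = 7)
  t2 <- transition_ci(p2, "second")
  expect_equal(t2, 42.75 * 268 / 16, tolerance = 1e-12)
  num2 <- uniroot(function(ci) rubp_limited_rate(ci, p2) - 21,
                  c(100, 5000), tol = 1e-10)$root
  expect_equal(t2, num2, tolerance = 1e-6)
  # absences: RuBP curve never overtakes Rubisco / never reaches 3 TPU
  expect_true(is.na(transition_ci(fvcb_params(V_cmax = 20, J = 100))))
  expect_true(is.na(transition_ci(fvcb_params(J = 100, TPU = 9), "second")))
})

test_that("coupled solver closes both equations and honours its limits", {
  ch <- chamber_state(C_a = 400)
  p <- fvcb_params(R_d = 0)
  # infinite-conductance limit: drawdown vanishes (no vapour flux so the
  # ternary term does not blow up with g_lw, and no boundary-layer cap)
  s <- coupled_solve(1000, 0, chamber_state(C_a = 400, VPD = 0, g_bw = 1e9),
                     p)
  expect_equal(s$C_i, 400, tolerance = 1e-2)
  # worked low-conductance case, both pathways
  u <- coupled_solve(0.056, 0.0056, ch, p, "uncorrected")
  co <- coupled_solve(0.056, 0.0056, ch, p, "corrected")
  expect_equal(u$C_i, 178, tolerance = 0.03)
  expect_equal(co$C_i, 169, tolerance = 0.03)
  expect_equal(ci_misestimation(u$C_i, co$C_i), 0.053, tolerance = 0.05)
  for (s2 in list(u, co)) {
    expect_lt(abs(s2$residual), 1e-8)
    # substituting back into the ternary equation closes
    expect_equal(intercellular_co2(s2$A, s2$E, 400, s2$g_tc, quiet = TRUE),
                 s2$C_i, tolerance = 1e-8)
    expect_equal(net_assimilation(s2$C_i, p), s2$A, tolerance = 1e-10)
  }
  expect_error(coupled_solve(0.005, 0.0056, ch, p, "corrected"),
               "non-physical")
})

test_that("coupled solver agrees with the exhaustive grid-search oracle", {
  set.seed(7)
  for (i in 1:12) {
    g_lw <- runif(1, 0.01, 0.6)
    ca <- runif(1, 150, 600)
    vc <- runif(1, 30, 120)
    j <- runif(1, 60, 220)
    p <- fvcb_params(V_cmax = vc, J = j, R_d = 1.5)
    ch <- chamber_state(C_a = ca)
    s <- coupled_solve(g_lw, 0, ch, p, "uncorrected")
    ora <- oracle_ci_grid(oracle_gtc_uncorr(g_lw), s$E, ca, vc, j, 1.5)
    expect_lt(abs(s$C_i - ora), 0.001 + 1e-9)
  }
})

test_that("C_i rises with leaf conductance and falls under correction", {
  ch <- chamber_state(C_a = 400)
  p <- fvcb_params()
  g <- seq(0.02, 0.5, length.out = 15)
  ci_u <- vapply(g, function(x) coupled_solve(x, 0.0056, ch, p)$C_i, 0)
  expect_true(all(diff(ci_u) > 0))
  ci_c <- vapply(g, function(x)
    coupled_solve(x, 0.0056, ch, p, "corrected")$C_i, 0)
  expect_true(all(ci_c < ci_u))
})

test_that("the solver handles net CO2 release at near-compensation ambient CO2", {
  # at C_a = 50 with respiration the leaf is a source and C_i exceeds C_a
  s <- coupled_solve(0.1, 0, chamber_state(C_a = 50), fvcb_params(R_d = 1.5))
  expect_lt(s$A, 0)
  expect_gt(s$C_i, 50)
  expect_lt(abs(s$residual), 1e-8)
})
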