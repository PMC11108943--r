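test_that("curve recomputation reproduces the two conductance pathways", {
  st <- stomatal_model(g_max = 0.17 - 0.0056, g_min = 0.17 - 0.0056,
                       g_cw_true = 0.0056)
  run <- generate_curve(protocol_ss(), stomata = st, noise = noise_spec(0, 0))
  unc <- recompute_curve(run, 0.0056, "uncorrected")
  expect_equal(unc$Ci, run$Ci, tolerance = 1e-10)  # instrument calculation
  cor <- recompute_curve(run, 0.0056, "corrected")
  expect_equal(unique(round(cor$g_sw_used, 6)), 0.1644)
  ok <- cor$flag == "ok" & run$A > 0.5
  expect_true(all(cor$Ci[ok] < unc$Ci[ok]))
  # g_cw = 0: corrected equals uncorrected exactly
  cor0 <- recompute_curve(run, 0, "corrected")
  expect_equal(cor0$Ci, unc$Ci, tolerance = 1e-12)
  # non-physical rows are flagged, not dropped
  low <- run
  low$gsw[1] <- 0.004
  flagged <- recompute_curve(low, 0.0056, "corrected")
  expect_equal(flagged$flag[1], "nonphysical")
  expect_equal(nrow(flagged), nrow(run))
})

test_that("noise-free parameter recovery is essentially exact", {
  truth <- fvcb_params(V_cmax = 100, J = 150, TPU = 9, R_d = 1.5)
  run <- make_clean_curve(truth)
  fit <- fit_aci(recompute_curve(run, 0.0056, "corrected"), fit_tpu = TRUE)
  expect_true(fit$convergence)
  rel <- abs(fit$coef - c(100, 150, 1.5, 9)) / c(100, 150, 1.5, 9)
  expect_true(all(rel < 0.005))
  expect_equal(fit$C_itrans1, transition_ci(truth), tolerance = 1e-3)
  expect_equal(fit$C_itrans2, transition_ci(truth, "second"),
               tolerance = 1e-3)
})

test_that("fitted transitions are internally consistent intersections", {
  truth <- fvcb_params(V_cmax = 80, J = 140, TPU = 10, R_d = 1)
  fit <- fit_aci(recompute_curve(make_clean_curve(truth), 0.0056,
                                 "corrected"), fit_tpu = TRUE)
  expect_equal(rubisco_limited_rate(fit$C_itrans1, fit$params),
               rubp_limited_rate(fit$C_itrans1, fit$params),
               tolerance = 1e-6)
})

test_that("a curve truncated below the TPU transition reports TPU absent", {
  truth <- fvcb_params(V_cmax = 100, J = 150, TPU = 9, R_d = 1.5)
  # true second transition ~ 372; stop the ramp well below it
  run <- make_clean_curve(truth, protocol = protocol_racir(100, 400))
  fit <- fit_aci(recompute_curve(run, 0.0056, "corrected"), fit_tpu = TRUE)
  expect_true(is.na(fit$coef["TPU"]))
  expect_true(is.na(fit$C_itrans2))
  # the other parameters are still recovered
  expect_equal(unname(fit$coef["V_cmax"]), 100, tolerance = 0.005)
})

test_that("correcting a low-conductance curve raises fitted V_cmax", {
  truth <- fvcb_params(V_cmax = 100, J = 150, TPU = 9, R_d = 1.5)
  run <- make_clean_curve(truth, g_sw = 0.045)
  fu <- fit_aci(recompute_curve(run, 0.0056, "uncorrected"), fit_tpu = TRUE)
  fc <- fit_aci(recompute_curve(run, 0.0056, "corrected"), fit_tpu = TRUE)
  expect_gt(fc$coef["V_cmax"], fu$coef["V_cmax"])
  expect_gt(fc$coef["J_1200"], fu$coef["J_1200"])
})

test_that("delta CV follows its sign convention on published summaries", {
  # bell pepper corrected C_itrans1, citrus and magnolia corrected V_cmax
  expect_equal(round(delta_cv_from_summary(590.93, 13.20, 570.88, 57.83), 2),
               0.78)
  expect_equal(round(delta_cv_from_summary(115.11, 6.79, 111.67, 5.90), 2),
               -0.12)
  expect_equal(round(delta_cv_from_summary(145.64, 7.43, 220.00, 31.14), 2),
               0.64)
})

test_that("delta CV across fit replicates matches the summary route", {
  truth <- fvcb_params(V_cmax = 100, J = 150, R_d = 1.5)
  st <- stomatal_model(g_max = 0.3, g_min = 0.3, g_cw_true = 0.0056)
  make_fits <- function(protocol, seeds, sd_A) {
    lapply(seeds, function(s) {
      run <- generate_curve(protocol, params = truth, stomata = st,
                            noise = noise_spec(0.00415, sd_A), seed = s)
      fit_aci(recompute_curve(run, 0.0056, "corrected"))
    })
  }
  fr <- make_fits(protocol_racir(100, 900), 1:4, 0.2)
  fs <- make_fits(protocol_ss(), 5:8, 0.2)
  dv <- delta_cv(fr, fs, "V_cmax")
  vr <- vapply(fr, function(f) f$coef[["V_cmax"]], 0)
  vs <- vapply(fs, function(f) f$coef[["V_cmax"]], 0)
  # sd-based and SE-based routes agree when both arms share n
  expect_equal(dv, delta_cv_from_summary(mean(vr), sd(vr) / 2,
                                         mean(vs), sd(vs) / 2),
               tolerance = 1e-12)
  # identical arms give exactly zero
  expect_equal(delta_cv(fr, fr, "V_cmax"), 0)
  expect_error(delta_cv(fr[1], fs, "V_cmax"), "at least 2")
})
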