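test_that("protocol trajectories produce the documented record counts", {
  expect_equal(nrow(generate_curve(protocol_racir(100, 900),
                                   noise = noise_spec(0, 0))), 270)
  expect_equal(nrow(generate_curve(protocol_racir(100, 2000),
                                   noise = noise_spec(0, 0))), 600)
  ss <- generate_curve(protocol_ss(), noise = noise_spec(0, 0))
  expect_equal(nrow(ss), 16)
  expect_equal(ss$Ca[1], 380)  # starts at 380 then walks the progression
  rl <- generate_redlight_run(noise = noise_spec(0, 0))
  expect_equal(floor(rl$protocol$steady / rl$protocol$cadence), 42)
  expect_gte(nrow(rl$records), 42)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_curve(protocol_ss(), noise = noise_spec(), seed = 11)
  b <- generate_curve(protocol_ss(), noise = noise_spec(), seed = 11)
  expect_identical(a, b)
  c <- generate_curve(protocol_ss(), noise = noise_spec(), seed = 12)
  expect_false(identical(a$gsw, c$gsw))
  expect_error(generate_curve(protocol_ss(), noise = noise_spec()),
               "seed")
})

test_that("noise-free records are self-consistent with the ternary equation", {
  st <- stomatal_model(g_max = 0.15, g_min = 0.15, g_cw_true = 0)
  run <- generate_curve(protocol_racir(200, 900), stomata = st,
                        noise = noise_spec(0, 0))
  redo <- intercellular_co2(run$A, run$E, run$Ca,
                            total_conductance_co2(run$gsw), quiet = TRUE)
  expect_equal(run$Ci, redo, tolerance = 1e-9)
  # with zero g_cw the instrument C_i equals the model C_i
  expect_equal(run$Ci, attr(run, "truth")$C_i, tolerance = 1e-9)
})

test_that("with cuticular conductance the instrument C_i overestimates truth", {
  st <- stomatal_model(g_max = 0.05, g_min = 0.05, g_cw_true = 0.0056)
  run <- generate_curve(protocol_ss(), stomata = st, noise = noise_spec(0, 0))
  tr <- attr(run, "truth")
  pos <- run$A > 0.5
  expect_true(all(run$Ci[pos] > tr$C_i[pos]))
})

test_that("stomata close as ambient CO2 rises above 400 during a ramp", {
  st <- stomatal_model(g_max = 0.12, g_min = 0.03, sensitivity = 5e-4,
                       tau = 60)
  run <- generate_curve(protocol_racir(100, 2000), stomata = st,
                        noise = noise_spec(0, 0))
  g <- attr(run, "truth")$g_sw
  high <- run$Ca > 1000
  expect_lt(g[which.max(run$Ca)], max(g))
  expect_true(all(diff(g[high]) <= 1e-12))
})

test_that("empty-chamber runs report drift plus pure conductance noise", {
  e0 <- generate_empty_chamber(coef = 0, noise = noise_spec(0, 0))
  expect_true(all(e0$A == 0) && all(e0$gsw == 0))
  e1 <- generate_empty_chamber(coef = c(0.5, 0.001), noise = noise_spec(0, 0))
  expect_equal(e1$A[e1$CO2_r == 400][1], 0.9)
  # sampled conductance sd consistent with sd 0.00415 at n = 270
  en <- generate_empty_chamber(noise = noise_spec(0.00415, 0), seed = 5)
  expect_equal(nrow(en), 270)
  expect_gt(sd(en$gsw), 0.003)
  expect_lt(sd(en$gsw), 0.0055)
  expect_error(generate_empty_chamber(coef = rep(1, 7)), "degree")
})

test_that("LI-6800-style CSV round trips losslessly and validates its schema", {
  run <- generate_curve(protocol_ss(), noise = noise_spec(), seed = 3)
  run$vendor_tag <- paste0("obs", seq_len(nrow(run)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_li6800_csv(run, path)
  back <- read_li6800_csv(path)
  for (cn in c("elapsed", "A", "E", "gsw", "Ca", "Ci", "CO2_r"))
    expect_equal(back[[cn]], run[[cn]], tolerance = 1e-12)
  expect_equal(back$vendor_tag, run$vendor_tag)

  # a glw column is accepted as the conductance synonym
  names(run)[names(run) == "gsw"] <- "glw"
  write_li6800_csv(run, path)
  expect_true("gsw" %in% names(read_li6800_csv(path)))

  # missing mandatory column is named in the error
  broken <- run
  broken$A <- NULL
  write_li6800_csv(broken, path)
  expect_error(read_li6800_csv(path), "A")
})

test_that("species presets reproduce the measured conductance levels at 400 ppm", {
  for (sp in list(c("magnolia", 0.09, 0.0053), c("citrus", 0.12, 0.0045),
                  c("pepper", 0.33, 0.0076), c("papaya", 0.17, 0.0056))) {
    st <- species_preset(sp[[1]])
    g_target <- st$g_min + (st$g_max - st$g_min)  # target at C_a = 400
    expect_equal(g_target + st$g_cw_true, as.numeric(sp[[2]]),
                 tolerance = 1e-12)
    expect_equal(st$g_cw_true, as.numeric(sp[[3]]))
  }
})
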