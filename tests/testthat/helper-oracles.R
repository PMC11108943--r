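# Independent oracles and shared fixtures. The grid-search oracle inlines
# all arithmetic so it shares no code path with coupled_solve().

# exhaustive search for the C_i fixed point on an equally spaced grid
oracle_ci_grid <- function(g_tc, E, C_a, V_cmax = 50, J = 100, R_d = 1.5,
                           Gamma_star = 42.75, K_c = 404.9, K_o = 278.4,
                           O = 210, TPU = Inf, step = 0.001) {
  ci <- seq(step, C_a, by = step)
  Km <- K_c * (1 + O / K_o)
  Ac <- V_cmax * (ci - Gamma_star) / (ci + Km)
  Aj <- J * (ci - Gamma_star) / (4 * ci + 8 * Gamma_star)
  A <- pmin(Ac, Aj, 3 * TPU) - R_d
  lhs <- ((g_tc - E / 2) * C_a - A) / (g_tc + E / 2)
  ci[which.min(abs(lhs - ci))]
}

# uncorrected-pathway g_tc, inlined (K = 0 form)
oracle_gtc_uncorr <- function(g_lw, g_bw = 2.23) {
  1 / (1.6 / g_lw + 1.37 / g_bw)
}

# corrected-pathway g_tc, inlined
oracle_gtc_corr <- function(g_lw, g_cw, g_bw = 2.23) {
  glc <- (g_lw - g_cw) / 1.6 + g_cw / 20
  1 / (1 / glc + 1.37 / g_bw)
}

# a clean steady-state curve from known parameters, static stomata
make_clean_curve <- function(params, g_sw = 0.3, g_cw = 0.0056,
                             protocol = protocol_ss()) {
  st <- stomatal_model(g_max = g_sw, g_min = g_sw, g_cw_true = g_cw)
  generate_curve(protocol, params = params, stomata = st,
                 noise = noise_spec(0, 0))
}
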