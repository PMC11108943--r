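# Farquhar-von Caemmerer-Berry forward model and the coupled
# photosynthesis/diffusion solver.

#' FvCB photosynthesis model parameters
#'
#' Container for the parameters of the C3 photosynthesis model. Kinetic
#' constants default to standard 25 degree C values (`Gamma_star` = 42.75
#' umol mol-1, `K_c` = 404.9 umol mol-1, `K_o` = 278.4 mmol mol-1, `O` = 210
#' mmol mol-1); `V_cmax` and `J` default to the values used throughout the
#' modelling analyses (50 and 100 umol m-2 s-1). `J` is interpreted as the
#' electron transport rate at the operating irradiance (here 1200
#' umol m-2 s-1, hence "J_1200"); no light-response extrapolation is applied.
#' `TPU = NULL` means the triose-phosphate-utilization limitation is absent
#' (never binding). No temperature corrections are applied anywhere.
#'
#' @param V_cmax Maximum carboxylation rate (umol m-2 s-1), > 0.
#' @param J Electron transport rate at operating light (umol m-2 s-1), > 0.
#' @param TPU Triose phosphate utilization rate (umol m-2 s-1), > 0 or `NULL`
#'   for absent.
#' @param R_d Day respiration (umol m-2 s-1), >= 0.
#' @param Gamma_star CO2 photo-compensation point (umol mol-1), > 0.
#' @param K_c Michaelis constant for CO2 (umol mol-1), > 0.
#' @param K_o Michaelis constant for O2 (mmol mol-1), > 0.
#' @param O Oxygen mole fraction (mmol mol-1), > 0.
#' @return A list of class `"fvcb_params"`.
#' @examples
#' p <- fvcb_params()
#' michaelis_co2(p)  # effective K_m = K_c (1 + O/K_o) ~ 710.3
#' @export
fvcb_params <- function(V_cmax = 50, J = 100, TPU = NULL, R_d = 1.5,
                        Gamma_star = 42.75, K_c = 404.9, K_o = 278.4,
                        O = 210) {
  if (V_cmax <= 0 || J <= 0 || Gamma_star <= 0 || K_c <= 0 || K_o <= 0 ||
      O <= 0)
    stop("V_cmax, J, Gamma_star, K_c, K_o and O must all be positive")
  if (!is.null(TPU) && (length(TPU) != 1 || is.na(TPU) || TPU <= 0))
    stop("`TPU` must be a positive scalar or NULL (absent)")
  if (R_d < 0) stop("`R_d` must be >= 0")
  p <- list(V_cmax = V_cmax, J = J, TPU = TPU, R_d = R_d,
            Gamma_star = Gamma_star, K_c = K_c, K_o = K_o, O = O)
  if (michaelis_co2(p) <= Gamma_star)
    stop("effective Michaelis term K_m must exceed Gamma_star")
  structure(p, class = "fvcb_params")
}

#' Effective Michaelis-Menten term for CO2
#'
#' `K_m = K_c (1 + O / K_o)`, the CO2 Michaelis constant in the presence of
#' competing oxygenation.
#'
#' @param params An [fvcb_params()] object.
#' @return `K_m` in umol mol-1.
#' @export
michaelis_co2 <- function(params) {
  params$K_c * (1 + params$O / params$K_o)
}

#' Rubisco-limited gross carboxylation rate
#'
#' `A_c = V_cmax (C_i - Gamma_star) / (C_i + K_m)`; negative below the
#' compensation point, asymptoting to `V_cmax` at high CO2.
#'
#' @param C_i Intercellular CO2 (umol mol-1), >= 0. Vectorised.
#' @param params An [fvcb_params()] object.
#' @return Gross rate (umol m-2 s-1).
#' @export
rubisco_limited_rate <- function(C_i, params) {
  params$V_cmax * (C_i - params$Gamma_star) / (C_i + michaelis_co2(params))
}

#' RuBP-regeneration-limited gross rate
#'
#' `A_j = J (C_i - Gamma_star) / (4 C_i + 8 Gamma_star)`, asymptoting to
#' `J/4`.
#'
#' @inheritParams rubisco_limited_rate
#' @return Gross rate (umol m-2 s-1).
#' @export
rubp_limited_rate <- function(C_i, params) {
  params$J * (C_i - params$Gamma_star) / (4 * C_i + 8 * params$Gamma_star)
}

#' TPU-limited gross rate
#'
#' Constant `3 TPU`, independent of `C_i`; `Inf` (never binding) when TPU is
#' absent.
#'
#' @param params An [fvcb_params()] object.
#' @return Gross rate (umol m-2 s-1), possibly `Inf`.
#' @export
tpu_limited_rate <- function(params) {
  if (is.null(params$TPU)) Inf else 3 * params$TPU
}

#' Net assimilation under the FvCB model
#'
#' Net rate `A = min(A_c, A_j, A_p) - R_d`, a hard minimum of the limiting
#' processes (no hyperbolic smoothing: limitation transitions are exact
#' intersections). `rates = "rubp"` restricts the model to the
#' RuBP-regeneration-limited rate, the operative limitation under strictly
#' light-limited conditions such as low red light.
#'
#' @inheritParams rubisco_limited_rate
#' @param rates `"all"` (minimum of the three limitations) or `"rubp"`.
#' @return Net assimilation (umol m-2 s-1). Vectorised over `C_i`.
#' @seealso [limiting_rate()] for which process binds.
#' @export
net_assimilation <- function(C_i, params, rates = c("all", "rubp")) {
  rates <- match.arg(rates)
  gross <- if (rates == "rubp") {
    rubp_limited_rate(C_i, params)
  } else {
    pmin(rubisco_limited_rate(C_i, params),
         rubp_limited_rate(C_i, params),
         tpu_limited_rate(params))
  }
  gross - params$R_d
}

#' Which FvCB process limits at a given C_i
#'
#' @inheritParams rubisco_limited_rate
#' @return Character vector: `"Rubisco"`, `"RuBP"` or `"TPU"`.
#' @export
limiting_rate <- function(C_i, params) {
  m <- cbind(Rubisco = rubisco_limited_rate(C_i, params),
             RuBP = rubp_limited_rate(C_i, params),
             TPU = rep(tpu_limited_rate(params), length(C_i)))
  colnames(m)[max.col(-m, ties.method = "first")]
}

#' Limitation-transition C_i values
#'
#' Closed-form intersections of the limiting rates:
#' * first (Rubisco to RuBP):
#'   `(J K_m - 8 Gamma_star V_cmax) / (4 V_cmax - J)` when `4 V_cmax > J`,
#'   else absent (the RuBP curve never overtakes Rubisco);
#' * second (RuBP to TPU):
#'   `Gamma_star (J + 24 TPU) / (J - 12 TPU)` when TPU is present and
#'   `J > 12 TPU`, else absent.
#'
#' Absence is a normal outcome (returned as `NA`), mirroring curves whose
#' data never reach the corresponding limitation.
#'
#' @param params An [fvcb_params()] object.
#' @param which `"first"` or `"second"`.
#' @return The transition `C_i` (umol mol-1) or `NA`.
#' @examples
#' transition_ci(fvcb_params(V_cmax = 50, J = 100))             # 539.3
#' transition_ci(fvcb_params(J = 100, TPU = 7), "second")       # 716.06
#' @export
transition_ci <- function(params, which = c("first", "second")) {
  which <- match.arg(which)
  if (which == "first") {
    if (4 * params$V_cmax <= params$J) return(NA_real_)
    (params$J * michaelis_co2(params) -
       8 * params$Gamma_star * params$V_cmax) /
      (4 * params$V_cmax - params$J)
  } else {
    if (is.null(params$TPU) || params$J <= 12 * params$TPU) return(NA_real_)
    params$Gamma_star * (params$J + 24 * params$TPU) /
      (params$J - 12 * params$TPU)
  }
}

#' Solve the coupled photosynthesis/diffusion system
#'
#' Finds the (`A`, `C_i`) pair simultaneously satisfying the FvCB net
#' assimilation model and the ternary `C_i` equation for a leaf of prescribed
#' conductance, by bracketed root search on `C_i` over
#' `(Gamma_star/1000, C_a]` (the bracket extends above `C_a` when
#' respiration makes the leaf a net CO2 source, e.g. at ambient CO2 near
#' the compensation point).
#'
#' In `"uncorrected"` mode the whole leaf conductance is treated as stomatal
#' (`g_sw := g_lw`) and `g_tc` follows the standard series combination with
#' the boundary layer. In `"corrected"` mode the cuticular component is
#' removed from the stomatal pathway (`g_sw = g_lw - g_cw`), the leaf CO2
#' conductance is rebuilt as `g_sw/1.6 + g_cw/20`, and a pseudo-`g_lw`
#' (1.6 times the corrected CO2 conductance) is passed through the same
#' series combination. Transpiration is `E = g_lw * VPD / P_atm` in both
#' modes (the water-side flux is unaffected by how its pathways are
#' partitioned).
#'
#' @param g_lw Leaf conductance to water (mol m-2 s-1), > 0.
#' @param g_cw Cuticular conductance to water (mol m-2 s-1), >= 0; must be
#'   `< g_lw` in corrected mode.
#' @param chamber A [chamber_state()].
#' @param params An [fvcb_params()] object.
#' @param mode `"uncorrected"` or `"corrected"`.
#' @param rates Passed to [net_assimilation()]: `"all"` or `"rubp"`.
#' @param tol Root tolerance on `C_i`.
#' @return A list of class `"coupled_solution"`: `A`, `C_i`, `E`, `g_tc`,
#'   `g_sw` (as used), `limitation`, `residual` (closure error of the fixed
#'   point, umol mol-1) and `mode`.
#' @examples
#' coupled_solve(0.056, 0.0056, chamber_state(C_a = 400),
#'               fvcb_params(R_d = 0))$C_i   # ~ 178 (uncorrected)
#' @export
coupled_solve <- function(g_lw, g_cw = 0, chamber = chamber_state(),
                          params = fvcb_params(),
                          mode = c("uncorrected", "corrected"),
                          rates = c("all", "rubp"), tol = 1e-12) {
  mode <- match.arg(mode)
  rates <- match.arg(rates)
  if (g_lw <= 0) stop("`g_lw` must be positive")
  if (g_cw < 0) stop("`g_cw` must be >= 0")
  E <- g_lw * chamber$VPD / chamber$P_atm
  if (mode == "uncorrected") {
    g_sw_used <- g_lw
    g_tc <- total_conductance_co2(g_lw, chamber$g_bw, chamber$K)
  } else {
    if (g_cw >= g_lw)
      stop("non-physical: g_cw >= g_lw in corrected mode")
    g_sw_used <- g_lw - g_cw
    g_lc <- leaf_conductance_co2(g_sw_used, g_cw)
    g_tc <- total_conductance_co2(pseudo_glw(g_lc), chamber$g_bw, chamber$K)
  }
  f <- function(ci) {
    intercellular_co2(net_assimilation(ci, params, rates), E, chamber$C_a,
                      g_tc, quiet = TRUE) - ci
  }
  lo <- params$Gamma_star * 1e-3
  hi <- chamber$C_a
  flo <- f(lo)
  fhi <- f(hi)
  # when the leaf is a net CO2 source (A < 0 at C_a) the solution lies above
  # C_a; expand the bracket upward until the residual changes sign
  while (is.finite(fhi) && flo > 0 && fhi > 0 &&
         hi < 10 * chamber$C_a + 5000) {
    hi <- hi * 1.5 + 100
    fhi <- f(hi)
  }
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop(sprintf(paste0("coupled solver: no sign change on [%.4g, %.4g] ",
                        "(f(lo) = %.4g, f(hi) = %.4g; g_tc = %.4g, E = %.4g)"),
                 lo, hi, flo, fhi, g_tc, E))
  root <- uniroot(f, c(lo, hi), tol = tol)
  C_i <- root$root
  structure(list(A = net_assimilation(C_i, params, rates),
                 C_i = C_i, E = E, g_tc = g_tc, g_sw = g_sw_used,
                 limitation = if (rates == "rubp") "RuBP"
                              else limiting_rate(C_i, params),
                 residual = f(C_i), mode = mode),
            class = "coupled_solution")
}

#' @export
print.coupled_solution <- function(x, ...) {
  cat(sprintf("Coupled FvCB/diffusion solution (%s pathway)\n", x$mode))
  cat(sprintf("  A   = %.4f umol m-2 s-1 (%s-limited)\n", x$A, x$limitation))
  cat(sprintf("  C_i = %.3f umol mol-1\n", x$C_i))
  cat(sprintf("  E   = %.6f mol m-2 s-1, g_tc = %.6f mol m-2 s-1\n",
              x$E, x$g_tc))
  cat(sprintf("  residual = %.2e\n", x$residual))
  invisible(x)
}
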