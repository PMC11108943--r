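# Conductance calculus: series/parallel combinations of stomatal, cuticular
# and boundary-layer conductances, and the ternary-corrected C_i calculation.
# Units follow instrument conventions throughout: conductances and E in
# mol m-2 s-1, A in umol m-2 s-1, CO2 mole fractions in umol mol-1.

#' Total conductance to CO2 of leaf plus boundary layer
#'
#' Combines stomatal and boundary-layer conductances into the total
#' conductance to CO2,
#' \deqn{g_{tc} = \frac{1}{(K+1)\frac{1.6}{g_{sw}} + \frac{1.37}{g_{bw}}} +
#'       \frac{K}{(K+1)\frac{1.6}{g_{sw}} + K\frac{1.37}{g_{bw}}}}
#' where 1.6 and 1.37 are the H2O:CO2 diffusivity ratios in stomata and in the
#' boundary layer, and `K` is the adaxial:abaxial stomatal resistance ratio.
#' With `K = 0` (hypostomatous leaf, the common case for low-conductance
#' species) the second term vanishes, and as `g_bw` grows the result tends to
#' `g_sw / 1.6`.
#'
#' @param g_sw Stomatal conductance to water vapour (mol m-2 s-1), > 0.
#' @param g_bw Boundary-layer conductance to water vapour (mol m-2 s-1), > 0.
#'   Default 2.23, typical of a well-stirred small chamber.
#' @param K Adaxial:abaxial stomatal resistance ratio (dimensionless, >= 0).
#' @return Total conductance to CO2 (mol m-2 s-1).
#' @examples
#' total_conductance_co2(0.16, 2.23, 0)     # 0.094212
#' total_conductance_co2(0.16, 1e9, 0)      # ~ 0.1 = g_sw / 1.6
#' @export
total_conductance_co2 <- function(g_sw, g_bw = 2.23, K = 0) {
  if (any(!is.finite(g_sw)) || any(g_sw <= 0))
    stop("`g_sw` must be finite and positive")
  if (any(g_bw <= 0)) stop("`g_bw` must be positive")
  if (any(K < 0)) stop("`K` must be >= 0")
  term1 <- 1 / ((K + 1) * 1.6 / g_sw + 1.37 / g_bw)
  # when K = 0 the second term's numerator vanishes
  term2 <- ifelse(K == 0, 0, K / ((K + 1) * 1.6 / g_sw + K * 1.37 / g_bw))
  term1 + term2
}

#' Stomatal conductance corrected for the cuticular component
#'
#' The measured leaf conductance to water is the sum of stomatal and
#' cuticular pathways, so the stomatal component is `g_sw = g_lw - g_cw`.
#'
#' @param g_lw Leaf conductance to water (mol m-2 s-1), > 0.
#' @param g_cw Cuticular conductance to water (mol m-2 s-1), >= 0.
#' @param on_nonphysical What to do when `g_cw >= g_lw` (stomatal conductance
#'   would be <= 0): `"error"` (default) or `"na"` to return `NA` for the
#'   offending elements with a warning.
#' @return Stomatal conductance to water (mol m-2 s-1).
#' @examples
#' correct_stomatal_conductance(0.17, 0.0056)  # 0.1644
#' @export
correct_stomatal_conductance <- function(g_lw, g_cw,
                                         on_nonphysical = c("error", "na")) {
  on_nonphysical <- match.arg(on_nonphysical)
  if (any(g_lw <= 0)) stop("`g_lw` must be positive")
  if (any(g_cw < 0)) stop("`g_cw` must be >= 0")
  bad <- g_cw >= g_lw
  if (any(bad)) {
    if (on_nonphysical == "error")
      stop("non-physical conductance: g_cw >= g_lw (stomatal conductance would be <= 0)")
    warning(sum(bad), " record(s) with g_cw >= g_lw set to NA")
  }
  out <- g_lw - g_cw
  out[bad] <- NA_real_
  out
}

#' Leaf conductance to CO2 with distinct stomatal and cuticular ratios
#'
#' `g_lc = g_sw / 1.6 + g_cw / 20`. The cuticle is a far stronger barrier to
#' CO2 than to water (ratio taken as 1:20), which is why cuticular transport
#' inflates apparent CO2 conductance when lumped into `g_sw`.
#'
#' @param g_sw Stomatal conductance to water (mol m-2 s-1), >= 0.
#' @param g_cw Cuticular conductance to water (mol m-2 s-1), >= 0.
#' @return Leaf conductance to CO2 (mol m-2 s-1).
#' @examples
#' leaf_conductance_co2(0.1644, 0.0056)  # 0.10303
#' @export
leaf_conductance_co2 <- function(g_sw, g_cw) {
  if (any(g_sw < 0) || any(g_cw < 0))
    stop("conductances must be >= 0")
  g_sw / 1.6 + g_cw / 20
}

#' Pseudo leaf conductance to water from a corrected CO2 conductance
#'
#' Downstream components (including the standard instrument firmware and
#' common fitting code) assume `g_tc = g_lw / 1.6`. To feed them a corrected
#' CO2 conductance, multiply it by 1.6 to obtain the pseudo-`g_lw` that those
#' components will convert back to the desired `g_tc`.
#'
#' @param g_tc_corrected Corrected conductance to CO2 (mol m-2 s-1), >= 0.
#' @return Pseudo leaf conductance to water (mol m-2 s-1).
#' @export
pseudo_glw <- function(g_tc_corrected) {
  if (any(g_tc_corrected < 0)) stop("`g_tc_corrected` must be >= 0")
  1.6 * g_tc_corrected
}

#' Intercellular CO2 concentration with the ternary correction
#'
#' The standard gas-exchange calculation
#' \deqn{C_i = \frac{(g_{tc} - E/2)\,C_a - A}{g_{tc} + E/2}}
#' including the `E/2` ternary terms for the mass flow of transpired water.
#' With `E = 0` it reduces to `C_a - A / g_tc`. Negative results (which arise
#' at very low conductance, where the calculation becomes unreliable) are
#' returned as-is with a warning rather than clamped.
#'
#' @param A Net CO2 assimilation (umol m-2 s-1).
#' @param E Transpiration (mol m-2 s-1).
#' @param C_a Ambient (sample) CO2 mole fraction (umol mol-1).
#' @param g_tc Total conductance to CO2 (mol m-2 s-1).
#' @param quiet Suppress the negative-`C_i` warning (used internally by
#'   solvers that probe the full bracket).
#' @return Intercellular CO2 mole fraction (umol mol-1).
#' @examples
#' intercellular_co2(10, 0, 400, 0.1)       # 300
#' intercellular_co2(10, 0.002, 400, 0.1)   # 293.0693
#' @export
intercellular_co2 <- function(A, E, C_a, g_tc, quiet = FALSE) {
  denom <- g_tc + E / 2
  if (any(denom <= 0))
    stop("`g_tc + E/2` must be positive")
  ci <- ((g_tc - E / 2) * C_a - A) / denom
  if (!quiet && any(ci < 0))
    warning("computed C_i < 0: unreliable low-conductance regime, value returned unclamped")
  ci
}

#' Proportional misestimation of intercellular CO2
#'
#' `(C_i_uncorr - C_i_cor) / C_i_cor`: the relative error committed by the
#' uncorrected calculation, expected positive because lumping cuticular into
#' stomatal conductance overestimates `C_i`.
#'
#' @param C_i_uncorr Uncorrected intercellular CO2 (umol mol-1).
#' @param C_i_cor Cuticular-conductance-corrected intercellular CO2
#'   (umol mol-1), > 0.
#' @return Proportional misestimation (dimensionless, sign preserved).
#' @examples
#' ci_misestimation(300, 285)  # 0.0526
#' @export
ci_misestimation <- function(C_i_uncorr, C_i_cor) {
  if (any(C_i_cor <= 0)) stop("`C_i_cor` must be positive")
  (C_i_uncorr - C_i_cor) / C_i_cor
}

#' Chamber state for forward modelling
#'
#' Bundles the environmental drivers used by [coupled_solve()] and the sweep
#' functions. Transpiration inside the forward model is computed as
#' `E = g_lw * VPD / P_atm`.
#'
#' @param C_a Ambient CO2 mole fraction (umol mol-1).
#' @param VPD Leaf-to-air vapour pressure deficit (kPa).
#' @param P_atm Atmospheric pressure (kPa).
#' @param T_leaf Leaf temperature (degrees C); carried as metadata, no
#'   temperature response is applied.
#' @param g_bw Boundary-layer conductance to water (mol m-2 s-1).
#' @param K Adaxial:abaxial stomatal resistance ratio.
#' @return A list of class `"chamber_state"`.
#' @export
chamber_state <- function(C_a = 400, VPD = 1.5, P_atm = 101.325,
                          T_leaf = 25, g_bw = 2.23, K = 0) {
  if (C_a <= 0) stop("`C_a` must be positive")
  if (P_atm <= 0) stop("`P_atm` must be positive")
  if (VPD < 0) stop("`VPD` must be >= 0")
  structure(list(C_a = C_a, VPD = VPD, P_atm = P_atm, T_leaf = T_leaf,
                 g_bw = g_bw, K = K),
            class = "chamber_state")
}
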