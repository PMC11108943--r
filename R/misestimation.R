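# Sweeps of corrected vs uncorrected C_i over leaf conductance, the
# g_cw:g_lw ratio framing, instrument-noise envelopes and the combined-error
# curve.

solve_ci_quiet <- function(g_lw, g_cw, chamber, params, mode, rates = "all") {
  tryCatch(coupled_solve(g_lw, g_cw, chamber, params, mode, rates)$C_i,
           error = function(e) NA_real_)
}

#' Sweep leaf conductance and compare corrected vs uncorrected C_i
#'
#' For each leaf conductance on the grid and each ambient CO2 scenario, runs
#' the coupled solver through both the uncorrected (`g_sw := g_lw`) and the
#' cuticular-corrected pathway and records the proportional misestimation of
#' `C_i`. Defaults reproduce the modelling conditions: `g_lw` from 0.001 to
#' 1 mol m-2 s-1 in 0.001 steps, `g_cw = 0.0056` mol m-2 s-1 (papaya, the
#' mid-range species), `C_a` scenarios of 100, 400 and 2000 umol mol-1, VPD
#' 1.5 kPa, `V_cmax` 50 and `J` 100 umol m-2 s-1 at 25 degrees C.
#'
#' Grid points with `g_lw <= g_cw` (corrected pathway non-physical) and
#' solver failures are flagged, not dropped.
#'
#' @param g_lw Strictly increasing, positive grid of leaf conductances.
#' @param g_cw Cuticular conductance to water (mol m-2 s-1).
#' @param C_a One or more ambient CO2 scenarios (umol mol-1).
#' @param params An [fvcb_params()] object.
#' @param chamber A [chamber_state()]; its `C_a` is overridden per scenario.
#' @return A data frame of class `"misestimation_profile"` with columns
#'   `g_lw`, `ratio` (= `g_cw/g_lw`), `C_a`, `C_i_uncorr`, `C_i_cor`,
#'   `C_i_mis` and `flag` (`"ok"`, `"nonphysical"`, `"solver_error"`), rows
#'   ordered by `g_lw` within `C_a`.
#' @examples
#' prof <- sweep_glw(g_lw = seq(0.01, 0.2, by = 0.01), C_a = 400)
#' threshold_ratio(prof)
#' @export
sweep_glw <- function(g_lw = seq(0.001, 1, by = 0.001), g_cw = 0.0056,
                      C_a = c(100, 400, 2000), params = fvcb_params(),
                      chamber = chamber_state()) {
  if (any(g_lw <= 0) || is.unsorted(g_lw, strictly = TRUE))
    stop("`g_lw` must be a strictly increasing positive grid")
  if (g_cw < 0) stop("`g_cw` must be >= 0")
  out <- lapply(C_a, function(ca) {
    ch <- chamber
    ch$C_a <- ca
    unc <- vapply(g_lw, solve_ci_quiet, 0, g_cw = g_cw, chamber = ch,
                  params = params, mode = "uncorrected")
    cor <- vapply(g_lw, function(g) {
      if (g <= g_cw) return(NA_real_)
      solve_ci_quiet(g, g_cw, ch, params, "corrected")
    }, 0)
    flag <- ifelse(g_lw <= g_cw, "nonphysical",
                   ifelse(is.na(unc) | is.na(cor), "solver_error", "ok"))
    mis <- ifelse(flag == "ok", (unc - cor) / cor, NA_real_)
    data.frame(g_lw = g_lw, ratio = g_cw / g_lw, C_a = ca,
               C_i_uncorr = unc, C_i_cor = cor, C_i_mis = mis,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, g_cw = g_cw, params = params, VPD = chamber$VPD,
            class = c("misestimation_profile", "data.frame"))
}

#' g_cw:g_lw ratio at which an error measure crosses a threshold
#'
#' Scans a profile from low to high `g_cw:g_lw` ratio (i.e. from high to low
#' `g_lw`) and returns the ratio at which the chosen error column first rises
#' above `threshold`, linearly interpolated between the bracketing grid rows.
#' `NA` if the threshold is never crossed. When the profile covers several
#' ambient CO2 scenarios a named value per scenario is returned.
#'
#' @param profile A data frame with columns `ratio`, `C_a` and the error
#'   column (a [sweep_glw()] or noise-sweep result).
#' @param threshold Crossing level (default 0.05, i.e. 5% error).
#' @param column Name of the error column (default `"C_i_mis"`).
#' @return Ratio(s) at the crossing, named by `C_a` when several scenarios
#'   are present.
#' @export
threshold_ratio <- function(profile, threshold = 0.05, column = "C_i_mis") {
  if (!column %in% names(profile)) stop("no column `", column, "` in profile")
  one <- function(d) {
    d <- d[order(d$ratio), ]
    v <- d[[column]]
    keep <- is.finite(v)
    v <- v[keep]
    r <- d$ratio[keep]
    if (!length(v)) return(NA_real_)
    above <- which(v > threshold)
    if (!length(above)) return(NA_real_)
    i <- above[1]
    if (i == 1) return(r[1])   # crossing immediate at the start of the grid
    if (any(diff(v[seq_len(i)]) < 0))
      warning("error measure is non-monotone below the crossing; first crossing reported")
    # linear interpolation between the bracketing rows
    r[i - 1] + (threshold - v[i - 1]) * (r[i] - r[i - 1]) / (v[i] - v[i - 1])
  }
  cas <- unique(profile$C_a)
  res <- vapply(cas, function(ca) one(profile[profile$C_a == ca, ]), 0)
  if (length(res) == 1) res else setNames(res, cas)
}

#' C_i envelope under a +/- 1 sd perturbation of measured conductance
#'
#' Empty-chamber runs put the standard deviation of instrument noise in
#' `g_lw` at 0.00415 mol m-2 s-1. Treating the true conductance as possibly
#' one standard deviation away from the measured value, this evaluates the
#' coupled solver at `g_lw - sd`, `g_lw` and `g_lw + sd` and reports the
#' worst-case proportional deviation of `C_i` from the unperturbed value.
#' The envelope is deterministic (a +/- 1 sd band), not Monte-Carlo.
#'
#' A lower perturbation that is non-physical (`g_lw - sd <= g_cw` in
#' corrected mode, or `<= 0`) yields a one-sided band with a flag.
#'
#' @param g_lw Leaf conductance grid (vectorised).
#' @param g_cw Cuticular conductance to water (mol m-2 s-1).
#' @param sd_glw Instrument noise standard deviation of `g_lw`
#'   (mol m-2 s-1), default 0.00415.
#' @param chamber A [chamber_state()].
#' @param params An [fvcb_params()] object.
#' @param mode Conductance pathway for all three evaluations.
#' @return Data frame with `g_lw`, `ratio`, `C_i_low`, `C_i_mid`, `C_i_high`,
#'   `prop_error` and `flag` (`"ok"` or `"one_sided"`).
#' @export
noise_band <- function(g_lw, g_cw = 0.0056, sd_glw = 0.00415,
                       chamber = chamber_state(), params = fvcb_params(),
                       mode = c("corrected", "uncorrected")) {
  mode <- match.arg(mode)
  if (sd_glw < 0) stop("`sd_glw` must be >= 0")
  g_floor <- if (mode == "corrected") g_cw else 0
  rows <- lapply(g_lw, function(g) {
    if (g <= g_floor)
      return(data.frame(g_lw = g, ratio = g_cw / g, C_i_low = NA_real_,
                        C_i_mid = NA_real_, C_i_high = NA_real_,
                        prop_error = NA_real_, flag = "nonphysical"))
    mid <- solve_ci_quiet(g, g_cw, chamber, params, mode)
    hi <- solve_ci_quiet(g + sd_glw, g_cw, chamber, params, mode)
    lo_ok <- (g - sd_glw) > g_floor
    lo <- if (lo_ok) solve_ci_quiet(g - sd_glw, g_cw, chamber, params, mode)
          else NA_real_
    dev <- max(abs(c(lo, hi) - mid), na.rm = TRUE)
    data.frame(g_lw = g, ratio = g_cw / g, C_i_low = lo, C_i_mid = mid,
               C_i_high = hi, prop_error = dev / mid,
               flag = if (lo_ok) "ok" else "one_sided",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$C_a <- chamber$C_a
  rownames(out) <- NULL
  out
}

#' Maximum combined error from conductance noise and ignoring g_cw
#'
#' The worst-case proportional deviation of the uncorrected `C_i`, evaluated
#' anywhere in the +/- 1 sd conductance-noise band, from the corrected `C_i`
#' at the measured conductance. By construction it dominates both the
#' correction-only error (recovered at `sd_glw = 0`) and the noise-only error
#' (recovered at `g_cw = 0`).
#'
#' @inheritParams noise_band
#' @return Numeric vector of combined proportional errors, aligned with
#'   `g_lw` (`NA` where the corrected reference is non-physical).
#' @export
combined_max_error <- function(g_lw, g_cw = 0.0056, sd_glw = 0.00415,
                               chamber = chamber_state(),
                               params = fvcb_params()) {
  vapply(g_lw, function(g) {
    if (g <= g_cw && g_cw > 0) return(NA_real_)
    ref <- if (g_cw > 0) solve_ci_quiet(g, g_cw, chamber, params, "corrected")
           else solve_ci_quiet(g, 0, chamber, params, "uncorrected")
    if (!is.finite(ref)) return(NA_real_)
    pert <- c(g - sd_glw, g, g + sd_glw)
    pert <- pert[pert > 0]
    unc <- vapply(pert, solve_ci_quiet, 0, g_cw = g_cw, chamber = chamber,
                  params = params, mode = "uncorrected")
    max(abs(unc - ref), na.rm = TRUE) / ref
  }, 0)
}
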