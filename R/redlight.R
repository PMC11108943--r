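# Red-light cuticular-conductance estimation: infer C_i from
# electron-transport kinetics under low red light, then split the water- and
# CO2-side conductances into stomatal and cuticular parts.

#' Electron transport rate and photo-compensation point from a companion curve
#'
#' Fits the RuBP-regeneration-limited model
#' `A = J (Ci - Gamma_star) / (4 Ci + 8 Gamma_star) - R_d` to a low-light
#' companion A/Ci curve with `R_d` fixed at the separately measured dark
#' respiration, returning the operating electron transport rate `J_a` and
#' `Gamma_star`. The curve must reach low enough `Ci` to pin down the
#' compensation point.
#'
#' @param curve A data frame with `Ci` and `A` (an `aci_curve` works; rows
#'   flagged non-`"ok"` are excluded).
#' @param R_d Dark respiration (umol m-2 s-1), held fixed.
#' @return Named vector `c(J_a, Gamma_star)`.
#' @export
estimate_j_gammastar <- function(curve, R_d) {
  df <- as.data.frame(curve)
  if (!is.null(df$flag)) df <- df[df$flag == "ok", , drop = FALSE]
  df <- df[is.finite(df$Ci) & is.finite(df$A), , drop = FALSE]
  if (nrow(df) < 5) stop("need at least 5 points")
  if (min(df$Ci) > 300)
    stop("companion curve never approaches the compensation point; ",
         "Gamma_star is not identifiable")
  start <- list(J = max(4 * (max(df$A) + R_d), 10), G = 45)
  # scaleOffset keeps the convergence test meaningful on (near-)exact data
  fit <- nls(A ~ J * (Ci - G) / (4 * Ci + 8 * G) - R_d, data = df,
             start = start,
             control = stats::nls.control(maxiter = 200, scaleOffset = 1))
  cf <- coef(fit)
  c(J_a = unname(cf["J"]), Gamma_star = unname(cf["G"]))
}

#' Invert the RuBP-limited rate for C_i under red light
#'
#' With gross assimilation `G = A + R_d` known to follow the
#' RuBP-regeneration-limited rate, the intercellular CO2 is
#' `C_i = Gamma_star (J_a + 8 G) / (J_a - 4 G)`. The inversion is singular
#' as `G` approaches `J_a / 4` (the light-saturated plateau).
#'
#' @param A Net assimilation (umol m-2 s-1). Vectorised.
#' @param R_d Dark respiration (umol m-2 s-1).
#' @param J_a Operating electron transport rate (umol m-2 s-1).
#' @param Gamma_star Photo-compensation point (umol mol-1).
#' @param tol Tolerance below `-R_d` before declaring a data-quality error.
#' @return `C_i` (umol mol-1).
#' @examples
#' invert_ci_redlight(A = 4, R_d = 1, J_a = 60, Gamma_star = 40)  # 100
#' @export
invert_ci_redlight <- function(A, R_d, J_a, Gamma_star, tol = 1e-6) {
  G <- A + R_d
  if (any(G < -tol))
    stop("gross assimilation below zero beyond tolerance: data-quality error")
  if (any(G >= J_a / 4))
    stop("G >= J_a/4: C_i inversion is singular at the electron-transport plateau")
  Gamma_star * (J_a + 8 * G) / (J_a - 4 * G)
}

#' Leaf CO2 conductance from measured fluxes and known C_i
#'
#' Inverts the ternary `C_i` equation for the conductance:
#' `g = (A + (E/2)(C_a + C_i)) / (C_a - C_i)`. The boundary layer is treated
#' as non-limiting, so the result is taken as the leaf conductance to CO2;
#' [estimate_gcw()] offers an exact series-resistor removal when `g_bw` is
#' supplied.
#'
#' @param A Net assimilation (umol m-2 s-1).
#' @param E Transpiration (mol m-2 s-1).
#' @param C_a Ambient CO2 (umol mol-1).
#' @param C_i Intercellular CO2 (umol mol-1), < `C_a`.
#' @return Leaf conductance to CO2 (mol m-2 s-1).
#' @examples
#' leaf_co2_conductance_from_fluxes(2, 0.0005, 400, 100)  # 0.0070833
#' @export
leaf_co2_conductance_from_fluxes <- function(A, E, C_a, C_i) {
  if (any(C_a <= C_i))
    stop("C_a <= C_i: conductance inversion undefined")
  (A + (E / 2) * (C_a + C_i)) / (C_a - C_i)
}

#' Partition leaf conductance into cuticular and stomatal components
#'
#' Solves the 2x2 linear system formed by the water-side identity
#' `g_lw = g_sw + g_cw` and the CO2-side composition
#' `g_lc = g_sw/1.6 + g_cw/20`:
#' \deqn{g_{cw} = \frac{g_{lw}/1.6 - g_{lc}}{1/1.6 - 1/20}, \quad
#'       g_{sw} = g_{lw} - g_{cw}.}
#' Solutions with `g_cw` outside `[0, g_lw]` are flagged non-physical (kept,
#' with a warning).
#'
#' @param g_lw Leaf conductance to water (mol m-2 s-1), > 0.
#' @param g_lc Leaf conductance to CO2 (mol m-2 s-1), > 0.
#' @return Data frame with `g_cw`, `g_sw`, `physical`.
#' @examples
#' solve_gcw(0.01, 0.003375)  # g_cw = 0.005, g_sw = 0.005
#' @export
solve_gcw <- function(g_lw, g_lc) {
  if (any(g_lw <= 0) || any(g_lc <= 0))
    stop("conductances must be positive")
  g_cw <- (g_lw / 1.6 - g_lc) / (1 / 1.6 - 1 / 20)
  g_sw <- g_lw - g_cw
  physical <- g_cw >= 0 & g_cw <= g_lw
  if (any(!physical))
    warning(sum(!physical), " record(s) yield g_cw outside [0, g_lw]")
  data.frame(g_cw = g_cw, g_sw = g_sw, physical = physical)
}

#' Estimate cuticular conductance from a red-light run
#'
#' For each record of the steady-state window (the final `steady` seconds of
#' the run, i.e. 42 records at the default 7-s cadence over 5 min), infers
#' `C_i` from the RuBP-limited inversion, the CO2-side conductance from the
#' fluxes, and the cuticular/stomatal split from the two-conductance system;
#' returns the mean and standard deviation of `g_cw` over the window.
#' Non-physical records are excluded (estimation fails if they exceed half
#' the window).
#'
#' @param run A `"redlight_run"` (see [generate_redlight_run()]) or a
#'   gas-exchange records data frame (then `R_dark` and `steady`/`cadence`
#'   must be supplied).
#' @param J_a,Gamma_star Companion-curve electron transport rate and
#'   photo-compensation point (see [estimate_j_gammastar()]).
#' @param R_dark Dark respiration; defaults to the run's recorded value.
#' @param g_bw Boundary-layer conductance to water for exact series-resistor
#'   removal of the boundary layer from the CO2-side conductance; `NULL`
#'   (default) treats the boundary layer as non-limiting.
#' @param steady,cadence Window duration and cadence (s); default from the
#'   run's protocol.
#' @return A list of class `"gcw_estimate"`: `mean`, `sd`, `n_used`,
#'   `n_excluded`, `values` (per-record `g_cw`).
#' @export
estimate_gcw <- function(run, J_a, Gamma_star, R_dark = NULL, g_bw = NULL,
                         steady = NULL, cadence = NULL) {
  if (inherits(run, "redlight_run")) {
    records <- run$records
    if (is.null(R_dark)) R_dark <- run$R_dark
    if (is.null(steady)) steady <- run$protocol$steady
    if (is.null(cadence)) cadence <- run$protocol$cadence
  } else {
    records <- as.data.frame(run)
    if (is.null(R_dark) || is.null(steady) || is.null(cadence))
      stop("`R_dark`, `steady` and `cadence` are required for raw records")
  }
  n_window <- floor(steady / cadence)
  if (nrow(records) < n_window)
    stop("run shorter than the steady-state window")
  win <- tail(records, n_window)

  res <- lapply(seq_len(nrow(win)), function(i) {
    r <- win[i, ]
    out <- tryCatch({
      ci <- invert_ci_redlight(r$A, R_dark, J_a, Gamma_star)
      g <- leaf_co2_conductance_from_fluxes(r$A, r$E, r$Ca, ci)
      g_lc <- if (is.null(g_bw)) g else {
        # remove the boundary-layer series resistance exactly
        inv <- 1 / g - 1.37 / g_bw
        if (inv <= 0) stop("boundary-layer removal leaves no leaf resistance")
        1 / inv
      }
      suppressWarnings(solve_gcw(r$gsw, g_lc))
    }, error = function(e) NULL)
    if (is.null(out)) data.frame(g_cw = NA_real_, physical = FALSE)
    else out[, c("g_cw", "physical")]
  })
  res <- do.call(rbind, res)
  ok <- res$physical & is.finite(res$g_cw)
  if (sum(!ok) > 0.5 * n_window)
    stop("more than half of the window records are non-physical: estimation failure")
  vals <- res$g_cw[ok]
  structure(list(mean = mean(vals), sd = sd(vals), n_used = length(vals),
                 n_excluded = sum(!ok), values = vals),
            class = "gcw_estimate")
}

#' @export
print.gcw_estimate <- function(x, ...) {
  cat(sprintf("g_cw = %.5f +/- %.5f mol m-2 s-1 (n = %d, %d excluded)\n",
              x$mean, x$sd, x$n_used, x$n_excluded))
  invisible(x)
}
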