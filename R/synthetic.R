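# Synthetic gas-exchange instrument: CO2-response protocols, a
# CO2-responsive stomatal model, instrument noise, and generation of
# leaf, empty-chamber and red-light runs in an LI-6800-style table.

li6800_mandatory <- c("elapsed", "A", "E", "Ca", "Ci", "CO2_r", "Tleaf",
                      "VPDleaf", "Patm")

#' Steady-state CO2-response protocol
#'
#' The 16-setpoint progression used for steady-state A/Ci curves: start at
#' 380 umol mol-1 then 285, 190, 145, 100, 50, back to 380 and up to 1960.
#' One record is logged per setpoint; the generator advances elapsed time by
#' `max_wait` seconds per setpoint (the stabilisation ceiling), making the
#' simulated run deterministic.
#'
#' @param setpoints Reference CO2 setpoints (umol mol-1).
#' @param min_wait,max_wait Stabilisation waiting-time bounds (s).
#' @return A protocol object of class `"gx_protocol"`.
#' @export
protocol_ss <- function(setpoints = c(380, 285, 190, 145, 100, 50, 380, 475,
                                      570, 665, 760, 960, 1160, 1460, 1760,
                                      1960),
                        min_wait = 60, max_wait = 120) {
  stopifnot(length(setpoints) >= 1, all(setpoints > 0), min_wait <= max_wait)
  structure(list(kind = "SS", setpoints = setpoints, min_wait = min_wait,
                 max_wait = max_wait),
            class = "gx_protocol")
}

#' Constant-ramp (RACiR) CO2 protocol
#'
#' A continuous reference-CO2 ramp at `rate` umol mol-1 min-1 logged every
#' `log_interval` seconds, padded by `pad` seconds of holding at each
#' endpoint (so the logged window slightly exceeds the nominal ramp: the
#' default 100 to 900 ramp at 100 umol mol-1 min-1 spans 8 min of ramping
#' inside a 9 min logged window, i.e. 270 records at 2 s, and 100 to 2000
#' spans 19 min inside 20, i.e. 600 records).
#'
#' @param start,end Ramp endpoints (umol mol-1).
#' @param rate Ramp rate (umol mol-1 min-1), > 0.
#' @param log_interval Logging cadence (s).
#' @param pad Endpoint holding time (s) at each end.
#' @return A protocol object of class `"gx_protocol"`.
#' @export
protocol_racir <- function(start = 100, end = 900, rate = 100,
                           log_interval = 2, pad = 30) {
  stopifnot(start > 0, end > 0, rate > 0, log_interval > 0, pad >= 0)
  structure(list(kind = "RACiR", start = start, end = end, rate = rate,
                 log_interval = log_interval, pad = pad),
            class = "gx_protocol")
}

#' Empty-chamber protocol
#'
#' Same trajectory as [protocol_racir()] but run with no leaf clamped, used
#' to characterise apparent-assimilation drift and conductance noise.
#'
#' @inheritParams protocol_racir
#' @return A protocol object of class `"gx_protocol"`.
#' @export
protocol_empty <- function(start = 100, end = 900, rate = 100,
                           log_interval = 2, pad = 30) {
  p <- protocol_racir(start, end, rate, log_interval, pad)
  p$kind <- "empty"
  p
}

#' Red-light induction protocol
#'
#' Constant CO2 under low red light: records every `cadence` seconds through
#' a photosynthetic induction phase followed by a steady-state window. The
#' cuticular-conductance estimator uses the final `steady` seconds, i.e.
#' `floor(steady / cadence)` complete intervals (42 at the defaults).
#'
#' @param C_a Chamber CO2 (umol mol-1).
#' @param induction Induction duration (s).
#' @param steady Steady-state window duration (s).
#' @param cadence Logging cadence (s).
#' @param Q_red Red-light irradiance (umol m-2 s-1).
#' @return A protocol object of class `"gx_protocol"`.
#' @export
protocol_redlight <- function(C_a = 400, induction = 300, steady = 300,
                              cadence = 7, Q_red = 100) {
  stopifnot(C_a > 0, induction >= 0, steady > 0, cadence > 0)
  structure(list(kind = "redlight", C_a = C_a, induction = induction,
                 steady = steady, cadence = cadence, Q_red = Q_red),
            class = "gx_protocol")
}

#' CO2-responsive stomatal model
#'
#' First-order stomatal dynamics toward a CO2-dependent target:
#' `g_target(C_a) = g_min + (g_max - g_min) * max(0, 1 - s (C_a - 400))`
#' (capped at `g_max`), relaxed with time constant `tau`. This is the
#' simplest mechanism reproducing the observed decline of stomatal
#' conductance as ambient CO2 rises above ~400 umol mol-1, with slower
#' stomata lagging a fast CO2 ramp.
#'
#' @param g_max,g_min Maximum and minimum stomatal conductance to water
#'   (mol m-2 s-1), `g_min >= g_cw_true >= 0` is required so the leaf total
#'   never falls below its cuticular floor.
#' @param sensitivity Slope `s` of the target decline per umol mol-1 above
#'   400 (dimensionless per umol mol-1).
#' @param tau Relaxation time constant (s), > 0.
#' @param g_cw_true True cuticular conductance to water (mol m-2 s-1).
#' @return A list of class `"stomatal_model"`.
#' @export
stomatal_model <- function(g_max = 0.2, g_min = 0.03, sensitivity = 5e-4,
                           tau = 60, g_cw_true = 0.0056) {
  if (tau <= 0) stop("`tau` must be positive")
  if (!(g_min >= g_cw_true && g_cw_true >= 0))
    stop("need g_min >= g_cw_true >= 0")
  if (g_max < g_min) stop("need g_max >= g_min")
  structure(list(g_max = g_max, g_min = g_min, sensitivity = sensitivity,
                 tau = tau, g_cw_true = g_cw_true),
            class = "stomatal_model")
}

stomatal_target <- function(stomata, C_a) {
  tgt <- stomata$g_min + (stomata$g_max - stomata$g_min) *
    pmax(0, 1 - stomata$sensitivity * (C_a - 400))
  pmin(tgt, stomata$g_max)
}

#' Species-level stomatal presets
#'
#' Stomatal models whose steady conductance at 400 umol mol-1 CO2 matches
#' the species means measured in this system: magnolia `g_lw` 0.09 /
#' `g_cw` 0.0053, citrus 0.12 / 0.0045, bell pepper 0.33 / 0.0076, papaya
#' 0.17 / 0.0056 (mol m-2 s-1). `g_max` is set so `g_sw + g_cw` reproduces
#' the species `g_lw` at 400 umol mol-1.
#'
#' @param species One of `"magnolia"`, `"citrus"`, `"pepper"`, `"papaya"`.
#' @param ... Overrides passed to [stomatal_model()].
#' @return A [stomatal_model()].
#' @export
species_preset <- function(species = c("magnolia", "citrus", "pepper",
                                       "papaya"), ...) {
  species <- match.arg(species)
  tab <- list(magnolia = c(g_lw = 0.09, g_cw = 0.0053),
              citrus   = c(g_lw = 0.12, g_cw = 0.0045),
              pepper   = c(g_lw = 0.33, g_cw = 0.0076),
              papaya   = c(g_lw = 0.17, g_cw = 0.0056))[[species]]
  g_max <- unname(tab["g_lw"] - tab["g_cw"])
  defaults <- list(g_max = g_max,
                   g_min = max(0.25 * g_max, tab[["g_cw"]]),
                   sensitivity = 5e-4, tau = 60,
                   g_cw_true = unname(tab["g_cw"]))
  do.call(stomatal_model, modifyList(defaults, list(...)))
}

#' Instrument noise specification
#'
#' Gaussian noise added to reported observables. The conductance noise
#' default, sd 0.00415 mol m-2 s-1, is the standard deviation of `g_lw`
#' observed in empty-chamber ramps (where the true conductance is zero).
#' Noise on `A` defaults to zero.
#'
#' @param sd_glw Standard deviation of noise in reported `g_lw`
#'   (mol m-2 s-1), >= 0.
#' @param sd_A Standard deviation of noise in reported `A`
#'   (umol m-2 s-1), >= 0.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(sd_glw = 0.00415, sd_A = 0) {
  if (sd_glw < 0 || sd_A < 0) stop("noise standard deviations must be >= 0")
  structure(list(sd_glw = sd_glw, sd_A = sd_A), class = "noise_spec")
}

# elapsed time / reference-CO2 / irradiance trajectory implied by a protocol
protocol_trajectory <- function(protocol) {
  switch(protocol$kind,
    SS = data.frame(
      elapsed = cumsum(rep(protocol$max_wait, length(protocol$setpoints))),
      C_ref = protocol$setpoints, Q_in = 1200),
    RACiR = ,
    empty = {
      ramp_s <- abs(protocol$end - protocol$start) / protocol$rate * 60
      total <- ramp_s + 2 * protocol$pad
      t <- seq(protocol$log_interval, total, by = protocol$log_interval)
      frac <- pmin(pmax(t - protocol$pad, 0), ramp_s)
      cref <- protocol$start +
        sign(protocol$end - protocol$start) * frac * protocol$rate / 60
      data.frame(elapsed = t, C_ref = cref, Q_in = 1200)
    },
    redlight = {
      t <- seq(protocol$cadence, protocol$induction + protocol$steady,
               by = protocol$cadence)
      data.frame(elapsed = t, C_ref = protocol$C_a, Q_in = protocol$Q_red)
    },
    stop("unknown protocol kind: ", protocol$kind))
}

#' Generate a synthetic leaf gas-exchange run
#'
#' Simulates a leaf measured under a CO2-response protocol: stomatal
#' conductance relaxes first-order toward its CO2-dependent target, the true
#' assimilation and intercellular CO2 come from the coupled FvCB/diffusion
#' solver with the cuticular pathway partitioned correctly
#' (`g_lc = g_sw/1.6 + g_cw/20`), Gaussian noise is added to the *reported*
#' conductance (and optionally to `A`), and the stored `Ci` is then
#' recomputed from the noisy observables exactly as the instrument would —
#' through the uncorrected pathway that lumps all conductance into `g_sw`.
#'
#' Under a red-light protocol assimilation uses the RuBP-regeneration-limited
#' rate only (`rates = "rubp"`): at 100 umol m-2 s-1 the leaf is strictly
#' light-limited, and stomata are held near their minimum, opening from half
#' of it during induction.
#'
#' The true state (conductances, `A`, `C_i` before noise) is attached as
#' `attr(, "truth")`.
#'
#' @param protocol A `gx_protocol` ([protocol_ss()], [protocol_racir()],
#'   [protocol_redlight()]).
#' @param params An [fvcb_params()] object.
#' @param stomata A [stomatal_model()] or [species_preset()].
#' @param noise A [noise_spec()]; a `seed` is mandatory whenever any noise sd
#'   is non-zero.
#' @param chamber A [chamber_state()]; `C_a` is driven by the protocol.
#' @param seed Integer seed for the noise draws.
#' @return A data frame of class `"gas_exchange_records"` with columns
#'   `elapsed`, `A`, `E`, `gsw` (the reported leaf conductance to water),
#'   `Ca`, `Ci`, `CO2_r`, `Tleaf`, `VPDleaf`, `Patm`, `Qin`.
#' @examples
#' run <- generate_curve(protocol_ss(), noise = noise_spec(0, 0))
#' nrow(run)  # 16
#' @export
generate_curve <- function(protocol, params = fvcb_params(),
                           stomata = stomatal_model(),
                           noise = noise_spec(), chamber = chamber_state(),
                           seed = NULL) {
  if (!inherits(protocol, "gx_protocol")) stop("`protocol` must be a gx_protocol")
  if ((noise$sd_glw > 0 || noise$sd_A > 0) && is.null(seed))
    stop("`seed` is required when any noise sd is non-zero")
  traj <- protocol_trajectory(protocol)
  n <- nrow(traj)
  g_cw <- stomata$g_cw_true
  redlight <- protocol$kind == "redlight"
  if (any(traj$C_ref < params$Gamma_star))
    warning("protocol drives C_a below the photo-compensation point; ",
            "assimilation is negative there")

  target <- if (redlight) rep(stomata$g_min, n)
            else stomatal_target(stomata, traj$C_ref)
  g_sw <- numeric(n)
  g_sw[1] <- if (redlight) stomata$g_min / 2 else target[1]
  if (n > 1) for (i in 2:n) {
    dt <- traj$elapsed[i] - traj$elapsed[i - 1]
    # exact first-order relaxation over the step (target constant in-step)
    g_sw[i] <- target[i] + (g_sw[i - 1] - target[i]) * exp(-dt / stomata$tau)
  }

  rates <- if (redlight) "rubp" else "all"
  mode <- if (g_cw > 0) "corrected" else "uncorrected"
  A_true <- Ci_true <- E_true <- numeric(n)
  lim <- character(n)
  for (i in seq_len(n)) {
    ch <- chamber
    ch$C_a <- traj$C_ref[i]
    s <- coupled_solve(g_sw[i] + g_cw, g_cw, ch, params, mode, rates)
    A_true[i] <- s$A
    Ci_true[i] <- s$C_i
    E_true[i] <- s$E
    lim[i] <- s$limitation
  }
  g_lw_true <- g_sw + g_cw

  if (!is.null(seed)) set.seed(seed)
  gsw_obs <- g_lw_true + if (noise$sd_glw > 0) rnorm(n, 0, noise$sd_glw) else 0
  A_obs <- A_true + if (noise$sd_A > 0) rnorm(n, 0, noise$sd_A) else 0
  # instrument Ci: uncorrected pathway applied to the reported conductance
  Ci_obs <- rep(NA_real_, n)
  ok <- gsw_obs > 0
  if (any(ok))
    Ci_obs[ok] <- intercellular_co2(
      A_obs[ok], E_true[ok], traj$C_ref[ok],
      total_conductance_co2(gsw_obs[ok], chamber$g_bw, chamber$K),
      quiet = TRUE)

  rec <- data.frame(elapsed = traj$elapsed, A = A_obs, E = E_true,
                    gsw = gsw_obs, Ca = traj$C_ref, Ci = Ci_obs,
                    CO2_r = traj$C_ref, Tleaf = chamber$T_leaf,
                    VPDleaf = chamber$VPD, Patm = chamber$P_atm,
                    Qin = traj$Q_in)
  structure(rec,
            truth = data.frame(g_sw = g_sw, g_lw = g_lw_true, A = A_true,
                               C_i = Ci_true, E = E_true, limitation = lim),
            protocol = protocol,
            class = c("gas_exchange_records", "data.frame"))
}

#' Generate a synthetic empty-chamber run
#'
#' An empty, sealed chamber has true conductance zero and true assimilation
#' zero; what the instrument reports is an apparent-assimilation drift
#' (modelled as a polynomial in reference CO2, degree at most 5) plus noise,
#' and a conductance that is pure Gaussian noise around zero. The stored `Ci`
#' is `NA` (the instrument value is meaningless with no leaf).
#'
#' @param protocol A [protocol_empty()] (or RACiR) protocol.
#' @param coef Polynomial coefficients of apparent `A` versus `CO2_r`,
#'   intercept first; length at most 6 (degree 5).
#' @param noise A [noise_spec()]; `sd_glw` feeds the reported conductance,
#'   `sd_A` adds onto the drift polynomial.
#' @param chamber A [chamber_state()].
#' @param seed Seed, mandatory when any noise sd is non-zero.
#' @return A `gas_exchange_records` data frame.
#' @examples
#' e <- generate_empty_chamber(coef = c(0.5, 0.001), noise = noise_spec(0, 0))
#' e$A[e$CO2_r == 400][1]  # 0.9
#' @export
generate_empty_chamber <- function(protocol = protocol_empty(),
                                   coef = c(0, 0), noise = noise_spec(),
                                   chamber = chamber_state(), seed = NULL) {
  if (!inherits(protocol, "gx_protocol") ||
      !protocol$kind %in% c("empty", "RACiR"))
    stop("`protocol` must be an empty-chamber (or RACiR) protocol")
  if (length(coef) > 6) stop("drift polynomial degree must be <= 5")
  if ((noise$sd_glw > 0 || noise$sd_A > 0) && is.null(seed))
    stop("`seed` is required when any noise sd is non-zero")
  traj <- protocol_trajectory(protocol)
  n <- nrow(traj)
  drift <- drop(outer(traj$C_ref, seq_along(coef) - 1, `^`) %*% coef)
  if (!is.null(seed)) set.seed(seed)
  gsw <- if (noise$sd_glw > 0) rnorm(n, 0, noise$sd_glw) else rep(0, n)
  A <- drift + if (noise$sd_A > 0) rnorm(n, 0, noise$sd_A) else 0
  rec <- data.frame(elapsed = traj$elapsed, A = A, E = 0, gsw = gsw,
                    Ca = traj$C_ref, Ci = NA_real_, CO2_r = traj$C_ref,
                    Tleaf = chamber$T_leaf, VPDleaf = chamber$VPD,
                    Patm = chamber$P_atm, Qin = traj$Q_in)
  structure(rec, protocol = protocol,
            class = c("gas_exchange_records", "data.frame"))
}

#' Generate a synthetic red-light cuticular-conductance run
#'
#' Wraps [generate_curve()] with a [protocol_redlight()] and packages the
#' pieces the red-light estimator needs: the records, the dark respiration
#' recorded before induction (the model's `R_d`), and the protocol defining
#' the steady window.
#'
#' @param params An [fvcb_params()]; `J` should be the electron transport
#'   rate sustained by the red light (well below the light-saturated value).
#' @param stomata A [stomatal_model()]; red light holds conductance near
#'   `g_min`.
#' @param noise A [noise_spec()].
#' @param chamber A [chamber_state()].
#' @param protocol A [protocol_redlight()].
#' @param seed Seed, mandatory when noise is non-zero.
#' @return A list of class `"redlight_run"`: `records`, `R_dark`,
#'   `protocol`.
#' @export
generate_redlight_run <- function(params = fvcb_params(J = 60, R_d = 1),
                                  stomata = stomatal_model(g_max = 0.02,
                                                           g_min = 0.01),
                                  noise = noise_spec(),
                                  chamber = chamber_state(),
                                  protocol = protocol_redlight(),
                                  seed = NULL) {
  chamber$C_a <- protocol$C_a
  rec <- generate_curve(protocol, params, stomata, noise, chamber, seed)
  structure(list(records = rec, R_dark = params$R_d, protocol = protocol),
            class = "redlight_run")
}

#' Write gas-exchange records to an LI-6800-style CSV
#'
#' Single header row, comma separated, full double precision. Any extra
#' (vendor) columns present are written too and survive a round trip.
#'
#' @param records A data frame of gas-exchange records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_li6800_csv <- function(records, path) {
  df <- as.data.frame(records)
  # full precision so that write/read round-trips losslessly
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an LI-6800-style gas-exchange CSV
#'
#' Expects a single header row naming at least `elapsed`, `A`, `E`, `gsw`
#' (or `glw`), `Ca`, `Ci`, `CO2_r`, `Tleaf`, `VPDleaf`, `Patm`. A `glw`
#' column is accepted as a synonym for `gsw` (what the instrument labels
#' stomatal conductance is really whole-leaf conductance). Unknown columns
#' are preserved.
#'
#' @param path CSV file path.
#' @return A data frame of class `"gas_exchange_records"`.
#' @export
read_li6800_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if ("glw" %in% names(df) && !"gsw" %in% names(df))
    names(df)[names(df) == "glw"] <- "gsw"
  missing <- setdiff(c(li6800_mandatory, "gsw"), names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  structure(df, class = c("gas_exchange_records", "data.frame"))
}
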