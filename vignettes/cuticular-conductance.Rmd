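---
title: "Correcting gas-exchange analyses for cuticular conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting gas-exchange analyses for cuticular conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuticond)
```

## The problem

Portable gas-exchange systems report a leaf conductance to water vapour,
`g_lw`, and nearly all downstream calculations treat it as if it were purely
stomatal. In reality the cuticle conducts too:

$$g_{lw} = g_{sw} + g_{cw}.$$

For water this distinction barely matters. For CO~2~ it matters a great
deal, because the two pathways discriminate very differently between the two
gases: stomatal conductance to CO~2~ is `g_sw / 1.6`, while the cuticle is a
far stronger barrier to CO~2~ than to water, here taken as a 1:20 ratio, so
the cuticular CO~2~ conductance is only `g_cw / 20`. Lumping the cuticular
pathway into the stomatal one therefore overestimates the leaf's CO~2~
conductance and, through the standard intercellular CO~2~ calculation,

$$C_i = \frac{(g_{tc} - E/2)\,C_a - A}{g_{tc} + E/2},$$

overestimates `C_i`. The error is negligible for well-open stomata but grows
rapidly as conductance falls — precisely the regime of drought studies,
xerophytes, high-temperature work, and any species that slams its stomata
shut at high CO~2~ in the middle of an A/C~i~ curve. Because every
parameter extracted from an A/C~i~ curve is keyed to `C_i`, the bias
propagates into `V_cmax`, `J`, respiration and the limitation transition
points.

The corrected pathway implemented here removes the cuticular component
before converting to CO~2~ units:

$$g_{sw} = g_{lw} - g_{cw}, \qquad
  g_{lc} = \frac{g_{sw}}{1.6} + \frac{g_{cw}}{20},$$

and rebuilds the total conductance to CO~2~ by feeding a *pseudo*-`g_lw`
(1.6 times the corrected CO~2~ conductance) through the usual series
combination with the boundary layer — the trick that lets any downstream
component which internally assumes `g_tc = g_lw / 1.6` consume a corrected
conductance unchanged. The misestimation committed by not correcting is
summarised as the proportional difference
`(C_i,uncorr − C_i,cor) / C_i,cor`.

## The coupled forward model

Quantifying the bias requires knowing what `C_i` *should* be at a given
conductance, which couples the diffusion equation above to a photosynthesis
model. We use the Farquhar–von Caemmerer–Berry (FvCB) model for C3 leaves:
net assimilation is the hard minimum of the Rubisco-limited,
RuBP-regeneration-limited and (optionally) triose-phosphate-utilization-
limited rates, minus day respiration:

$$A = \min\!\left(
  \frac{V_{cmax}(C_i - \Gamma^*)}{C_i + K_m},\;
  \frac{J(C_i - \Gamma^*)}{4C_i + 8\Gamma^*},\;
  3\,\mathrm{TPU}\right) - R_d,
  \qquad K_m = K_c\left(1 + \frac{O}{K_o}\right).$$

`coupled_solve()` finds the unique `(A, C_i)` pair satisfying both equations
by bracketed root search on `C_i`; transpiration is `E = g_lw\,VPD/P_{atm}`.
The residual of the fixed point is reported and is held below 10^-8^.

Choices worth stating explicitly:

* **Hard minimum, not hyperbolic smoothing,** in the forward model, so that
  the limitation transitions `C_itrans1` and `C_itrans2` are exact
  intersections with closed forms (`transition_ci()`). Smoothing is offered
  as a fitting option only.
* **Kinetic constants** default to standard 25 °C values: Γ\* = 42.75,
  K~c~ = 404.9 µmol mol^−1^, K~o~ = 278.4, O = 210 mmol mol^−1^. No
  temperature responses are applied anywhere; all parameters refer to the
  measurement temperature (25 °C), and `J` means the electron transport rate
  at the operating irradiance of 1200 µmol m^−2^ s^−1^.
* **Respiration** for the modelling sweeps defaults to `R_d` = 1.5
  µmol m^−2^ s^−1^, a standard default, and is configurable.
* **Bracket** (Γ\*/1000, C~a~], extended upward when respiration makes the
  leaf a net CO~2~ source (ambient CO~2~ near the compensation point), in
  which case `C_i` legitimately exceeds `C_a`.
* **Negative computed `C_i`** from the uncorrected instrument arithmetic is
  returned with a warning rather than clamped or raised: that such values
  occur at low conductance is part of what the analysis is meant to show.
* **`K` defaults to 0** (hypostomatous; common for low-conductance species)
  and the boundary-layer conductance to 2.23 mol m^−2^ s^−1^; both are
  configurable through `chamber_state()`.

## Misestimation sweeps and noise envelopes

`sweep_glw()` runs both conductance pathways over a grid of `g_lw` from
0.001 to 1 mol m^−2^ s^−1^ in 0.001 steps, at ambient CO~2~ scenarios of
100, 400 and 2000 µmol mol^−1^, with `g_cw` = 0.0056 mol m^−2^ s^−1^ (the
mid-range of the four species measured in this system). Expressed against
the ratio `g_cw`:`g_lw`, the misestimation curves for different species
align closely. `threshold_ratio()` reports the ratio at which the error
first exceeds a threshold (default 5%), linearly interpolating between the
bracketing grid rows; at 400 µmol mol^−1^ this crossing sits near a ratio of
0.11:

```{r}
prof <- sweep_glw(g_lw = seq(0.005, 0.3, by = 0.001), g_cw = 0.0056,
                  C_a = 400)
threshold_ratio(prof)
```

Instrument noise compounds the problem. Empty-chamber ramps — where the true
conductance is exactly zero — put the standard deviation of reported `g_lw`
at 0.00415 mol m^−2^ s^−1^. `noise_band()` treats the true conductance as
possibly ±1 sd away from the measured value and reports the worst-case
proportional `C_i` deviation; this is a deterministic envelope, not a
Monte-Carlo exercise, matching how the uncertainty is defined.
`combined_max_error()` stacks both effects: the worst uncorrected `C_i`
anywhere in the noise band against the corrected value at the measured
conductance. Even with the cuticular correction applied, conductance noise
alone pushes the `C_i` error past 5% once `g_cw`:`g_lw` reaches about 0.13.

Crossings are reported to the grid's interpolated precision; whether one
interpolates or takes the nearest grid row matters only below the two
decimals at which these ratios are quoted.

## What the synthetic instrument emulates — and what it does not

`generate_curve()` plays the role of the gas analyzer so that every
estimator in the package can be tested against known truth:

* **Protocols.** The 16-setpoint steady-state progression (380, down to 50,
  back to 380 and up to 1960 µmol mol^−1^); constant ramps at 100
  µmol mol^−1^ min^−1^ logged every 2 s; a red-light induction run logged
  every 7 s with a 5-min steady window. Ramp windows carry 30 s of endpoint
  holding on each side, so the 100→900 ramp logs 540 s = 270 records and the
  100→2000 ramp logs 1200 s = 600 records — both matching the record counts
  these protocols produce in practice. Steady-state setpoints advance by the
  120-s stabilisation ceiling, deterministically.
* **Stomatal dynamics.** A first-order relaxation (exact exponential update
  per logging step) toward a CO~2~-dependent target that declines linearly
  above 400 µmol mol^−1^ — the simplest mechanism that reproduces stomata
  closing as ambient CO~2~ rises, and lagging a fast ramp. Species presets
  pin the steady conductance at 400 µmol mol^−1^ to the measured species
  means (e.g. papaya `g_lw` 0.17, `g_cw` 0.0056 mol m^−2^ s^−1^).
* **Truth vs report.** The *true* state is solved through the corrected
  pathway with the cuticle partitioned properly; Gaussian noise (sd 0.00415
  by default) is then added to the *reported* conductance, and the stored
  `Ci` is recomputed from the noisy observables through the uncorrected
  pathway — exactly the calculation the instrument performs. The true state
  travels along as an attribute.
* **Red light.** Under 100 µmol m^−2^ s^−1^ red light the leaf is strictly
  light-limited, so the generator uses the RuBP-regeneration-limited rate
  alone; with the full minimum rule the default `V_cmax` would spuriously
  take over at the low `C_i` reached under red light, which is not the
  physiology the red-light method exploits. Stomata are held near their
  minimum, opening from half of it during induction.

Not emulated: reference/sample matching drift beyond the empty-chamber
polynomial (degree ≤ 5 in reference CO~2~), humidity-control dynamics,
chamber leaks, and any difference between sample and reference CO~2~ along
the flow path (the generator sets `Ca = CO2_r`). Passing tests against this
generator therefore demonstrate the *estimators'* correctness and
noise behaviour, not robustness to every artefact of real instruments.

## RACiR calibration

Constant-ramp curves require subtracting the apparent assimilation an empty
chamber shows along the same ramp. `select_calibration_range()` trims the
distorted ramp ends (the cutoffs are deliberately required arguments — they
depend on the instrument and ramp), `fit_empty_model()` fits polynomials of
degree 1–5 in reference CO~2~ and picks the degree by BIC, and
`apply_correction()` subtracts the drift and recomputes `Ci` from the
corrected `A` through the uncorrected instrument pathway. The
cuticular-conductance recomputation is deliberately *not* applied here but
at refitting time (`recompute_curve()`), keeping the two corrections
orthogonal.

Two numerical choices: the polynomial basis is orthogonal (raw powers of
CO~2~ up to 2000^5^ would be numerically fragile), and the residual sum of
squares is floored at a scale-relative epsilon before the BIC comparison —
on noise-free data every candidate degree fits exactly and the comparison
would otherwise be decided by floating-point dust rather than by the
parameter penalty.

## Fitting A/C~i~ curves

`fit_aci()` estimates `V_cmax`, `J_1200`, `R_dark` and optionally TPU by
bounded least squares on the hard-minimum model, with Γ\* and the kinetic
constants held fixed (they are not identifiable from a single curve at one
temperature; fixing them is also the conventional choice). Starting values
are deterministic: each observation is inverted for the parameter value that
would make its candidate limitation pass through it exactly — the binding
process attains the maximum of those per-point estimates — and a small grid
around these seeds a multi-start quasi-Newton search. No randomness is
involved anywhere in the fit. Standard errors come from the Gauss–Newton
curvature at the optimum.

TPU is reported absent (`NA`) when the data cannot support it: the fitted
plateau `3 TPU` exceeds the largest observed `A` by more than twice the
residual scale, or the optimum sits on its bound. This reproduces the
practical pattern that ramps stopping at moderate CO~2~ yield no TPU
estimate while wider ramps do. Transition points are computed from the
fitted parameters by the same closed forms as the forward model, so a
missing TPU implies a missing second transition.

`delta_cv()` compares the precision of ramp-derived versus steady-state
parameter estimates as `1 − CV_ramp / CV_SS` (CV = sd/mean across replicate
fits): positive values mean the ramp is more precise.
`delta_cv_from_summary()` accepts published mean ± SE pairs; with equal
replicate counts the √n factors cancel, so SEs work in place of sds.

## The red-light method for cuticular conductance

Under low red light, gross assimilation follows the RuBP-limited rate, which
can be inverted for `C_i` once the operating electron transport rate `J_a`
and Γ\* are known (from a companion low-light A/C~i~ ramp fitted with
`estimate_j_gammastar()`, respiration fixed at the separately measured
`R_dark`):

$$C_i = \Gamma^* \frac{J_a + 8G}{J_a - 4G}, \qquad G = A + R_{dark}.$$

With `C_i` known, the ternary equation inverts for the leaf's CO~2~-side
conductance, and the water-side/CO~2~-side pair
(`g_lw = g_sw + g_cw`, `g_lc = g_sw/1.6 + g_cw/20`) is a 2×2 linear system
for the split (`solve_gcw()`). `estimate_gcw()` applies this per record over
the steady window — the final 300 s, i.e. 42 complete 7-s intervals — and
reports the mean ± sd, excluding (and counting) non-physical records.

Choices: `G` uses the measured dark respiration with no light-inhibition
factor applied; the boundary layer is treated as non-limiting by default
(under red light `g_lw` ≈ 0.01 ≪ `g_bw` = 2.23 mol m^−2^ s^−1^), with an
exact series-resistor removal available via the `g_bw` argument — the
removal matters only when `g_cw` itself is very small, where a
half-percent bias in `g_lc` is no longer negligible relative to `g_cw`.
Note one behaviour inherited from the method itself: because records whose
solved `g_cw` falls outside `[0, g_lw]` are excluded, per-record noise
produces a small upward bias in the window mean.

## Problem sizes and determinism

The package's own test suite regenerates everything it checks: sweeps run
the full 1000-point conductance grid; solver validation compares against an
exhaustive 0.001-resolution grid search over `C_i` for 100 random parameter
draws under a fixed seed; fitting is validated on one noise-free curve per
scenario plus 50 seeded noisy steady-state curves (conductance noise sd
0.00415, assimilation noise sd 0.2 µmol m^−2^ s^−1^). All stochastic paths
require an explicit seed, and identical inputs produce byte-identical
outputs.

## Known limitations

* C3 leaves only; no mesophyll conductance, no C4 pathway.
* No temperature response functions: everything is at measurement
  temperature.
* The cuticular water:CO~2~ ratio is fixed at 1:20; literature values range
  to 1:40, which would halve the cuticular CO~2~ term.
* The stomatal dynamics model is deliberately minimal (linear CO~2~ target,
  single time constant); it reproduces the qualitative closing behaviour,
  not any particular species' kinetics.
* `delta_cv()` compares dispersion only; it says nothing about accuracy.
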