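# Empty-chamber calibration of constant-ramp (RACiR) curves: trim the
# usable reference-CO2 range, fit the apparent-assimilation drift, and
# subtract it from leaf runs before refitting.

#' Trim an empty-chamber run to the usable calibration range
#'
#' Ramp endpoints are distorted by the system settling in and out of the
#' ramp, so calibration uses an interior window of reference CO2. Rows
#' outside `[lower, upper]` on `CO2_r` are removed and the removal count is
#' attached as `attr(, "removed")`.
#'
#' @param records Empty-chamber gas-exchange records.
#' @param lower,upper Reference-CO2 cutoffs (umol mol-1), which must overlap
#'   the data span.
#' @return The trimmed records.
#' @export
select_calibration_range <- function(records, lower, upper) {
  if (lower >= upper) stop("`lower` must be below `upper`")
  span <- range(records$CO2_r)
  if (lower > span[2] || upper < span[1])
    stop(sprintf("calibration range [%g, %g] is outside the data span [%g, %g]",
                 lower, upper, span[1], span[2]))
  keep <- records$CO2_r >= lower & records$CO2_r <= upper
  if (!any(keep)) stop("calibration range excludes every row")
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Fit the empty-chamber apparent-assimilation model
#'
#' Least-squares polynomials of apparent `A` on `CO2_r` are fitted for each
#' degree from 1 to `max_degree` (orthogonal polynomial basis, for numerical
#' stability over the wide CO2 range) and the degree is chosen by BIC. On
#' effectively noise-free data every degree fits exactly and the BIC
#' comparison would be decided by floating-point dust, so the residual sum of
#' squares is floored at a scale-relative epsilon before the comparison,
#' letting the parameter penalty select the smallest adequate degree.
#'
#' @param records Trimmed empty-chamber records (at least `max_degree + 2`
#'   rows).
#' @param max_degree Largest polynomial degree considered (1 to 5).
#' @return An object of class `"empty_chamber_model"`: the selected `lm`
#'   fit, `degree`, `coefficients`, valid `range` of `CO2_r`, `rmse`, `n`
#'   and the per-degree `bic` table.
#' @export
fit_empty_model <- function(records, max_degree = 5) {
  if (max_degree < 1 || max_degree > 5)
    stop("`max_degree` must be between 1 and 5")
  n <- nrow(records)
  if (n < max_degree + 2)
    stop(sprintf("need at least %d rows to fit degree %d (have %d)",
                 max_degree + 2, max_degree, n))
  if (length(unique(records$CO2_r)) <= max_degree)
    stop("rank deficiency: too few distinct CO2_r values")
  fits <- lapply(seq_len(max_degree), function(d)
    lm(A ~ poly(CO2_r, d), data = records))
  rss <- vapply(fits, function(f) sum(f$residuals^2), 0)
  floor_rss <- n * (1e-10 * max(1, sd(records$A)))^2
  bic <- n * log(pmax(rss, floor_rss) / n) +
    (seq_len(max_degree) + 2) * log(n)
  degree <- which.min(bic)
  fit <- fits[[degree]]
  structure(list(fit = fit, degree = degree, coefficients = coef(fit),
                 range = range(records$CO2_r),
                 rmse = sqrt(rss[degree] / (n - degree - 1)), n = n,
                 bic = setNames(bic, paste0("degree", seq_len(max_degree)))),
            class = "empty_chamber_model")
}

#' Predict apparent assimilation from an empty-chamber model
#'
#' @param object An [fit_empty_model()] result.
#' @param C_ref Reference CO2 values (umol mol-1).
#' @param ... Unused.
#' @return Predicted apparent `A` (umol m-2 s-1).
#' @export
predict.empty_chamber_model <- function(object, C_ref, ...) {
  as.numeric(predict(object$fit, newdata = data.frame(CO2_r = C_ref)))
}

#' @export
print.empty_chamber_model <- function(x, ...) {
  cat(sprintf("Empty-chamber drift model: degree %d, n = %d, RMSE = %.4g\n",
              x$degree, x$n, x$rmse))
  cat(sprintf("  valid CO2_r range [%g, %g]\n", x$range[1], x$range[2]))
  invisible(x)
}

#' Apply an empty-chamber correction to a leaf run
#'
#' Subtracts the fitted apparent-assimilation drift from the leaf run's `A`
#' at matching reference CO2, then recomputes `Ci` from the corrected `A`
#' and the record's measured conductances through the uncorrected
#' (instrument) pathway — the cuticular-conductance recomputation is applied
#' later, at refitting time, so the two corrections stay orthogonal. Rows
#' whose `CO2_r` falls outside the model's valid range are flagged and get
#' `NA` corrected values; original columns are preserved alongside
#' `A_corrected`, `Ci_corrected` and `flag`.
#'
#' @param records Leaf gas-exchange records.
#' @param model An [fit_empty_model()] result.
#' @param g_bw Boundary-layer conductance used in the `Ci` recomputation.
#' @param K Adaxial:abaxial stomatal resistance ratio.
#' @return The records with `A_corrected`, `Ci_corrected`, `flag` columns.
#' @export
apply_correction <- function(records, model, g_bw = 2.23, K = 0) {
  if (!inherits(model, "empty_chamber_model"))
    stop("`model` must be an empty_chamber_model")
  out <- as.data.frame(records)
  in_range <- out$CO2_r >= model$range[1] & out$CO2_r <= model$range[2]
  out$A_corrected <- NA_real_
  out$A_corrected[in_range] <- out$A[in_range] -
    predict(model, out$CO2_r[in_range])
  out$Ci_corrected <- NA_real_
  usable <- in_range & out$gsw > 0
  if (any(usable))
    out$Ci_corrected[usable] <- intercellular_co2(
      out$A_corrected[usable], out$E[usable], out$Ca[usable],
      total_conductance_co2(out$gsw[usable], g_bw, K), quiet = TRUE)
  out$flag <- ifelse(in_range, "ok", "out_of_range")
  structure(out, class = c("gas_exchange_records", "data.frame"))
}
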