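# Treatment planning: convert the nucleus dose factor and the decay law
# into required activity concentrations, decay-corrected stock volumes,
# mean dose rates, and the volume-per-dose metric.

#' Reference nucleus dose factor, Gy per decay per ml
#'
#' The published Monte Carlo estimate of the mean absorbed dose to the
#' nucleus of an attached cell per Ra-223 cascade decay per ml of medium,
#' 2.198e-9 Gy/decay/ml, which [run_dosimetry()] reproduces to within its
#' Monte Carlo tolerance. Used as the default dose factor by the planner.
#'
#' @format A length-one numeric.
#' @export
ra223_reference_dose_factor <- 2.198e-9

# round half away from zero at `digits` decimals (printed-table convention)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Required initial activity concentration for a target nucleus dose
#'
#' Inverts the decay-integrated dose relation: an initial concentration
#' `A0` sustains `A0 * (1 - exp(-lambda*T)) / lambda` decays per ml over an
#' exposure of duration `T`, each contributing the dose factor `f`, so
#' `A0 = D / (f * (1 - exp(-lambda*T)) / lambda)`. Linear in the target
#' dose.
#'
#' @param dose_Gy Target mean nucleus dose, Gy (vectorised).
#' @param duration_h Exposure duration, hours.
#' @param dose_factor Nucleus dose factor, Gy per decay per ml
#'   (default [ra223_reference_dose_factor]).
#' @param law A [decay_law()].
#' @return Initial activity concentration in kBq per ml of medium.
#' @examples
#' required_activity(1, 24)    # ~5.4 kBq/ml
#' required_activity(1, 6)     # ~21.2 kBq/ml
#' @export
required_activity <- function(dose_Gy, duration_h,
                              dose_factor = ra223_reference_dose_factor,
                              law = decay_law()) {
  if (any(dose_Gy < 0) || any(duration_h <= 0)) {
    stop("dose must be non-negative and duration positive")
  }
  if (!is.numeric(dose_factor) || dose_factor <= 0) {
    stop("dose factor must be a positive number")
  }
  decays_per_Bq <- decays_in_interval(1, duration_h * 3600, law)
  dose_Gy / (dose_factor * decays_per_Bq) / 1000
}

#' Cumulative nucleus dose from an activity concentration
#'
#' Exact inverse of [required_activity()]: the mean nucleus dose delivered
#' by an initial concentration left to decay for the exposure duration.
#'
#' @param A0_kBq_per_ml Initial activity concentration, kBq/ml.
#' @inheritParams required_activity
#' @return Dose in Gy.
#' @export
cumulative_dose <- function(A0_kBq_per_ml, duration_h,
                            dose_factor = ra223_reference_dose_factor,
                            law = decay_law()) {
  if (any(A0_kBq_per_ml < 0) || any(duration_h < 0)) {
    stop("inputs must be non-negative")
  }
  A0_kBq_per_ml * 1000 * dose_factor *
    decays_in_interval(1, duration_h * 3600, law)
}

#' Mean dose rate of a protracted exposure
#'
#' @param dose_Gy Delivered dose, Gy.
#' @param duration_h Exposure duration, hours (> 0).
#' @return Mean dose rate in mGy/min.
#' @examples
#' mean_dose_rate(2, 24)  # ~1.4 mGy/min
#' @export
mean_dose_rate <- function(dose_Gy, duration_h) {
  if (any(duration_h <= 0)) stop("duration must be positive")
  dose_Gy * 1000 / (duration_h * 60)
}

#' Stock solution volume to reach a target activity concentration
#'
#' Decay-corrects the vial concentration (reference activity over vial
#' volume at the reference date) to the experiment date and converts the
#' required activity concentration into microlitres of stock per ml of
#' medium. Volumes above `flag_above_ul_per_ml` (default 25 ul/ml, the
#' practical cap per ml of medium) are flagged via the `"flagged"`
#' attribute.
#'
#' @param required_kBq_per_ml Required activity concentration, kBq per ml
#'   of medium (e.g. from [required_activity()]).
#' @param elapsed_days Days elapsed since the vial reference date.
#' @param vial_activity_MBq Vial activity at the reference date (default
#'   6.6 MBq).
#' @param vial_volume_ml Vial volume (default 6 ml).
#' @param law A [decay_law()].
#' @param flag_above_ul_per_ml Flag threshold, ul per ml of medium.
#' @return Volume in ul per ml of medium, with attribute `flagged`.
#' @examples
#' volume_to_add(1.1)                   # 1 ul/ml at reference date
#' volume_to_add(1.1, elapsed_days = 11.4)  # doubled after one half-life
#' @export
volume_to_add <- function(required_kBq_per_ml, elapsed_days = 0,
                          vial_activity_MBq = 6.6, vial_volume_ml = 6,
                          law = decay_law(), flag_above_ul_per_ml = 25) {
  if (any(required_kBq_per_ml < 0) || any(elapsed_days < 0)) {
    stop("inputs must be non-negative")
  }
  conc_MBq_per_ml <- vial_activity_MBq / vial_volume_ml *
    exp(-law$lambda_per_s * elapsed_days * 86400)
  # 1 MBq/ml stock = 1 kBq/ul
  vol <- required_kBq_per_ml / conc_MBq_per_ml
  flagged <- vol > flag_above_ul_per_ml
  if (any(flagged)) {
    warning(sprintf("required stock volume exceeds %g ul per ml of medium",
                    flag_above_ul_per_ml))
  }
  structure(vol, flagged = flagged)
}

#' Assemble a full treatment plan
#'
#' Combines the dose factor, decay law and vial description into the
#' quantities needed at the bench: required activity concentration, mean
#' dose rate, decay-corrected stock volume per ml of medium and in total,
#' and the volume-per-dose ratio `V / D_treat` (total stock volume added
#' divided by target dose), the covariate of the solution-volume toxicity
#' analysis.
#'
#' @param target_dose_Gy Target mean nucleus dose, Gy.
#' @param duration_h Exposure duration, hours.
#' @param elapsed_days Days since the vial reference date.
#' @param media_volume_ml Volume of culture medium treated, ml.
#' @inheritParams required_activity
#' @inheritParams volume_to_add
#' @return Object of class `treatment_plan`.
#' @examples
#' treatment_plan(0.5, 24)
#' @export
treatment_plan <- function(target_dose_Gy, duration_h, elapsed_days = 0,
                           media_volume_ml = 2,
                           dose_factor = ra223_reference_dose_factor,
                           vial_activity_MBq = 6.6, vial_volume_ml = 6,
                           law = decay_law()) {
  conc <- required_activity(target_dose_Gy, duration_h, dose_factor, law)
  vol_per_ml <- volume_to_add(conc, elapsed_days, vial_activity_MBq,
                              vial_volume_ml, law)
  total_vol <- as.numeric(vol_per_ml) * media_volume_ml
  structure(list(
    target_dose_Gy = target_dose_Gy,
    duration_h = duration_h,
    required_activity_kBq_per_ml = conc,
    mean_dose_rate_mGy_per_min = mean_dose_rate(target_dose_Gy, duration_h),
    elapsed_days = elapsed_days,
    vial_activity_MBq = vial_activity_MBq,
    vial_volume_ml = vial_volume_ml,
    media_volume_ml = media_volume_ml,
    volume_to_add_ul_per_ml = as.numeric(vol_per_ml),
    total_volume_ul = total_vol,
    v_over_d_ul_per_Gy = total_vol / target_dose_Gy,
    volume_flagged = any(attr(vol_per_ml, "flagged")),
    dose_factor = dose_factor),
    class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("Treatment plan: %.3g Gy over %g h (%.2f mGy/min)\n",
              x$target_dose_Gy, x$duration_h, x$mean_dose_rate_mGy_per_min))
  cat(sprintf("  required activity: %.3g kBq/ml of medium\n",
              x$required_activity_kBq_per_ml))
  cat(sprintf("  stock volume: %.3g ul per ml (%.3g ul total in %g ml), V/D = %.3g ul/Gy%s\n",
              x$volume_to_add_ul_per_ml, x$total_volume_ul,
              x$media_volume_ml, x$v_over_d_ul_per_Gy,
              if (x$volume_flagged) " [volume flag]" else ""))
  invisible(x)
}

#' Grid of required activities by dose and exposure time
#'
#' Regenerates the planning grid of initial activity concentrations
#' (kBq/ml) over target doses and exposure durations, rounded half away
#' from zero to `digits` decimals as in printed planning tables.
#'
#' @param doses_Gy Target doses, Gy.
#' @param durations_h Exposure durations, hours.
#' @param digits Decimals for rounding (default 1); `NULL` for unrounded.
#' @inheritParams required_activity
#' @return Data frame with one row per duration and one column per dose.
#' @export
activity_table <- function(doses_Gy = c(0.05, 0.1, 0.25, 0.5, 1, 2),
                           durations_h = c(6, 24),
                           dose_factor = ra223_reference_dose_factor,
                           law = decay_law(), digits = 1) {
  grid <- outer(durations_h, doses_Gy,
                function(T, D) required_activity(D, T, dose_factor, law))
  if (!is.null(digits)) grid <- round_half_up(grid, digits)
  out <- data.frame(duration_h = durations_h, grid)
  names(out)[-1] <- paste0("Gy_", doses_Gy)
  out
}

#' Published planning-grid reference values
#'
#' The printed reference grid of initial activities (kBq/ml) for doses
#' 0.05-2 Gy at 6 and 24 h exposures, used to validate
#' [activity_table()]. Two cells of the printed grid differ by one unit in
#' the last decimal from the closed-form recomputation (rounding of
#' intermediate values in the original); the remaining ten agree exactly.
#'
#' @return Data frame in the layout of [activity_table()].
#' @export
reference_activity_table <- function() {
  out <- data.frame(duration_h = c(6, 24),
                    rbind(c(1.0, 2.1, 5.3, 10.6, 21.2, 42.4),
                          c(0.3, 0.5, 1.4, 2.7, 5.4, 10.8)))
  names(out)[-1] <- paste0("Gy_", c(0.05, 0.1, 0.25, 0.5, 1, 2))
  out
}
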