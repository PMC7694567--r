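#' Detect stance phases from plantar forefoot force
#'
#' A sample is in stance exactly when its forefoot force exceeds the
#' threshold; stance intervals are maximal runs of such samples. An
#' optional debounce drops stance runs shorter than `debounce_s`, rejecting
#' sensor chatter near the threshold.
#'
#' `detect_stance()` is the data-frame verb: it adds a logical `stance`
#' column per limb to a gait trial. `stance_intervals()` is the vector
#' workhorse returning the intervals themselves.
#'
#' @param trial A gait-trial tibble with `time_s`, `limb`, `force_n`.
#' @param threshold Force threshold in N (>= 0).
#' @param debounce_s Minimum stance duration in s (0 disables); needs the
#'   trial's `sample_rate` attribute or the `sample_rate` argument.
#' @param sample_rate Sampling rate in Hz, used only for the debounce.
#' @return `detect_stance()`: the trial with a `stance` column.
#'   `stance_intervals()`: a tibble with `start`, `end` (sample indices,
#'   inclusive) of each stance interval.
#' @examples
#' trial <- generate_gait_trial(participant_profile(), duration = 5, seed = 1)
#' trial <- detect_stance(trial, threshold = 10)
#' stance_intervals(trial$force_n[trial$limb == "left"], threshold = 10)
#' @export
detect_stance <- function(trial, threshold = 10, debounce_s = 0.1,
                          sample_rate = attr(trial, "sample_rate")) {
  check_columns(trial, c("time_s", "limb", "force_n"), "trial")
  if (nrow(trial) == 0L) stop_invalid("`trial` has no samples.")
  check_number(threshold, "threshold", min = 0)
  min_samples <- debounce_samples(debounce_s, sample_rate)
  out <- trial %>%
    group_by(.data$limb) %>%
    mutate(stance = stance_flags(.data$force_n, threshold, min_samples)) %>%
    ungroup()
  for (a in c("sample_rate", "lever_arm", "base_peak_nm")) {
    attr(out, a) <- attr(trial, a)
  }
  out
}

#' @rdname detect_stance
#' @param force_n Nonnegative forefoot-force vector, N.
#' @export
stance_intervals <- function(force_n, threshold = 10, debounce_s = 0,
                             sample_rate = NULL) {
  check_numeric_vector(force_n, "force_n")
  check_number(threshold, "threshold", min = 0)
  min_samples <- debounce_samples(debounce_s, sample_rate)
  flags <- stance_flags(force_n, threshold, min_samples)
  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  tibble(start = starts[keep], end = ends[keep])
}

debounce_samples <- function(debounce_s, sample_rate) {
  if (is.null(debounce_s) || debounce_s <= 0) return(1L)
  if (is.null(sample_rate)) {
    warn("No `sample_rate` available; stance debounce disabled.")
    return(1L)
  }
  max(1L, as.integer(ceiling(debounce_s * sample_rate)))
}

stance_flags <- function(force_n, threshold, min_samples = 1L) {
  if (any(force_n < 0)) stop_invalid("forefoot force must be >= 0.")
  flags <- force_n > threshold
  if (min_samples > 1L) {
    runs <- rle(flags)
    runs$values[runs$values & runs$lengths < min_samples] <- FALSE
    flags <- inverse.rle(runs)
  }
  flags
}

#' Estimate ankle moment from forefoot force
#'
#' The wearable device has no joint torque measurement of the biological
#' ankle; it estimates the plantar-flexion moment from the force under the
#' forefoot through a fixed effective lever arm:
#' `moment = force * lever_arm`. Only the ratio of this estimate to its
#' calibrated peak enters the controller, so the lever arm cancels from
#' the commanded torque.
#'
#' @param force_n Nonnegative forefoot force, N (vectorised).
#' @param lever_arm Effective lever arm, m (> 0).
#' @return Estimated ankle moment(s), Nm.
#' @examples
#' estimate_ankle_moment(100, lever_arm = 0.15) # 15 Nm
#' @export
estimate_ankle_moment <- function(force_n, lever_arm = 0.15) {
  check_numeric_vector(force_n, "force_n", min = 0)
  check_number(lever_arm, "lever_arm", min = 0, strict_min = TRUE)
  force_n * lever_arm
}

#' Calibrate the average peak ankle moment while walking
#'
#' The calibration bout every user performs before training: detect stance
#' intervals per limb, take the maximum estimated ankle moment within each
#' interval (one peak per stride), and average the peaks. The result is
#' the per-limb reference `M_peak` against which the controller normalises
#' the instantaneous moment estimate.
#'
#' @inheritParams detect_stance
#' @param lever_arm Effective lever arm, m, for the moment estimate.
#' @return A tibble with one row per limb: `limb`, `mean_peak_moment_nm`,
#'   `strides_used`.
#' @examples
#' trial <- generate_gait_trial(participant_profile(), duration = 30, seed = 1)
#' calibrate_peak_moment(trial)
#' @export
calibrate_peak_moment <- function(trial, threshold = 10, debounce_s = 0.1,
                                  lever_arm = 0.15,
                                  sample_rate = attr(trial, "sample_rate")) {
  check_columns(trial, c("time_s", "limb", "force_n"), "trial")
  min_samples <- debounce_samples(debounce_s, sample_rate)
  out <- trial %>%
    group_by(.data$limb) %>%
    summarise(
      res = list(limb_peaks(.data$force_n, threshold, min_samples,
                            lever_arm)),
      .groups = "drop"
    ) %>%
    tidyr::unnest("res")
  if (any(out$strides_used < 1L)) {
    abort(
      sprintf("Calibration failed: no stance intervals on limb(s) %s.",
              paste(out$limb[out$strides_used < 1L], collapse = ", ")),
      class = "exoresist_calibration_failure"
    )
  }
  out
}

limb_peaks <- function(force_n, threshold, min_samples, lever_arm) {
  flags <- stance_flags(force_n, threshold, min_samples)
  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  peaks <- vapply(keep, function(i) {
    max(estimate_ankle_moment(force_n[starts[i]:ends[i]], lever_arm))
  }, numeric(1))
  tibble(
    mean_peak_moment_nm = if (length(peaks)) mean(peaks) else NA_real_,
    strides_used = length(peaks)
  )
}

#' Proportional resistance torque command
#'
#' The heart of the adaptive resistance scheme: the prescribed resistance
#' level `r` (Nm/kg) is applied in proportion to the instantaneous
#' estimated ankle moment expressed as a fraction of the calibrated peak,
#' clipped to \[0, 1\]:
#' `tau_nmkg = r * min(max(fraction, 0), 1)`. At 100 % of the calibrated
#' peak (late stance) the full `r` is commanded; at 50 % (early stance)
#' half of it; during swing (0 %) nothing.
#'
#' @param moment_fraction Instantaneous estimated moment divided by the
#'   calibrated peak (unitless, vectorised; values outside \[0, 1\] clip).
#' @param resistance Prescribed resistance level `r`, Nm/kg (>= 0).
#' @param body_mass Optional body mass, kg; when supplied the absolute
#'   torque `tau_nm = tau_nmkg * body_mass` is returned instead.
#' @return Commanded torque, Nm/kg (or Nm when `body_mass` is given).
#' @examples
#' compute_resistance_torque(c(1, 0.5, 0), resistance = 0.1)
#' @export
compute_resistance_torque <- function(moment_fraction, resistance,
                                      body_mass = NULL) {
  if (!is.numeric(moment_fraction) || anyNA(moment_fraction)) {
    stop_invalid("`moment_fraction` must be numeric with no missing values.")
  }
  check_number(resistance, "resistance", min = 0)
  tau <- resistance * pmin(pmax(moment_fraction, 0), 1)
  if (!is.null(body_mass)) {
    check_number(body_mass, "body_mass", min = 0, strict_min = TRUE)
    tau <- tau * body_mass
  }
  tau
}

#' Run the resistance controller over a walking bout
#'
#' Simulates one training bout sample by sample: stance is detected from
#' the forefoot force, the ankle moment is estimated through the lever
#' arm, normalised by the calibrated per-limb peak, and converted to the
#' commanded resistance torque. The output at sample `k` depends only on
#' sample `k`'s force and the static calibration — a pointwise threshold
#' with no run-length debounce, because the real-time device cannot look
#' ahead to know how long a force burst will last. (Offline stance
#' analysis via [detect_stance()] may debounce; the controller itself
#' must stay causal.) Swing samples command exactly zero torque.
#'
#' @inheritParams detect_stance
#' @param calibration A `calibrate_peak_moment()` result covering every
#'   limb present in `trial`.
#' @param resistance Prescribed resistance level, Nm/kg (>= 0).
#' @param body_mass Body mass, kg (> 0).
#' @param lever_arm Effective lever arm, m.
#' @param engagement_tolerance Fraction of the prescription a stride peak
#'   must reach to count as engaged (see [engagement_fraction()]).
#' @return An object of class `exo_session`: list with `torque` (tibble:
#'   `time_s`, `limb`, `stance`, `tau_nmkg`, `tau_nm`), `stride_peaks`
#'   (tibble: `limb`, `stride`, `peak_tau_nm`), and the parameters.
#' @examples
#' trial <- generate_gait_trial(participant_profile(), duration = 20, seed = 1)
#' cal <- calibrate_peak_moment(trial)
#' sess <- run_session(trial, cal, resistance = 0.1, body_mass = 50)
#' head(tidy(sess))
#' @export
run_session <- function(trial, calibration, resistance, body_mass,
                        threshold = 10, lever_arm = 0.15,
                        engagement_tolerance = 0.95) {
  check_columns(trial, c("time_s", "limb", "force_n"), "trial")
  check_columns(calibration, c("limb", "mean_peak_moment_nm"), "calibration")
  check_number(resistance, "resistance", min = 0)
  check_number(body_mass, "body_mass", min = 0, strict_min = TRUE)
  limbs <- unique(trial$limb)
  if (!all(limbs %in% calibration$limb)) {
    abort(
      sprintf("Calibration lacks limb(s): %s.",
              paste(setdiff(limbs, calibration$limb), collapse = ", ")),
      class = "exoresist_configuration_error"
    )
  }
  torque <- trial %>%
    left_join(select(calibration, "limb", "mean_peak_moment_nm"),
              by = "limb") %>%
    group_by(.data$limb) %>%
    mutate(stance = stance_flags(.data$force_n, threshold, 1L)) %>%
    ungroup() %>%
    mutate(
      fraction = estimate_ankle_moment(.data$force_n, lever_arm) /
        .data$mean_peak_moment_nm,
      tau_nmkg = ifelse(
        .data$stance,
        compute_resistance_torque(.data$fraction, resistance), 0
      ),
      tau_nm = .data$tau_nmkg * body_mass
    ) %>%
    select("time_s", "limb", "stance", "tau_nmkg", "tau_nm")

  stride_peaks <- torque %>%
    group_by(.data$limb) %>%
    summarise(res = list(stride_peak_torques(.data$stance, .data$tau_nm)),
              .groups = "drop") %>%
    tidyr::unnest("res")

  structure(
    list(
      torque = torque,
      stride_peaks = stride_peaks,
      resistance = resistance,
      body_mass = body_mass,
      prescribed_nm = resistance * body_mass,
      engagement_tolerance = engagement_tolerance
    ),
    class = "exo_session"
  )
}

stride_peak_torques <- function(stance, tau_nm) {
  runs <- rle(stance)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  tibble(
    stride = seq_along(keep),
    peak_tau_nm = vapply(keep, function(i) max(tau_nm[starts[i]:ends[i]]),
                         numeric(1))
  )
}

#' @export
print.exo_session <- function(x, ...) {
  cat(sprintf(
    "<exo_session> r = %.3f Nm/kg (%.2f Nm at %.1f kg), %d strides, %d samples\n",
    x$resistance, x$prescribed_nm, x$body_mass,
    nrow(x$stride_peaks), nrow(x$torque)
  ))
  invisible(x)
}

#' @method tidy exo_session
#' @export
tidy.exo_session <- function(x, ...) x$stride_peaks

#' @method glance exo_session
#' @export
glance.exo_session <- function(x, ...) {
  tibble(
    resistance_nmkg = x$resistance,
    prescribed_nm = x$prescribed_nm,
    n_strides = nrow(x$stride_peaks),
    engagement = engagement_fraction(x$stride_peaks$peak_tau_nm,
                                     x$prescribed_nm,
                                     x$engagement_tolerance)
  )
}
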