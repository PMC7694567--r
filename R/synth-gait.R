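#' Simulate a bilateral walking bout with plantar force and ankle moment
#'
#' Generates a quasi-periodic gait trial: each limb alternates stance and
#' swing at the configured cadence, and within every stance phase the
#' biological plantar-flexion ankle moment follows a smooth single-peak
#' profile with its maximum in late stance (default at 75 % of stance,
#' where push-off torque peaks). Forefoot force is generated coherently as
#' `moment / lever_arm`, matching how the wearable device estimates ankle
#' moment from a force sensor under the forefoot. Stride-to-stride peak
#' variability is log-normal with unit mean, and the more-affected limb's
#' peaks are scaled by the profile's asymmetry ratio.
#'
#' @param profile A `participant_profile()` row.
#' @param duration Bout length in s (> 0).
#' @param cadence Total step rate, steps/min across both limbs (> 0); each
#'   limb completes `cadence / 2` strides per minute.
#' @param sample_rate Sampling rate in Hz (>= 50).
#' @param seed Integer seed; the trial is a pure function of its arguments.
#' @param stance_fraction Fraction of the stride spent in stance (0.6 is
#'   typical of walking).
#' @param peak_cv Stride-to-stride coefficient of variation of the peak
#'   moment (log-normal, mean-one).
#' @param peak_time Location of the moment peak as a fraction of stance.
#' @param lever_arm Effective forefoot-to-ankle lever arm in m (> 0).
#'
#' @return A tibble with columns `time_s`, `limb` (`"left"`/`"right"`),
#'   `force_n`, `moment_nm`, plus attributes `sample_rate`, `lever_arm`,
#'   and `base_peak_nm` (named per-limb expected peak moment, Nm).
#' @examples
#' trial <- generate_gait_trial(participant_profile(), duration = 10, seed = 1)
#' dplyr::count(trial, limb)
#' @export
generate_gait_trial <- function(profile,
                                duration = 60,
                                cadence = 100,
                                sample_rate = 100,
                                seed = 1,
                                stance_fraction = 0.6,
                                peak_cv = 0.1,
                                peak_time = 0.75,
                                lever_arm = 0.15) {
  check_columns(profile, c("body_mass", "more_affected", "asymmetry",
                           "peak_moment_nmkg"), "profile")
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  check_number(cadence, "cadence", min = 0, strict_min = TRUE)
  check_number(sample_rate, "sample_rate", min = 50)
  check_number(stance_fraction, "stance_fraction", min = 0, max = 1,
               strict_min = TRUE, strict_max = TRUE)
  check_number(peak_time, "peak_time", min = 0, max = 1,
               strict_min = TRUE, strict_max = TRUE)
  check_number(lever_arm, "lever_arm", min = 0, strict_min = TRUE)
  check_number(peak_cv, "peak_cv", min = 0)

  stride_period <- 120 / cadence # s per limb stride (cadence counts steps)
  time_s <- seq(0, duration, by = 1 / sample_rate)
  base_peak <- profile$peak_moment_nmkg * profile$body_mass
  peaks_nm <- c(left = base_peak, right = base_peak)
  peaks_nm[[profile$more_affected]] <-
    peaks_nm[[profile$more_affected]] * profile$asymmetry
  # right limb strides half a period out of phase with the left
  offsets <- c(left = 0, right = stride_period / 2)

  limb_trace <- function(limb, seed) {
    withr::with_seed(seed, {
      n_strides <- ceiling(duration / stride_period) + 2L
      # mean-one log-normal stride peaks: E[exp(N(-s^2/2, s^2))] = 1
      slog <- sqrt(log(1 + peak_cv^2))
      mult <- rlnorm(n_strides, meanlog = -slog^2 / 2, sdlog = slog)
      starts <- (seq_len(n_strides) - 1) * stride_period + offsets[[limb]] -
        stride_period
      stance_len <- stance_fraction * stride_period
      moment <- numeric(length(time_s))
      for (k in seq_len(n_strides)) {
        s <- (time_s - starts[k]) / stance_len
        inside <- s > 0 & s < 1
        if (!any(inside)) next
        moment[inside] <- peaks_nm[[limb]] * mult[k] *
          stance_moment_shape(s[inside], peak_time)
      }
      tibble(
        time_s = time_s,
        limb = limb,
        force_n = moment / lever_arm,
        moment_nm = moment
      )
    })
  }

  out <- bind_rows(
    limb_trace("left", split_seed(seed, "gait-left")),
    limb_trace("right", split_seed(seed, "gait-right"))
  )
  attr(out, "sample_rate") <- sample_rate
  attr(out, "lever_arm") <- lever_arm
  attr(out, "base_peak_nm") <- peaks_nm
  out
}

# Smooth unimodal stance profile on (0, 1), zero at both ends, maximum 1 at
# `peak_time`: a beta-kernel s^a (1-s)^b with the exponents chosen so the
# mode sits at peak_time while keeping the ascent gentle (a + b = 4).
stance_moment_shape <- function(s, peak_time = 0.75) {
  a <- 4 * peak_time
  b <- 4 - a
  (s^a * (1 - s)^b) / (peak_time^a * (1 - peak_time)^b)
}
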