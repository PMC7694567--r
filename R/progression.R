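#' Fraction of strides that reached the prescribed resistance
#'
#' Engagement with the resistance is tracked per gait cycle: a stride
#' counts as engaged when its peak applied torque reaches at least
#' `tolerance` times the prescribed absolute resistance. Because the
#' applied torque saturates at the prescription exactly when the
#' biological moment reaches its calibrated peak, this equals the fraction
#' of strides whose biological peak reached `tolerance * M_peak`.
#'
#' @param peak_tau_nm Per-stride peak applied torque, Nm (>= 1 stride).
#' @param prescribed_nm Prescribed absolute resistance, Nm (> 0).
#' @param tolerance Fraction of the prescription that counts as reached.
#' @return Engagement fraction in \[0, 1\].
#' @examples
#' engagement_fraction(c(5, 4.9, 3.0), prescribed_nm = 5) # 2/3
#' @export
engagement_fraction <- function(peak_tau_nm, prescribed_nm,
                                tolerance = 0.95) {
  check_numeric_vector(peak_tau_nm, "peak_tau_nm")
  check_number(prescribed_nm, "prescribed_nm", min = 0, strict_min = TRUE)
  check_number(tolerance, "tolerance", min = 0, max = 1)
  mean(peak_tau_nm >= tolerance * prescribed_nm)
}

#' Advance the resistance prescription by one session
#'
#' The training-progression rule: resistance increases by a fixed
#' increment of 0.5–1 Nm for the next session only when the participant
#' both (1) reached the prescribed level of resistance on more than half
#' of the session and (2) reported soreness no worse than Moderate.
#' Otherwise the prescription is unchanged.
#'
#' @param resistance_nm Current prescription, Nm (>= 0).
#' @param engagement Fraction of the session at the prescription, \[0, 1\].
#' @param soreness A level of [soreness_levels()].
#' @param increment_nm Per-session increment, Nm; must lie in \[0.5, 1\].
#' @param body_mass Optional body mass, kg, to also report Nm/kg.
#' @return A one-row tibble: `resistance_nm`, `increased`, and
#'   `resistance_nmkg` when `body_mass` is given.
#' @examples
#' next_resistance(4, engagement = 0.6, soreness = "Moderate")
#' next_resistance(4, engagement = 0.9, soreness = "Severe")
#' @export
next_resistance <- function(resistance_nm, engagement, soreness,
                            increment_nm = 0.75, body_mass = NULL) {
  check_number(resistance_nm, "resistance_nm", min = 0)
  check_number(engagement, "engagement", min = 0, max = 1)
  check_number(increment_nm, "increment_nm", min = 0.5, max = 1)
  rank <- soreness_rank(soreness)
  increased <- engagement > 0.5 && rank <= soreness_rank("Moderate")
  new_nm <- resistance_nm + if (increased) increment_nm else 0
  out <- tibble(resistance_nm = new_nm, increased = increased)
  if (!is.null(body_mass)) {
    check_number(body_mass, "body_mass", min = 0, strict_min = TRUE)
    out$resistance_nmkg <- new_nm / body_mass
  }
  out
}

#' Simulate a full training course of resistance sessions
#'
#' Chains the whole training loop for one participant: each visit
#' generates a walking bout, recalibrates the peak ankle moment on a short
#' calibration bout, runs the proportional controller at the current
#' prescription, scores per-stride engagement, draws an ordinal soreness
#' response from the session dose, and applies the progression rule to set
#' the next visit's resistance. Every session is 20 minutes of walking
#' (the protocol's dose); the simulated bout is a shorter representative
#' sample of strides.
#'
#' @param profile A `participant_profile()` row.
#' @param start_r Initial resistance, Nm/kg; the protocol starts in
#'   \[0.025, 0.075\] and values outside it draw a warning (not an error).
#' @param sessions Number of training visits (default 10).
#' @param seed Integer seed; the course is a pure function of its inputs.
#' @param increment_nm Per-session increment, Nm, in \[0.5, 1\].
#' @param bout_duration Simulated bout length per visit, s.
#' @param walk_minutes Protocol walking dose per visit, min.
#' @param cadence,sample_rate,peak_cv Passed to [generate_gait_trial()].
#' @param engagement_tolerance Stride-level tolerance for
#'   [engagement_fraction()].
#' @param soreness_override Optional fixed soreness level (a value of
#'   [soreness_levels()]) reported at every visit instead of the
#'   stochastic response — useful for protocol what-ifs (e.g. how the
#'   progression behaves if every session ends Very Severe).
#' @return A tibble of session records with class `exo_training_course`:
#'   `visit`, `resistance_nmkg`, `resistance_nm`, `engagement`,
#'   `soreness`, `walk_min`.
#' @examples
#' course <- simulate_training_course(participant_profile(), seed = 5,
#'                                    bout_duration = 20)
#' course
#' @export
simulate_training_course <- function(profile,
                                     start_r = 0.05,
                                     sessions = 10,
                                     seed = 1,
                                     increment_nm = 0.75,
                                     bout_duration = 60,
                                     walk_minutes = 20,
                                     cadence = 100,
                                     sample_rate = 100,
                                     peak_cv = 0.1,
                                     engagement_tolerance = 0.95,
                                     soreness_override = NULL) {
  check_columns(profile, c("id", "body_mass", "soreness_propensity"),
                "profile")
  check_number(start_r, "start_r", min = 0)
  if (start_r < 0.025 || start_r > 0.075) {
    warn(sprintf(
      "`start_r` = %g Nm/kg is outside the documented 0.025-0.075 Nm/kg starting range.",
      start_r
    ))
  }
  if (!is.numeric(sessions) || length(sessions) != 1L || sessions < 0) {
    stop_invalid("`sessions` must be a single number >= 0.")
  }
  check_number(increment_nm, "increment_nm", min = 0.5, max = 1)

  mass <- profile$body_mass
  r_nm <- start_r * mass
  records <- vector("list", sessions)
  for (visit in seq_len(sessions)) {
    cal_trial <- generate_gait_trial(
      profile, duration = bout_duration, cadence = cadence,
      sample_rate = sample_rate, peak_cv = peak_cv,
      seed = split_seed(seed, sprintf("visit%02d-cal", visit))
    )
    calibration <- calibrate_peak_moment(cal_trial,
                                         sample_rate = sample_rate)
    trial <- generate_gait_trial(
      profile, duration = bout_duration, cadence = cadence,
      sample_rate = sample_rate, peak_cv = peak_cv,
      seed = split_seed(seed, sprintf("visit%02d-walk", visit))
    )
    sess <- run_session(trial, calibration,
                        resistance = r_nm / mass, body_mass = mass,
                        engagement_tolerance = engagement_tolerance)
    engagement <- engagement_fraction(sess$stride_peaks$peak_tau_nm,
                                      sess$prescribed_nm,
                                      engagement_tolerance)
    soreness <- if (is.null(soreness_override)) {
      generate_soreness(
        r_nm, engagement, profile$soreness_propensity,
        seed = split_seed(seed, sprintf("visit%02d-sore", visit))
      )
    } else {
      soreness_levels()[soreness_rank(soreness_override) + 1L]
    }
    records[[visit]] <- tibble(
      visit = visit,
      resistance_nmkg = r_nm / mass,
      resistance_nm = r_nm,
      engagement = engagement,
      soreness = soreness,
      walk_min = walk_minutes
    )
    r_nm <- next_resistance(r_nm, engagement, soreness,
                            increment_nm = increment_nm)$resistance_nm
  }
  out <- bind_rows(records)
  class(out) <- c("exo_training_course", class(out))
  attr(out, "participant") <- profile$id
  out
}
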