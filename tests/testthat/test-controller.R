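test_that("stance detection follows the threshold definition exactly", {
  expect_identical(nrow(stance_intervals(rep(0, 100), threshold = 10)), 0L)
  sq <- rep(c(0, 100), each = 50, times = 3)
  iv <- stance_intervals(sq, threshold = 10)
  expect_equal(iv$start, c(51, 151, 251))
  expect_equal(iv$end, c(100, 200, 300))
  expect_error(stance_intervals(numeric(0), threshold = 10),
               class = "exoresist_invalid_argument")
})

test_that("stance-interval count matches the generator's cadence", {
  p <- participant_profile()
  trial <- generate_gait_trial(p, duration = 60, cadence = 100, seed = 4)
  trial <- detect_stance(trial, threshold = 10)
  # cadence 100 steps/min over 60 s -> 50 strides per limb
  for (l in c("left", "right")) {
    f <- trial$force_n[trial$limb == l]
    n_iv <- nrow(stance_intervals(f, threshold = 10, debounce_s = 0.1,
                                  sample_rate = 100))
    expect_lte(abs(n_iv - 50), 1)
  }
  expect_identical(trial$stance, trial$force_n > 10)
})

test_that("moment estimation is a lever-arm proportionality", {
  expect_identical(estimate_ankle_moment(0, 0.15), 0)
  expect_equal(estimate_ankle_moment(100, 0.15), 15)
  expect_error(estimate_ankle_moment(-5, 0.15),
               class = "exoresist_invalid_argument")
  expect_error(estimate_ankle_moment(10, 0),
               class = "exoresist_invalid_argument")
  # estimated and ground-truth moments peak on the same samples
  trial <- generate_gait_trial(participant_profile(), duration = 20, seed = 6)
  f <- trial$force_n[trial$limb == "left"]
  m <- trial$moment_nm[trial$limb == "left"]
  est <- estimate_ankle_moment(f, attr(trial, "lever_arm"))
  expect_lte(abs(which.max(est) - which.max(m)), 2)
})

test_that("calibration averages per-stride peak moments", {
  # constant stride peaks: mean peak equals the common value
  tr1 <- square_trial(peaks_n = rep(40 / 0.15, 5))
  cal1 <- calibrate_peak_moment(tr1, threshold = 10, lever_arm = 0.15,
                                sample_rate = 100)
  expect_equal(cal1$mean_peak_moment_nm, c(40, 40))
  expect_equal(cal1$strides_used, c(5L, 5L))
  # three strides with peaks 1.0 / 1.2 / 1.4 Nm -> mean 1.2 Nm
  tr2 <- square_trial(peaks_n = c(1.0, 1.2, 1.4) / 0.15)
  cal2 <- calibrate_peak_moment(tr2, threshold = 0.5, lever_arm = 0.15,
                                sample_rate = 100)
  expect_equal(cal2$mean_peak_moment_nm, c(1.2, 1.2))
  # no stance at all -> calibration failure
  tr3 <- square_trial(peaks_n = 5)
  expect_error(calibrate_peak_moment(tr3, threshold = 100,
                                     sample_rate = 100),
               class = "exoresist_calibration_failure")
})

test_that("calibration recovers the generator's configured peak within 3%", {
  p <- participant_profile(affected_side = "left", asymmetry = 0.8,
                           body_mass = 50, peak_moment_nmkg = 1)
  trial <- generate_gait_trial(p, duration = 120, seed = 9, peak_cv = 0.1)
  cal <- calibrate_peak_moment(trial)
  base <- attr(trial, "base_peak_nm")
  for (l in c("left", "right")) {
    got <- cal$mean_peak_moment_nm[cal$limb == l]
    expect_equal(got, unname(base[[l]]), tolerance = 0.03)
  }
})

test_that("torque command reproduces the proportional worked example", {
  expect_identical(compute_resistance_torque(1.0, resistance = 0.1), 0.1)
  expect_identical(compute_resistance_torque(0.5, resistance = 0.1), 0.05)
  expect_identical(compute_resistance_torque(0.0, resistance = 0.1), 0)
  # fractions beyond the calibrated peak clip to the prescription
  expect_identical(compute_resistance_torque(1.7, resistance = 0.1), 0.1)
  expect_equal(compute_resistance_torque(0.5, 0.1, body_mass = 50), 2.5)
})

test_that("torque command is monotone in the fraction and linear in r", {
  withr::with_seed(13, {
    for (i in 1:20) {
      f <- sort(runif(50, -0.2, 1.5))
      tau <- compute_resistance_torque(f, resistance = 0.1)
      expect_true(all(diff(tau) >= 0))
      expect_true(all(tau >= 0 & tau <= 0.1))
      expect_equal(compute_resistance_torque(f, resistance = 0.2), 2 * tau)
    }
  })
})

test_that("controller session clips, gates swing to zero, and is causal", {
  p <- participant_profile()
  trial <- generate_gait_trial(p, duration = 30, seed = 10, peak_cv = 0.2)
  cal <- calibrate_peak_moment(trial)
  sess <- run_session(trial, cal, resistance = 0.1, body_mass = 50)
  expect_true(all(sess$torque$tau_nm >= 0))
  expect_true(all(sess$torque$tau_nm <= 0.1 * 50 + 1e-12))
  expect_true(all(sess$torque$tau_nm[!sess$torque$stance] == 0))
  # zero prescription -> zero torque everywhere
  sess0 <- run_session(trial, cal, resistance = 0, body_mass = 50)
  expect_true(all(sess0$torque$tau_nm == 0))
  # causality: outputs over the first k samples are unchanged when the
  # future of the bout is removed
  cut <- dplyr::filter(trial, time_s <= 10)
  sess_cut <- run_session(cut, cal, resistance = 0.1, body_mass = 50)
  full_head <- dplyr::filter(sess$torque, time_s <= 10)
  expect_equal(full_head$tau_nm, sess_cut$torque$tau_nm)
})

test_that("a noiseless bout reaches the prescription on every full stride", {
  p <- participant_profile()
  trial <- generate_gait_trial(p, duration = 30, seed = 2, peak_cv = 0)
  cal <- calibrate_peak_moment(trial)
  sess <- run_session(trial, cal, resistance = 0.1, body_mass = 50)
  interior <- sess$stride_peaks %>%
    dplyr::group_by(limb) %>%
    dplyr::filter(stride > min(stride), stride < max(stride)) %>%
    dplyr::ungroup()
  expect_equal(interior$peak_tau_nm, rep(5, nrow(interior)),
               tolerance = 1e-9)
})

test_that("stride engagement equals the biological-peak criterion", {
  p <- participant_profile()
  trial <- generate_gait_trial(p, duration = 60, seed = 15, peak_cv = 0.2)
  cal_trial <- generate_gait_trial(p, duration = 60, seed = 16, peak_cv = 0.2)
  cal <- calibrate_peak_moment(cal_trial)
  sess <- run_session(trial, cal, resistance = 0.1, body_mass = 50)
  reached <- engagement_fraction(sess$stride_peaks$peak_tau_nm,
                                 sess$prescribed_nm, tolerance = 0.95)
  # ground truth: strides whose biological peak moment reached 95% of the
  # calibrated peak
  bio <- trial %>%
    dplyr::group_by(limb) %>%
    dplyr::summarise(
      frac = {
        iv <- stance_intervals(force_n, threshold = 10)
        peaks <- vapply(seq_len(nrow(iv)), function(i) {
          max(moment_nm[iv$start[i]:iv$end[i]])
        }, numeric(1))
        mp <- cal$mean_peak_moment_nm[cal$limb == limb[1]]
        list(peaks >= 0.95 * mp)
      }
    )
  truth <- mean(unlist(bio$frac))
  expect_equal(reached, truth, tolerance = 1e-12)
})

test_that("session demands a calibration covering every limb", {
  trial <- generate_gait_trial(participant_profile(), duration = 10, seed = 1)
  cal <- calibrate_peak_moment(trial)
  expect_error(
    run_session(trial, cal[cal$limb == "left", ], 0.1, 50),
    class = "exoresist_configuration_error"
  )
})
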