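test_that("gait trials are deterministic in the seed and differ across seeds", {
  p <- participant_profile()
  a <- generate_gait_trial(p, duration = 10, seed = 7)
  b <- generate_gait_trial(p, duration = 10, seed = 7)
  c <- generate_gait_trial(p, duration = 10, seed = 8)
  expect_identical(a$force_n, b$force_n)
  expect_identical(a$moment_nm, b$moment_nm)
  expect_false(identical(a$moment_nm, c$moment_nm))
})

test_that("gait force is nonnegative, zero in swing, and force/moment are coherent", {
  p <- participant_profile()
  trial <- generate_gait_trial(p, duration = 30, seed = 1,
                               stance_fraction = 0.6, lever_arm = 0.15)
  expect_true(all(trial$force_n >= 0))
  # swing occupies the zero-force samples; stance fraction ~60% of the bout
  for (l in c("left", "right")) {
    f <- trial$force_n[trial$limb == l]
    expect_equal(mean(f > 0), 0.6, tolerance = 0.05)
  }
  expect_equal(trial$moment_nm, trial$force_n * 0.15)
})

test_that("limb asymmetry scales the more-affected limb's mean peak moment", {
  peak_means <- function(asym, seed) {
    p <- participant_profile(affected_side = "left", asymmetry = asym,
                             body_mass = 50, peak_moment_nmkg = 1)
    trial <- generate_gait_trial(p, duration = 120, seed = seed)
    sapply(c("left", "right"), function(l) {
      f <- trial$force_n[trial$limb == l]
      iv <- stance_intervals(f, threshold = 10)
      mean(vapply(seq_len(nrow(iv)), function(i) {
        max(f[iv$start[i]:iv$end[i]]) * 0.15
      }, numeric(1)))
    })
  }
  sym <- peak_means(1.0, seed = 3)
  expect_equal(unname(sym["left"] / sym["right"]), 1, tolerance = 0.05)
  halved <- peak_means(0.5, seed = 3)
  expect_equal(unname(halved["left"] / halved["right"]), 0.5,
               tolerance = 0.05)
})

test_that("gait generator rejects non-positive duration and cadence", {
  p <- participant_profile()
  expect_error(generate_gait_trial(p, duration = 0, seed = 1),
               class = "exoresist_invalid_argument")
  expect_error(generate_gait_trial(p, duration = 10, cadence = -5, seed = 1),
               class = "exoresist_invalid_argument")
})

test_that("breath series follow the exponential on-transient exactly when noiseless", {
  b <- generate_breath_series("walk", steady_vo2 = 900, steady_vco2 = 780,
                              tau_on = 30, noise_sd = 0, duration = 360,
                              seed = 2, resolution = 0)
  rest <- 0.35 * 900
  expected <- rest + (900 - rest) * (1 - exp(-b$time_s / 30))
  expect_equal(b$vo2_mlmin, expected, tolerance = 1e-12)
  # asymptote: last breath of a long noiseless bout sits at the steady rate
  expect_equal(tail(b$vo2_mlmin, 1), 900, tolerance = 0.01 * 900)
  # interpolated value at t = tau is rest + (1 - 1/e) of the rise
  at_tau <- approx(b$time_s, b$vo2_mlmin, xout = 30)$y
  expect_lt(abs(at_tau - (rest + 0.6321 * (900 - rest))), 5)
  # monotone nondecreasing expectation when steady > rest
  expect_true(all(diff(b$vo2_mlmin) >= -1e-12))
})

test_that("breath series are seeded, jittered, and end near the steady rate", {
  a <- generate_breath_series("walk", 900, 780, noise_sd = 25,
                              duration = 360, seed = 5)
  b <- generate_breath_series("walk", 900, 780, noise_sd = 25,
                              duration = 360, seed = 5)
  expect_identical(a, b)
  expect_true(is.unsorted(diff(a$time_s)) || sd(diff(a$time_s)) > 0)
  last2 <- a$vo2_mlmin[a$time_s >= 240]
  se <- sd(last2) / sqrt(length(last2))
  expect_lt(abs(mean(last2) - 900), 2 * se + 900 * exp(-240 / 30))
  expect_error(
    generate_breath_series("walk", 900, 780, noise_sd = -1, duration = 60),
    class = "exoresist_invalid_argument"
  )
})

test_that("cohort generator is a pure function of the seed with exact null case", {
  coh0 <- generate_cohort(6, null_effects(noise_cv = 0), seed = 11)
  expect_equal(coh0$outcomes$post, coh0$outcomes$pre)
  a <- generate_cohort(6, effect_config(), seed = 12)
  b <- generate_cohort(6, effect_config(), seed = 12)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$profiles, b$profiles)
  expect_error(generate_cohort(1, effect_config(), seed = 1),
               class = "exoresist_invalid_argument")
})

test_that("cohort generator recovers a configured CoT reduction at large n", {
  eff <- effect_config(d_cot = -0.33, sd_cot = 0.09)
  coh <- generate_cohort(200, eff, seed = 21)
  cot <- dplyr::filter(coh$outcomes, measure == "cot")
  pct <- (cot$post - cot$pre) / cot$pre * 100
  expect_lt(abs(mean(pct) - (-33)), 2)
})

test_that("soreness responses are ordinal, seeded, and dose-responsive", {
  s <- generate_soreness(8, engagement = 0.7, propensity = 1, seed = 3)
  expect_s3_class(s, "ordered")
  expect_identical(s, generate_soreness(8, 0.7, 1, seed = 3))
  # average rank rises with mechanical dose
  rank_at <- function(dose_nm) {
    mean(sapply(1:200, function(i) {
      soreness_rank(generate_soreness(dose_nm, 1, 1, seed = i))
    }))
  }
  expect_lt(rank_at(1), rank_at(12))
})
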