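#' Construct a participant profile
#'
#' A profile holds the per-participant quantities that drive every synthetic
#' generator: anthropometrics, the more-affected side and its relative
#' weakness, and baseline values for the five trial outcome measures
#' (plantar-flexor MVC strength, preferred treadmill speed, net metabolic
#' cost of transport, timed-up-and-go time, and six-minute-walk distance).
#'
#' @param id Participant label.
#' @param body_mass Body mass in kg (> 0).
#' @param affected_side `"left"`, `"right"`, or `"both"` (diplegic
#'   presentation). A single more-affected limb is always designated for
#'   training: the named side, or the left limb by convention when both
#'   sides are affected.
#' @param asymmetry Ratio in (0, 1] scaling the more-affected limb's peak
#'   plantar-flexion moment relative to the less-affected limb.
#' @param baseline_mvc Plantar-flexor maximum voluntary contraction,
#'   averaged across limbs and normalised to body mass (N/kg).
#' @param baseline_speed Preferred treadmill walking speed (m/s).
#' @param baseline_cot Net metabolic cost of transport (J/(kg*m)).
#' @param baseline_tug Timed-up-and-go time (s).
#' @param baseline_6mwt Six-minute-walk distance (m).
#' @param peak_moment_nmkg Peak biological plantar-flexion moment of the
#'   less-affected limb during gait, normalised to body mass (Nm/kg).
#' @param soreness_propensity Unitless multiplier (>= 0) on the latent
#'   soreness drive; 1 is a typical responder.
#'
#' @return A one-row tibble with class `exo_profile` retained on the row
#'   values (plain tibble; the column set is the contract).
#' @examples
#' participant_profile("S1", body_mass = 45)
#' @export
participant_profile <- function(id = "S1",
                                body_mass = 50,
                                affected_side = c("left", "right", "both"),
                                asymmetry = 0.8,
                                baseline_mvc = 2.0,
                                baseline_speed = 0.9,
                                baseline_cot = 6.0,
                                baseline_tug = 9.0,
                                baseline_6mwt = 420,
                                peak_moment_nmkg = 1.0,
                                soreness_propensity = 1.0) {
  affected_side <- match.arg(affected_side)
  check_number(body_mass, "body_mass", min = 0, strict_min = TRUE)
  check_number(asymmetry, "asymmetry", min = 0, max = 1, strict_min = TRUE)
  check_number(baseline_mvc, "baseline_mvc", min = 0, strict_min = TRUE)
  check_number(baseline_speed, "baseline_speed", min = 0, strict_min = TRUE)
  check_number(baseline_cot, "baseline_cot", min = 0, strict_min = TRUE)
  check_number(baseline_tug, "baseline_tug", min = 0, strict_min = TRUE)
  check_number(baseline_6mwt, "baseline_6mwt", min = 0, strict_min = TRUE)
  check_number(peak_moment_nmkg, "peak_moment_nmkg", min = 0, strict_min = TRUE)
  check_number(soreness_propensity, "soreness_propensity", min = 0)
  tibble(
    id = as.character(id),
    body_mass = body_mass,
    affected_side = affected_side,
    more_affected = if (affected_side == "right") "right" else "left",
    asymmetry = asymmetry,
    baseline_mvc = baseline_mvc,
    baseline_speed = baseline_speed,
    baseline_cot = baseline_cot,
    baseline_tug = baseline_tug,
    baseline_6mwt = baseline_6mwt,
    peak_moment_nmkg = peak_moment_nmkg,
    soreness_propensity = soreness_propensity
  )
}

#' Draw a cohort of participant profiles
#'
#' Baselines are drawn from ranges typical of independently ambulant
#' adolescents with spastic cerebral palsy: reduced plantar-flexor strength,
#' slowed preferred speed, and a walking cost of transport elevated well
#' above the ~3.5 J/(kg*m) of unimpaired gait.
#'
#' @param n Number of participants (>= 2).
#' @param seed Integer seed; the draw is a pure function of `(n, seed)`.
#' @return A tibble with one `participant_profile()` row per participant.
#' @examples
#' cohort_profiles(6, seed = 1)
#' @export
cohort_profiles <- function(n = 6, seed = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop_invalid("`n` must be a single number >= 2.")
  }
  n <- as.integer(n)
  withr::with_seed(split_seed(seed, "profiles"), {
    sides <- sample(c("left", "right", "both"), n, replace = TRUE)
    purrr::map_dfr(seq_len(n), function(i) {
      participant_profile(
        id = sprintf("S%d", i),
        body_mass = min(90, max(25, rnorm(1, 50, 12))),
        affected_side = sides[i],
        asymmetry = runif(1, 0.6, 1),
        baseline_mvc = max(0.8, rnorm(1, 2.0, 0.5)),
        baseline_speed = max(0.3, rnorm(1, 0.85, 0.25)),
        baseline_cot = max(3.0, rnorm(1, 6.0, 1.5)),
        baseline_tug = max(5.0, rnorm(1, 9.0, 2.0)),
        baseline_6mwt = max(150, rnorm(1, 420, 90)),
        peak_moment_nmkg = max(0.5, rnorm(1, 1.0, 0.15)),
        soreness_propensity = rlnorm(1, meanlog = -0.045, sdlog = 0.3)
      )
    })
  })
}

#' Configure pre-to-post training effects for the cohort generator
#'
#' Fractional multiplicative changes applied to each outcome measure from
#' pre- to post-assessment, with a between-participant SD for each effect
#' and a multiplicative measurement-noise coefficient of variation. The
#' defaults reproduce the group-level training response of the pilot trial
#' the package models: strength +17 +/- 8 %, preferred speed +39 +/- 25 %,
#' cost of transport -33 +/- 9 %, timed-up-and-go -11 +/- 9 %,
#' six-minute-walk distance +13 +/- 9 %.
#'
#' @param d_mvc,d_speed,d_cot,d_tug,d_6mwt Mean fractional change per
#'   measure (e.g. `0.17` is +17 %).
#' @param sd_mvc,sd_speed,sd_cot,sd_tug,sd_6mwt Between-participant SD of
#'   the fractional change (>= 0).
#' @param noise_cv Multiplicative measurement-noise coefficient of
#'   variation applied independently to every pre and post value (>= 0).
#'   One scalar shared by all five measures.
#' @return A named list with class `exo_effects`.
#' @examples
#' effect_config()                      # the trial's observed effects
#' effect_config(d_mvc = 0, d_speed = 0, d_cot = 0, d_tug = 0, d_6mwt = 0)
#' @export
effect_config <- function(d_mvc = 0.17, d_speed = 0.39, d_cot = -0.33,
                          d_tug = -0.11, d_6mwt = 0.13,
                          sd_mvc = 0.08, sd_speed = 0.25, sd_cot = 0.09,
                          sd_tug = 0.09, sd_6mwt = 0.09,
                          noise_cv = 0.03) {
  for (nm in c("sd_mvc", "sd_speed", "sd_cot", "sd_tug", "sd_6mwt",
               "noise_cv")) {
    check_number(get(nm), nm, min = 0)
  }
  structure(
    list(
      effects = c(mvc = d_mvc, speed = d_speed, cot = d_cot,
                  tug = d_tug, sixmwt = d_6mwt),
      effect_sd = c(mvc = sd_mvc, speed = sd_speed, cot = sd_cot,
                    tug = sd_tug, sixmwt = sd_6mwt),
      noise_cv = noise_cv
    ),
    class = "exo_effects"
  )
}
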