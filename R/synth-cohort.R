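#' Soreness levels used after each training session
#'
#' The ordinal scale participants use to rate muscle soreness at the end of
#' a session, from rank 0 (`None`) to rank 4 (`Very Severe`).
#'
#' @return An ordered factor of the five levels.
#' @examples
#' soreness_levels()
#' soreness_rank("Moderate") # 2
#' @export
soreness_levels <- function() {
  factor(c("None", "Mild", "Moderate", "Severe", "Very Severe"),
         levels = c("None", "Mild", "Moderate", "Severe", "Very Severe"),
         ordered = TRUE)
}

#' @rdname soreness_levels
#' @param x Character or factor of soreness levels.
#' @export
soreness_rank <- function(x) {
  lev <- levels(soreness_levels())
  x <- as.character(x)
  bad <- !(x %in% lev)
  if (any(bad)) {
    stop_invalid(sprintf("Unknown soreness level(s): %s.",
                         paste(unique(x[bad]), collapse = ", ")))
  }
  match(x, lev) - 1L
}

#' Draw an ordinal soreness response after a training session
#'
#' A latent logistic variable centred on the session's mechanical dose
#' (`resistance_nm * engagement * propensity`, in Nm) is cut at fixed
#' thresholds into the five ordinal levels. The thresholds are set so that
#' light early-course sessions (~2 Nm) typically yield None/Mild, a
#' mid-course dose (~7 Nm at good engagement) is most often Moderate,
#' Severe stays uncommon, and Very Severe is rare.
#'
#' @param resistance_nm Prescribed resistance, Nm (>= 0).
#' @param engagement Fraction of strides reaching the prescription, in
#'   \[0, 1\].
#' @param propensity Participant soreness propensity (>= 0).
#' @param seed Integer seed.
#' @param thresholds Four increasing latent cut points (Nm-dose scale).
#' @param scale Scale of the latent logistic noise.
#' @return A length-1 ordered factor on `soreness_levels()`.
#' @examples
#' generate_soreness(8, engagement = 0.7, propensity = 1, seed = 3)
#' @export
generate_soreness <- function(resistance_nm, engagement, propensity = 1,
                              seed = 1,
                              thresholds = c(2, 4.5, 9.5, 15),
                              scale = 1.5) {
  check_number(resistance_nm, "resistance_nm", min = 0)
  check_number(engagement, "engagement", min = 0, max = 1)
  check_number(propensity, "propensity", min = 0)
  stopifnot(length(thresholds) == 4L, !is.unsorted(thresholds))
  dose <- resistance_nm * engagement * propensity
  withr::with_seed(split_seed(seed, "soreness"), {
    z <- rlogis(1, location = dose, scale = scale)
  })
  rank <- findInterval(z, thresholds)
  soreness_levels()[rank + 1L]
}

#' Simulate a pre/post outcome table for a training cohort
#'
#' Draws per-participant pre-assessment values around the profile baselines
#' with multiplicative measurement noise, then applies a participant-level
#' training effect to form the post-assessment:
#' `post = pre * (1 + d_m + delta_i) * (1 + noise)`, where `d_m` is the
#' configured mean fractional effect for measure `m` and `delta_i` is a
#' Gaussian participant deviate with the configured between-participant SD.
#' With all effects and noise zero, post equals pre exactly.
#'
#' @param n Number of participants (>= 2).
#' @param effects An `effect_config()`.
#' @param seed Integer seed; profiles and outcomes are pure functions of
#'   `(n, effects, seed)`.
#' @param profiles Optional tibble of profiles (from `cohort_profiles()` or
#'   `participant_profile()` rows); drawn from `seed` when `NULL`.
#' @return A list with `outcomes` (tibble: `participant`, `measure` in
#'   `mvc`/`speed`/`cot`/`tug`/`sixmwt`, `pre`, `post`) and `profiles`.
#' @examples
#' coh <- generate_cohort(6, effect_config(), seed = 4)
#' coh$outcomes
#' @export
generate_cohort <- function(n = 6, effects = effect_config(), seed = 1,
                            profiles = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop_invalid("`n` must be a single number >= 2.")
  }
  stopifnot(inherits(effects, "exo_effects"))
  if (is.null(profiles)) profiles <- cohort_profiles(n, seed)
  n <- nrow(profiles)
  measures <- names(effects$effects)
  baseline_cols <- c(mvc = "baseline_mvc", speed = "baseline_speed",
                     cot = "baseline_cot", tug = "baseline_tug",
                     sixmwt = "baseline_6mwt")
  outcomes <- withr::with_seed(split_seed(seed, "cohort-outcomes"), {
    purrr::map_dfr(measures, function(m) {
      base <- profiles[[baseline_cols[[m]]]]
      pre <- base * (1 + rnorm(n, sd = effects$noise_cv))
      effect_i <- effects$effects[[m]] +
        rnorm(n, sd = effects$effect_sd[[m]])
      post <- pre * (1 + effect_i) * (1 + rnorm(n, sd = effects$noise_cv))
      tibble(participant = profiles$id, measure = m, pre = pre, post = post)
    })
  })
  outcomes <- outcomes %>%
    mutate(measure = factor(.data$measure, levels = measures)) %>%
    arrange(.data$participant, .data$measure) %>%
    mutate(measure = as.character(.data$measure))
  list(outcomes = outcomes, profiles = profiles)
}
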