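#' Simulate breath-by-breath gas exchange with an exponential on-transient
#'
#' Emulates what a metabolic cart reports during an activity bout: oxygen
#' uptake and carbon-dioxide output rise from a resting level to a steady
#' rate along a mono-exponential on-transient
#' `rest + (steady - rest) * (1 - exp(-t / tau_on))`, sampled at irregular
#' breath times (log-normally jittered inter-breath intervals), with
#' additive Gaussian noise, and quantised to the analyser's reporting
#' resolution. For `"sit"` and `"stand"` the resting level defaults to the
#' steady rate, i.e. no transient.
#'
#' @param activity `"sit"`, `"stand"`, or `"walk"`.
#' @param steady_vo2,steady_vco2 Asymptotic steady-state gas rates, ml/min
#'   (> 0).
#' @param tau_on Time constant of the on-transient in s (> 0).
#' @param noise_sd Additive breath-to-breath noise SD, ml/min (>= 0).
#' @param duration Bout length in s (> 0).
#' @param seed Integer seed; the series is a pure function of its arguments.
#' @param rest_vo2,rest_vco2 Starting (resting) rates, ml/min. Default:
#'   `0.35 * steady` for walking, `steady` otherwise.
#' @param mean_ibi Mean inter-breath interval, s.
#' @param ibi_sdlog Log-scale SD of the inter-breath jitter.
#' @param resolution Reporting resolution of the analyser in ml/min; gas
#'   rates are rounded to this grid (0 disables quantisation).
#'
#' @return A tibble with columns `time_s` (strictly increasing),
#'   `vo2_mlmin`, `vco2_mlmin`, `activity`.
#' @examples
#' b <- generate_breath_series("walk", 900, 780, tau_on = 30,
#'                             noise_sd = 25, duration = 360, seed = 2)
#' head(b)
#' @export
generate_breath_series <- function(activity = c("walk", "sit", "stand"),
                                   steady_vo2,
                                   steady_vco2,
                                   tau_on = 30,
                                   noise_sd = 0,
                                   duration = 360,
                                   seed = 1,
                                   rest_vo2 = NULL,
                                   rest_vco2 = NULL,
                                   mean_ibi = 3,
                                   ibi_sdlog = 0.25,
                                   resolution = 0.1) {
  activity <- match.arg(activity)
  check_number(steady_vo2, "steady_vo2", min = 0, strict_min = TRUE)
  check_number(steady_vco2, "steady_vco2", min = 0, strict_min = TRUE)
  check_number(tau_on, "tau_on", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  check_number(mean_ibi, "mean_ibi", min = 0, strict_min = TRUE)
  check_number(resolution, "resolution", min = 0)
  rest_frac <- if (activity == "walk") 0.35 else 1
  if (is.null(rest_vo2)) rest_vo2 <- rest_frac * steady_vo2
  if (is.null(rest_vco2)) rest_vco2 <- rest_frac * steady_vco2
  check_number(rest_vo2, "rest_vo2", min = 0)
  check_number(rest_vco2, "rest_vco2", min = 0)

  withr::with_seed(split_seed(seed, paste0("breath-", activity)), {
    n_max <- ceiling(duration / mean_ibi * 3) + 10L
    ibi <- rlnorm(n_max, meanlog = log(mean_ibi) - ibi_sdlog^2 / 2,
                  sdlog = ibi_sdlog)
    t <- cumsum(ibi)
    t <- t[t <= duration]
    on_transient <- 1 - exp(-t / tau_on)
    vo2 <- rest_vo2 + (steady_vo2 - rest_vo2) * on_transient
    vco2 <- rest_vco2 + (steady_vco2 - rest_vco2) * on_transient
    vo2 <- vo2 + rnorm(length(t), sd = noise_sd)
    vco2 <- vco2 + rnorm(length(t), sd = noise_sd)
    if (resolution > 0) {
      vo2 <- round(vo2 / resolution) * resolution
      vco2 <- round(vco2 / resolution) * resolution
    }
    tibble(
      time_s = t,
      vo2_mlmin = pmax(vo2, 0),
      vco2_mlmin = pmax(vco2, 0),
      activity = activity
    )
  })
}
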