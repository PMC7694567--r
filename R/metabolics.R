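#' Brockway metabolic power from gas-exchange rates
#'
#' Converts oxygen uptake and carbon-dioxide output to metabolic energy
#' expenditure with the Brockway equation, using energy equivalents of
#' 16.58 kJ per litre O2 and 4.51 kJ per litre CO2 (protein oxidation
#' neglected). Rates in ml/min convert internally to L/s, so
#' `power_w = (16.58 * vo2 + 4.51 * vco2) / 60` for inputs in ml/min.
#'
#' @param vo2_mlmin Oxygen uptake, ml/min (>= 0, vectorised).
#' @param vco2_mlmin Carbon-dioxide output, ml/min (>= 0, vectorised).
#' @return Metabolic power in W.
#' @examples
#' brockway_power(1000, 0)   # 276.33 W
#' brockway_power(1000, 850) # RER 0.85
#' @export
brockway_power <- function(vo2_mlmin, vco2_mlmin) {
  check_numeric_vector(vo2_mlmin, "vo2_mlmin", min = 0)
  check_numeric_vector(vco2_mlmin, "vco2_mlmin", min = 0)
  (16.58 * vo2_mlmin + 4.51 * vco2_mlmin) / 60
}

#' Net metabolic power of walking
#'
#' Subtracts the steady-state metabolic power of quiet standing from that
#' of walking, leaving the power attributable to locomotion itself. A
#' negative result (walking apparently cheaper than standing) is allowed
#' but flagged with a warning, since it usually signals a failed
#' steady-state selection.
#'
#' @param walk_power_w Steady-state walking power, W.
#' @param stand_power_w Steady-state standing power, W.
#' @return Net power, W.
#' @examples
#' net_metabolic_power(300, 100)
#' @export
net_metabolic_power <- function(walk_power_w, stand_power_w) {
  check_numeric_vector(walk_power_w, "walk_power_w")
  check_numeric_vector(stand_power_w, "stand_power_w")
  net <- walk_power_w - stand_power_w
  if (any(net < 0)) {
    warn("Net metabolic power is negative; check steady-state selection.")
  }
  net
}

#' Metabolic cost of transport
#'
#' Normalises net metabolic power by body mass and walking speed, giving
#' the energy required to move a unit body mass a unit distance,
#' J/(kg*m): `cot = net_power / (body_mass * speed)`.
#'
#' @param net_power_w Net metabolic power, W.
#' @param body_mass Body mass, kg (> 0).
#' @param speed Walking speed, m/s (> 0).
#' @return Cost of transport, J/(kg*m).
#' @examples
#' cost_of_transport(100, body_mass = 50, speed = 1) # 2 J/(kg*m)
#' @export
cost_of_transport <- function(net_power_w, body_mass, speed) {
  check_numeric_vector(net_power_w, "net_power_w")
  check_number(body_mass, "body_mass", min = 0, strict_min = TRUE)
  check_number(speed, "speed", min = 0, strict_min = TRUE)
  net_power_w / (body_mass * speed)
}

#' Full metabolic pipeline: breath series to cost of transport
#'
#' Runs the complete processing chain on a walking and a standing breath
#' series: Brockway power per breath, tau-b steady-state classification,
#' mean power over each activity's selected steady window, net power by
#' standing subtraction, and cost of transport.
#'
#' @param walk,stand Breath tibbles (see [generate_breath_series()] or
#'   [read_breath_csv()]).
#' @param body_mass Body mass, kg (> 0).
#' @param speed Treadmill speed of the walking bout, m/s (> 0).
#' @param window,alpha,rule,smooth Passed to [classify_steady_state()].
#' @return A one-row tibble: `walk_power_w`, `stand_power_w`,
#'   `net_power_w`, `cot_jkgm`, `walk_window_start_s`,
#'   `walk_window_end_s`, `window`, `alpha`.
#' @examples
#' walk <- generate_breath_series("walk", 900, 780, noise_sd = 20,
#'                                duration = 360, seed = 1)
#' stand <- generate_breath_series("stand", 320, 270, noise_sd = 15,
#'                                 duration = 240, seed = 1)
#' compute_cot(walk, stand, body_mass = 50, speed = 1.0)
#' @export
compute_cot <- function(walk, stand, body_mass, speed,
                        window = 20, alpha = 0.05, rule = "centered",
                        smooth = FALSE) {
  ss_walk <- classify_steady_state(walk, window = window, alpha = alpha,
                                   rule = rule, smooth = smooth)
  ss_stand <- classify_steady_state(stand, window = window, alpha = alpha,
                                    rule = rule, smooth = smooth)
  walk_p <- steady_state_mean(ss_walk)
  stand_p <- steady_state_mean(ss_stand)
  net <- net_metabolic_power(walk_p, stand_p)
  sel <- ss_walk$windows[ss_walk$windows$selected, ]
  tibble(
    walk_power_w = walk_p,
    stand_power_w = stand_p,
    net_power_w = net,
    cot_jkgm = cost_of_transport(net, body_mass, speed),
    walk_window_start_s = ss_walk$points$time_s[sel$start],
    walk_window_end_s = ss_walk$points$time_s[sel$end],
    window = window,
    alpha = alpha
  )
}
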