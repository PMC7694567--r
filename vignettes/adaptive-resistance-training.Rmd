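---
title: "Adaptive ankle-resistance gait training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive ankle-resistance gait training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(exoresist)
library(dplyr)
```

exoresist simulates and analyses a style of gait rehabilitation in which a
wearable ankle exoskeleton *resists* plantar flexion in proportion to the
wearer's own effort, session by session, and the training response is
quantified with the standard clinical-trial toolkit: pre/post outcome
measures, steady-state indirect calorimetry, and paired statistics. This
vignette documents the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic generators do and do not
emulate.

## The proportional resistance controller

The device estimates the biological plantar-flexion ankle moment
$\hat{M}(t)$ from a force sensor under the forefoot through a fixed
effective lever arm $\ell$ (default 0.15 m): $\hat{M}(t) = \ell\,F(t)$. A
calibration bout first records the average peak ankle moment across
strides, $M_{\mathrm{peak}}$ (per limb). During training with a prescribed
resistance level $r$ (Nm/kg), the commanded resistance torque is

$$
\tau(t) \;=\; r \, m \,
\operatorname{clip}\!\left(\frac{\hat{M}(t)}{M_{\mathrm{peak}}},\, 0,\, 1\right),
$$

with $m$ body mass in kg. At the calibrated peak (late stance) the full
prescription is applied; at half the peak (early stance) half of it;
during swing, nothing. The choice of $\ell$ cancels out of
$\hat{M}/M_{\mathrm{peak}}$, so only the prescription and the calibration
matter — which is why a single proportionality is an adequate moment
model here. Moment fractions above 1 (a stride stronger than the
calibration average) are clipped to 1, keeping
$0 \le \tau \le r\,m$ always.

Two numerical details are deliberate:

* **Causality.** `run_session()` gates torque with a pointwise force
  threshold (default 10 N) and no run-length debounce, because its output
  at sample $k$ must depend only on samples up to $k$, as in the real-time
  controller. The offline stance analyses (`detect_stance()`,
  `calibrate_peak_moment()`) may use a 100 ms minimum-interval debounce to
  reject threshold chatter; the simulated traces are clean, so the two
  conventions agree there.
* **Stride accounting.** A "stride" is one maximal above-threshold run of
  the forefoot force; its peak applied torque is the stride's engagement
  summary.

```{r controller}
profile <- participant_profile(body_mass = 50)
trial <- generate_gait_trial(profile, duration = 30, seed = 1)
cal <- calibrate_peak_moment(trial)
cal
sess <- run_session(trial, cal, resistance = 0.1, body_mass = 50)
glance(sess)
```

## Training progression

Training is ten visits of 20 minutes of walking. Engagement is scored per
gait cycle: the fraction of strides whose peak applied torque reached at
least 95 % of the prescription (`engagement_fraction()`; the tolerance is
configurable — the protocol itself states no number, only "reaching the
prescribed level of resistance"). After each session the participant
reports soreness on the ordinal scale None / Mild / Moderate / Severe /
Very Severe. The prescription increases by a fixed increment — default
0.75 Nm, the midpoint of the protocol's 0.5–1 Nm band — for the next
session only when *both* engagement exceeded 50 % of strides *and*
soreness was at worst Moderate. Resistance is therefore nondecreasing and
moves in whole increments. The "> 50 % of the training session" criterion
is interpreted per gait cycle rather than per unit time, matching how
engagement is monitored (the fraction of gait cycles reaching the
prescribed resistance); a time-based variant would require modelling rest
breaks, which carry no information here and are ignored. The increment
applies to both limbs identically.

Starting resistance defaults to 0.05 Nm/kg, inside the protocol's
0.025–0.075 Nm/kg band; values outside the band warn but do not error,
since the engine is also useful for what-if exploration
(`soreness_override` forces a fixed report, e.g. to confirm that
persistent Very Severe soreness freezes the prescription).

```{r progression}
course <- simulate_training_course(profile, start_r = 0.05, seed = 2,
                                   bout_duration = 30)
course
```

With the default generator settings, ten-session courses typically end
between 0.10 and 0.35 Nm/kg, bracketing the 0.14–0.27 Nm/kg range the
protocol reports at visit ten.

## Steady-state metabolics

Breath-by-breath gas exchange never sits still; deciding *which* breaths
represent steady state is the main methodological hazard of treadmill
calorimetry, especially in populations with variable gait. The package
classifies each breath by a windowed Kendall tau-b trend test of the
Brockway power trace against time: within a sliding window (default 20
breaths), a significantly positive tau (two-sided $p < \alpha$, default
$\alpha = 0.05$) marks the window rising, significantly negative falling,
otherwise stable. The null hypothesis is that a point lies in a steady
window; rejection marks non-steady data.

tau-b is computed with Knight's merge-sort algorithm ($O(n\log n)$), with
tie corrections in both variables; the p-value uses the tie-adjusted
normal approximation for the variance of the S statistic, or exact
permutation enumeration for $n \le 8$. Because tau is rank-based, the
classification is invariant to affine rescaling of the power trace.

A point is steady when its *centred* window is stable (at the edges, the
nearest full window). The alternative rule — all covering windows stable
— is available but not the default: each window test has a 5 % false
positive rate by construction, and under the all-windows rule a single
chance rejection disqualifies an entire window-length span of genuinely
steady breaths, which empirically leaves realistic six-minute bouts with
no steady window at all in roughly one bout in ten. Steady-state windows
are maximal runs of steady breaths at least one window long; when several
exist, the longest is used (ties broken toward the latest, i.e. the most
settled data). Breath values enter unsmoothed by default; a 5-breath
running median is available behind `smooth = TRUE`.

Energy expenditure uses the Brockway equation with 16.58 kJ/L O2 and
4.51 kJ/L CO2 (protein oxidation neglected), net walking power subtracts
quiet standing, and the cost of transport divides by body mass and speed:

$$
P = \frac{16.58\,\dot{V}\mathrm{O}_2 + 4.51\,\dot{V}\mathrm{CO}_2}{60}
\ \mathrm{W}
\quad (\dot V \text{ in ml/min}), \qquad
\mathrm{CoT} = \frac{P_{\mathrm{walk}} - P_{\mathrm{stand}}}{m\,v}
\ \mathrm{J/(kg\,m)}.
$$

Sitting bouts are processed identically for quality control but only
standing enters the subtraction. A negative net power is allowed but
warns, as it usually signals a failed window selection. If no steady
window emerges within a six-minute bout, the practical remedy — as in the
protocol, where participants walk "until oxygen consumption plateaus" —
is to extend the bout and reprocess.

```{r metabolics}
walk <- generate_breath_series("walk", 900, 780, noise_sd = 20,
                               duration = 360, seed = 1)
stand <- generate_breath_series("stand", 320, 270, noise_sd = 10,
                                duration = 300, seed = 1)
compute_cot(walk, stand, body_mass = 50, speed = 1.0) %>%
  select(walk_power_w, stand_power_w, net_power_w, cot_jkgm)
```

## The statistical battery

`analyze_trial()` reproduces the trial's analysis plan per measure:

1. incomplete pre/post pairs are dropped listwise (a participant who
   misses one assessment is excluded from that measure only);
2. pre and post values are screened separately with the 1.5 x IQR fence
   rule — quartiles by linear interpolation of order statistics
   (`quantile` type 7, fixed and documented since the convention matters
   at $n = 6$) — and flagged participants removed from that measure;
3. normality is checked with a Kolmogorov–Smirnov test with Lilliefors
   correction; since the classical KS null does not apply when mean and SD
   are estimated from the sample, the p-value comes from a seeded
   Monte-Carlo null (default $10^4$ standard-normal replicates of the same
   n). The result is reported, never used to gate the t-test;
4. the pre-to-post change is tested with a two-tailed paired t-test,
   adjusted across the five-measure family by Holm–Bonferroni, at
   $\alpha = 0.05$;
5. the effect is summarised as Cohen's d and as the mean ± SD of
   per-participant percent changes $(post-pre)/pre$ — the mean of
   percent changes, not the percent change of means, matching how group
   effects like "17 ± 8 %" are quoted.

Cohen's d defaults to the difference-score variant
$d_z = \bar{d}/s_d$; the average-SD variant $d_{av}$ is available. With
$n = 6$ the two can differ substantially, and published paired-design d
values are not always explicit about the formula, so the variant is a
documented choice rather than something to tune.

The Monte-Carlo normality step is the only stochastic component; it is
seeded, so the whole analysis is deterministic given the table and seed.
Inside large simulation studies it can be thinned (`normality_reps`) or
switched off (`normality = FALSE`) without touching the inferential
chain.

```{r outcomes}
coh <- generate_cohort(6, effect_config(), seed = 1)
fit <- analyze_trial(coh$outcomes, seed = 1, normality_reps = 2000)
fit
```

## What the synthetic generators emulate

The generators stand in for the study's raw data; their defaults are the
study's conditions, chosen once and not tuned.

**Gait** (`generate_gait_trial()`): each limb alternates stance (60 % of
a 1.2 s stride at the default 100 steps/min) and swing; the right limb is
half a stride out of phase. Within stance the ankle moment follows a
smooth unimodal beta-kernel profile $s^{a}(1-s)^{b}$ with its mode at
75 % of stance — late-stance push-off — because no waveform is prescribed
anywhere; any smooth single-peak shape serves, and this one is
parameterised by peak position alone. Stride peaks vary log-normally with
mean one (CV default 10 %; mean-one so the calibration target equals the
configured peak), the more-affected limb is scaled by the profile's
asymmetry ratio, and forefoot force is moment over lever arm, so force
and moment are coherent by construction. Not emulated: double support,
heel-strike transients, EMG, spasticity-related variability structure, or
any hardware dynamics (motors, Bowden cables, torque-sensor error).

**Breaths** (`generate_breath_series()`): gas rates follow
$rest + (steady - rest)(1 - e^{-t/\tau})$ (default $\tau = 30$ s;
resting level 35 % of steady for walking, no transient for sit/stand)
sampled at log-normally jittered inter-breath intervals (mean 3 s, log-SD
0.25 — no timing data exist to fit, these are physiological magnitudes),
plus additive Gaussian noise, quantised to the analyser's reporting
resolution (default 0.1 ml/min). The quantisation is deliberate and
load-bearing: a noiseless exponential approach is strictly increasing in
double precision, so a rank-based trend test would label it rising
forever; a real metabolic cart reports finitely many digits, and the
resulting ties are exactly what lets the plateau register as stable. Not
emulated: slow drift components, RER dynamics, artifacts (coughs,
talking).

**Cohort** (`generate_cohort()`): baselines are drawn from ranges typical
of independently ambulant adolescents with spastic CP (mass ~50 kg, MVC
~2 N/kg, preferred speed ~0.85 m/s, CoT ~6 J/(kg·m) — well above the
~3.5 of unimpaired gait — TUG ~9 s, 6MWT ~420 m). Post values apply a
participant-level multiplicative effect,
$post = pre\,(1 + d_m + \delta_i)(1 + \varepsilon)$, with the default
effect means and between-participant SDs set to the trial's reported
group changes (+17 ± 8 % strength, +39 ± 25 % speed, −33 ± 9 % CoT,
−11 ± 9 % TUG, +13 ± 9 % 6MWT) and a 3 % measurement CV. Preferred speed
is treated as a per-assessment scalar; within-participant speed
variability across visits is not modelled, as no data describe it.

**Soreness** (`generate_soreness()`): a latent logistic variable centred
on the session's mechanical dose (resistance × engagement × propensity,
Nm) cut at fixed thresholds (2, 4.5, 9.5, 15 on the dose scale, logistic
scale 1.5). The thresholds were placed so that early-course sessions
(~2 Nm) are typically None/Mild, a mid-course dose at good engagement
(~7 Nm) is most often Moderate, Severe stays uncommon, and Very Severe is
rare — the qualitative pattern the protocol reports. Only the observed
scale and range are documented anywhere, so this mapping is a modelling
choice, not a fit.

All generators are pure functions of their arguments and a seed: one
user-facing seed is split into independent per-stream seeds by a fixed
affine hash, so e.g. the gait trial and the soreness draw of a visit
never share a random stream, yet every run is exactly reproducible.

Passing tests on these generators demonstrates that the *methods* behave
correctly under controlled conditions with known ground truth. It does
not validate the generators against real patients: real gait and gas
exchange are richer than these models, and results on synthetic cohorts
quantify method behaviour (bias, error control, robustness), not clinical
effect sizes.

## Simulation sizes and limitations

The test-suite simulation studies use cohorts of 6 (the study design),
500 replicates for parameter-recovery and family-wise-error checks,
100 seeds for the metabolic pipeline, and 30-60 s simulated walking bouts
per training visit (a representative sample of ~25-50 strides standing in
for the 20-minute session); these sizes give Monte-Carlo errors
comfortably below the tolerances being checked.

Known limitations:

* Individual-level reproduction of the motivating trial's statistics is
  impossible from published group summaries; the package's claim is
  methodological fidelity plus parameter recovery on synthetic cohorts.
* The steady-state detector's window length (20 breaths) and alpha
  (0.05) follow common practice for breath-by-breath data but are not
  prescribed by any source; both are recorded in every result object.
* Whether a session's engagement should be scored per gait cycle or per
  unit time is a genuine ambiguity; per-cycle is the default reading and
  the only one implemented without a rest-break model.
* The controller simulation applies commanded torque perfectly;
  actuation latency, cable friction, and torque-tracking error are out of
  scope.
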