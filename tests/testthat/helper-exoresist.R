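# Shared fixtures and independent oracles used across the suite.

# O(n^2) brute-force Kendall tau-b by full pair enumeration with tie
# corrections — the independent oracle for the merge-sort implementation.
bruteforce_tau_b <- function(x, t) {
  sx <- sign(outer(x, x, "-"))
  st <- sign(outer(t, t, "-"))
  iu <- upper.tri(sx)
  s <- sum((sx * st)[iu])
  n0 <- sum(iu)
  n1 <- sum(st[iu] == 0)
  n2 <- sum(sx[iu] == 0)
  s / sqrt((n0 - n1) * (n0 - n2))
}

# Textbook paired-t computation, independent of stats::t.test.
textbook_paired_t <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1), df = n - 1)
}

# Step-down Holm adjustment straight from its definition.
textbook_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[ord]))
  out <- numeric(m)
  out[ord] <- adj
  out
}

null_effects <- function(noise_cv = 0.03) {
  effect_config(d_mvc = 0, d_speed = 0, d_cot = 0, d_tug = 0, d_6mwt = 0,
                sd_mvc = 0, sd_speed = 0, sd_cot = 0, sd_tug = 0,
                sd_6mwt = 0, noise_cv = noise_cv)
}

# A hand-built gait trial: rectangular-ish stance bursts with known peak
# forces, for exact calibration arithmetic.
square_trial <- function(peaks_n, stance_samples = 40, gap_samples = 40,
                         sample_rate = 100) {
  force <- unlist(lapply(peaks_n, function(p) {
    c(rep(0, gap_samples), rep(p, stance_samples))
  }))
  force <- c(force, rep(0, gap_samples))
  tibble::tibble(
    time_s = rep(seq_along(force) / sample_rate, 2),
    limb = rep(c("left", "right"), each = length(force)),
    force_n = rep(force, 2),
    moment_nm = rep(force, 2) * 0.15
  )
}
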