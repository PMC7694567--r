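#' Average plantar-flexor MVC across trials and limbs
#'
#' The strength protocol: three maximum-voluntary-contraction pushes per
#' limb into a hand-held dynamometer, averaged within each limb, averaged
#' between limbs, and normalised to body mass. Fewer or more than three
#' trials per limb draws a protocol warning but is still computed on what
#' is available.
#'
#' @param left,right Per-limb MVC forces in N (nominally 3 each).
#' @param body_mass Body mass, kg (> 0).
#' @return Mass-normalised MVC, N/kg.
#' @examples
#' average_mvc(c(100, 110, 120), c(100, 110, 120), body_mass = 50) # 2.2
#' @export
average_mvc <- function(left, right, body_mass) {
  check_numeric_vector(left, "left", min = 0)
  check_numeric_vector(right, "right", min = 0)
  check_number(body_mass, "body_mass", min = 0, strict_min = TRUE)
  if (length(left) != 3L || length(right) != 3L) {
    warn(sprintf(
      "MVC protocol expects 3 trials per limb (got %d left, %d right); averaging available trials.",
      length(left), length(right)
    ))
  }
  mean(c(mean(left), mean(right))) / body_mass
}

#' Flag outliers by the 1.5 x IQR fence rule
#'
#' A value is an outlier when it lies more than 1.5 interquartile ranges
#' below the first quartile or above the third quartile. Quartiles use
#' linear interpolation between order statistics (`stats::quantile`
#' type 7). With fewer than 4 values no screening is attempted (warning,
#' empty mask).
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (1.5 by convention).
#' @return A list: `outlier` (logical mask), `lower`, `upper` (fences).
#' @examples
#' iqr_outliers(c(4, 4.5, 5, 5.5, 6, 16.9))$outlier
#' @export
iqr_outliers <- function(values, k = 1.5) {
  check_numeric_vector(values, "values")
  check_number(k, "k", min = 0)
  if (length(values) < 4L) {
    warn("Fewer than 4 values; outlier screening skipped.")
    return(list(outlier = rep(FALSE, length(values)),
                lower = -Inf, upper = Inf))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  list(outlier = values < lower | values > upper,
       lower = lower, upper = upper)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' Tests a sample against a normal distribution whose mean and SD are
#' estimated from the same sample. Because of that estimation step the
#' classical KS null distribution does not apply; the p-value is obtained
#' from a seeded Monte-Carlo null (standard-normal samples of the same
#' size, each standardised and reduced to its KS statistic).
#'
#' @param values Numeric sample (n >= 4).
#' @param n_mc Number of Monte-Carlo null replicates (>= 1000).
#' @param seed Integer seed for the null simulation.
#' @return A list: `statistic` (KS distance `D`), `p_value`, `n`,
#'   `degenerate` (TRUE with `p_value = 0` for a zero-variance sample).
#' @examples
#' lilliefors_normality(rnorm(20), n_mc = 2000, seed = 1)$p_value
#' @export
lilliefors_normality <- function(values, n_mc = 10000, seed = 1) {
  check_numeric_vector(values, "values", min_length = 4L)
  if (n_mc < 1000) stop_invalid("`n_mc` must be >= 1000.")
  n <- length(values)
  if (sd(values) == 0) {
    return(list(statistic = NA_real_, p_value = 0, n = n, degenerate = TRUE))
  }
  d_obs <- lilliefors_statistic(values)
  d_null <- withr::with_seed(split_seed(seed, "lilliefors"), {
    vapply(seq_len(n_mc), function(i) {
      lilliefors_statistic(rnorm(n))
    }, numeric(1))
  })
  list(
    statistic = d_obs,
    p_value = mean(d_null >= d_obs),
    n = n,
    degenerate = FALSE
  )
}

lilliefors_statistic <- function(values) {
  n <- length(values)
  z <- sort((values - mean(values)) / sd(values))
  phi <- pnorm(z)
  max(pmax(seq_len(n) / n - phi, phi - (seq_len(n) - 1) / n))
}

#' Two-tailed paired t-test
#'
#' Tests whether post differs from pre within participants; the statistic
#' is computed on the paired differences (`post - pre`) with `n - 1`
#' degrees of freedom via `stats::t.test`. A zero-variance difference
#' vector is handled explicitly: identical nonzero shifts give `p = 0`
#' with an infinite t (flagged); identical pre and post give `t = 0`,
#' `p = 1`.
#'
#' @param pre,post Paired numeric vectors (equal length, n >= 2, complete).
#' @return A list: `t`, `p_value`, `df`, `mean_diff`, `degenerate`.
#' @examples
#' paired_t(c(1, 2, 3, 4), c(3, 6, 9, 12))
#' @export
paired_t <- function(pre, post) {
  check_numeric_vector(pre, "pre", min_length = 2L)
  check_numeric_vector(post, "post", min_length = 2L)
  if (length(pre) != length(post)) {
    stop_invalid("`pre` and `post` must have the same length.")
  }
  d <- post - pre
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p_value = 1, df = n - 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p_value = 0, df = n - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  fit <- t.test(post, pre, paired = TRUE, alternative = "two.sided")
  list(
    t = unname(fit$statistic),
    p_value = fit$p.value,
    df = unname(fit$parameter),
    mean_diff = mean(d),
    degenerate = FALSE
  )
}

#' Holm-Bonferroni step-down adjustment
#'
#' Controls the family-wise error rate across a family of hypotheses:
#' sort the raw p-values ascending, multiply the i-th smallest by
#' `m - i + 1`, enforce monotonicity by running maxima, cap at 1, and
#' return in the input order (`stats::p.adjust(method = "holm")`).
#'
#' @param p_values Raw p-values, all in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_bonferroni(c(0.01, 0.02, 0.03))
#' @export
holm_bonferroni <- function(p_values) {
  check_numeric_vector(p_values, "p_values")
  if (any(p_values < 0 | p_values > 1)) {
    stop_invalid("All p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "holm")
}

#' Cohen's d effect size for paired designs
#'
#' Two paired-design variants: `dz` (the default) standardises the mean
#' difference by the SD of the differences, `mean(post - pre) / sd(post -
#' pre)`; `dav` standardises by the average of the pre and post SDs. The
#' sign follows `post - pre`. A zero denominator returns `NA` with a
#' warning.
#'
#' @param pre,post Paired numeric vectors (equal length, n >= 2).
#' @param variant `"dz"` or `"dav"`.
#' @return Effect size d (unitless).
#' @examples
#' cohens_d(c(0, 0, 0, 0), c(2, 4, 6, 8)) # dz = 1.936
#' @export
cohens_d <- function(pre, post, variant = c("dz", "dav")) {
  variant <- match.arg(variant)
  check_numeric_vector(pre, "pre", min_length = 2L)
  check_numeric_vector(post, "post", min_length = 2L)
  if (length(pre) != length(post)) {
    stop_invalid("`pre` and `post` must have the same length.")
  }
  d <- post - pre
  denom <- switch(variant,
    dz = sd(d),
    dav = mean(c(sd(pre), sd(post)))
  )
  if (denom == 0) {
    if (mean(d) == 0) return(0)
    warn("Zero-variance denominator; Cohen's d is undefined.")
    return(NA_real_)
  }
  mean(d) / denom
}
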