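#' Run the pre/post statistical battery on an outcome table
#'
#' The trial's full analysis, measure by measure: drop incomplete pairs
#' (listwise per measure), screen pre and post values separately with the
#' 1.5 x IQR fence rule and remove flagged participants, report Lilliefors
#' normality p-values (informative, never gating), test the pre-to-post
#' change with a two-tailed paired t-test, adjust across the measure
#' family with Holm-Bonferroni, and summarise the per-participant percent
#' change `(post - pre) / pre` as mean +/- SD together with Cohen's d.
#'
#' @param table An outcome tibble with columns `participant`, `measure`,
#'   `pre`, `post` (at most one row per participant x measure; `NA` post
#'   marks a missed assessment).
#' @param alpha Significance level for flagging adjusted p-values.
#' @param d_variant Cohen's d variant, `"dz"` (default) or `"dav"`.
#' @param normality Run the Monte-Carlo Lilliefors check (on by default;
#'   switch off inside large simulation loops).
#' @param normality_reps Monte-Carlo replicates for the Lilliefors null.
#' @param seed Integer seed (only the normality Monte-Carlo consumes
#'   randomness; the rest of the battery is deterministic).
#' @return An `exo_trial_stats` object. `tidy()` returns one row per
#'   measure: `measure`, `n_used`, `mean_pre`, `sd_pre`, `mean_post`,
#'   `sd_post`, `pct_change_mean`, `pct_change_sd`, `t`, `df`, `p_raw`,
#'   `p_adjusted`, `significant`, `d`, `p_normal_pre`, `p_normal_post`,
#'   `outliers_removed` (list column), `note`.
#' @examples
#' coh <- generate_cohort(6, effect_config(), seed = 1)
#' fit <- analyze_trial(coh$outcomes, seed = 1, normality_reps = 1000)
#' tidy(fit)
#' glance(fit)
#' @export
analyze_trial <- function(table, alpha = 0.05,
                          d_variant = c("dz", "dav"),
                          normality = TRUE, normality_reps = 10000,
                          seed = 1) {
  d_variant <- match.arg(d_variant)
  check_columns(table, c("participant", "measure", "pre", "post"), "table")
  check_number(alpha, "alpha", min = 0, max = 1,
               strict_min = TRUE, strict_max = TRUE)
  if (anyDuplicated(table[c("participant", "measure")])) {
    stop_invalid("`table` has more than one row per participant x measure.")
  }

  measure_order <- c("mvc", "speed", "cot", "tug", "sixmwt")
  measures <- unique(table$measure)
  measures <- c(intersect(measure_order, measures),
                setdiff(measures, measure_order))

  rows <- purrr::map(measures, function(m) {
    sub <- filter(table, .data$measure == m)
    complete <- !is.na(sub$pre) & !is.na(sub$post)
    n_missing <- sum(!complete)
    sub <- sub[complete, ]

    removed <- character(0)
    if (nrow(sub) >= 4L) {
      out_pre <- iqr_outliers(sub$pre)$outlier
      out_post <- iqr_outliers(sub$post)$outlier
      flagged <- out_pre | out_post
      removed <- sub$participant[flagged]
      sub <- sub[!flagged, ]
    }

    if (nrow(sub) < 2L) {
      return(tibble(
        measure = m, n_used = nrow(sub), mean_pre = NA_real_,
        sd_pre = NA_real_, mean_post = NA_real_, sd_post = NA_real_,
        pct_change_mean = NA_real_, pct_change_sd = NA_real_,
        t = NA_real_, df = NA_real_, p_raw = NA_real_, d = NA_real_,
        p_normal_pre = NA_real_, p_normal_post = NA_real_,
        outliers_removed = list(removed),
        note = sprintf("skipped: %d complete pair(s) after screening",
                       nrow(sub))
      ))
    }

    tt <- paired_t(sub$pre, sub$post)
    pct <- (sub$post - sub$pre) / sub$pre * 100
    p_norm_pre <- p_norm_post <- NA_real_
    if (normality && nrow(sub) >= 4L) {
      p_norm_pre <- lilliefors_normality(
        sub$pre, n_mc = normality_reps,
        seed = split_seed(seed, paste0("normal-pre-", m))
      )$p_value
      p_norm_post <- lilliefors_normality(
        sub$post, n_mc = normality_reps,
        seed = split_seed(seed, paste0("normal-post-", m))
      )$p_value
    }
    tibble(
      measure = m,
      n_used = nrow(sub),
      mean_pre = mean(sub$pre), sd_pre = sd(sub$pre),
      mean_post = mean(sub$post), sd_post = sd(sub$post),
      pct_change_mean = mean(pct), pct_change_sd = sd(pct),
      t = tt$t, df = tt$df, p_raw = tt$p_value,
      d = cohens_d(sub$pre, sub$post, d_variant),
      p_normal_pre = p_norm_pre, p_normal_post = p_norm_post,
      outliers_removed = list(as.character(removed)),
      note = if (n_missing > 0) {
        sprintf("%d incomplete pair(s) dropped", n_missing)
      } else NA_character_
    )
  })
  results <- bind_rows(rows)

  tested <- !is.na(results$p_raw)
  results$p_adjusted <- NA_real_
  results$p_adjusted[tested] <- holm_bonferroni(results$p_raw[tested])
  results$significant <- !is.na(results$p_adjusted) &
    results$p_adjusted < alpha
  results <- select(
    results, "measure", "n_used", "mean_pre", "sd_pre", "mean_post",
    "sd_post", "pct_change_mean", "pct_change_sd", "t", "df", "p_raw",
    "p_adjusted", "significant", "d", "p_normal_pre", "p_normal_post",
    "outliers_removed", "note"
  )

  structure(
    list(results = results, table = table, alpha = alpha,
         d_variant = d_variant, seed = seed),
    class = "exo_trial_stats"
  )
}

#' @method tidy exo_trial_stats
#' @export
tidy.exo_trial_stats <- function(x, ...) x$results

#' @method glance exo_trial_stats
#' @export
glance.exo_trial_stats <- function(x, ...) {
  tibble(
    n_measures = nrow(x$results),
    n_tested = sum(!is.na(x$results$p_raw)),
    n_significant = sum(x$results$significant),
    alpha = x$alpha,
    d_variant = x$d_variant
  )
}

#' @export
print.exo_trial_stats <- function(x, digits = 2, ...) {
  r <- x$results
  cat(sprintf("Pre/post outcome analysis (paired t, Holm-Bonferroni, Cohen's %s)\n",
              x$d_variant))
  cat(sprintf("%-8s %2s %14s %14s %12s %7s %7s %7s\n",
              "measure", "n", "pre (mean+/-SD)", "post (mean+/-SD)",
              "% change", "p", "p.adj", "d"))
  for (i in seq_len(nrow(r))) {
    if (is.na(r$p_raw[i])) {
      cat(sprintf("%-8s %2d   %s\n", r$measure[i], r$n_used[i], r$note[i]))
      next
    }
    cat(sprintf(
      "%-8s %2d %6.2f +/- %-5.2f %6.2f +/- %-5.2f %5.0f +/- %-4.0f %7.3f %7.3f%s %6.2f\n",
      r$measure[i], r$n_used[i], r$mean_pre[i], r$sd_pre[i],
      r$mean_post[i], r$sd_post[i], r$pct_change_mean[i],
      r$pct_change_sd[i], r$p_raw[i], r$p_adjusted[i],
      if (r$significant[i]) "*" else " ", r$d[i]
    ))
    removed <- r$outliers_removed[[i]]
    if (length(removed) > 0) {
      cat(sprintf("         outlier(s) removed: %s\n",
                  paste(removed, collapse = ", ")))
    }
  }
  invisible(x)
}
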