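#' Plot methods for exoresist result objects
#'
#' `autoplot()` methods give a quick ggplot2 view of each result type:
#' the commanded torque trace of a controller session, the labelled
#' breath-by-breath power trace with its steady-state window shaded, the
#' resistance/soreness progression across training visits, and the
#' pre/post change per outcome measure.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name exoresist_autoplot
NULL

#' @rdname exoresist_autoplot
#' @param max_time Truncate the torque trace to the first `max_time`
#'   seconds for readability.
#' @method autoplot exo_session
#' @export
autoplot.exo_session <- function(object, max_time = 10, ...) {
  df <- filter(object$torque, .data$time_s <= max_time)
  ggplot(df, aes(x = .data$time_s, y = .data$tau_nm)) +
    geom_line(colour = "steelblue") +
    geom_hline(yintercept = object$prescribed_nm, linetype = "dashed") +
    facet_wrap(~limb, ncol = 1) +
    labs(x = "Time (s)", y = "Applied resistance torque (Nm)",
         title = sprintf("Proportional resistance at r = %.3f Nm/kg",
                         object$resistance),
         subtitle = "Dashed: prescribed level (reached at calibrated peak moment)") +
    theme_minimal()
}

#' @rdname exoresist_autoplot
#' @method autoplot exo_steady_state
#' @export
autoplot.exo_steady_state <- function(object, ...) {
  pts <- object$points
  p <- ggplot(pts, aes(x = .data$time_s, y = .data$power_w))
  if (nrow(object$windows) > 0L) {
    sel <- object$windows[object$windows$selected, ]
    p <- p + annotate(
      "rect",
      xmin = pts$time_s[sel$start], xmax = pts$time_s[sel$end],
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "seagreen"
    )
  }
  p +
    geom_point(aes(colour = .data$label), size = 1) +
    scale_colour_manual(values = c(rising = "firebrick",
                                   falling = "royalblue",
                                   stable = "grey40")) +
    labs(x = "Time (s)", y = "Metabolic power (W)", colour = "Trend",
         title = "Kendall tau-b steady-state classification",
         subtitle = "Shaded: selected steady-state window") +
    theme_minimal()
}

#' @rdname exoresist_autoplot
#' @method autoplot exo_training_course
#' @export
autoplot.exo_training_course <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$visit, y = .data$resistance_nmkg)) +
    geom_step(colour = "grey30") +
    geom_point(aes(colour = .data$soreness), size = 3) +
    scale_colour_manual(values = c(
      "None" = "forestgreen", "Mild" = "gold2", "Moderate" = "orange",
      "Severe" = "darkorange3", "Very Severe" = "firebrick"
    ), drop = FALSE) +
    scale_x_continuous(breaks = df$visit) +
    labs(x = "Training visit", y = "Resistance (Nm/kg)",
         colour = "Soreness",
         title = "Resistance progression across training visits") +
    theme_minimal()
}

#' @rdname exoresist_autoplot
#' @method autoplot exo_trial_stats
#' @export
autoplot.exo_trial_stats <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$pct_change_mean), ]
  ggplot(df, aes(x = .data$measure, y = .data$pct_change_mean,
                 fill = .data$significant)) +
    geom_col(width = 0.6) +
    geom_errorbar(aes(ymin = .data$pct_change_mean - .data$pct_change_sd,
                      ymax = .data$pct_change_mean + .data$pct_change_sd),
                  width = 0.2) +
    geom_hline(yintercept = 0) +
    scale_fill_manual(values = c(`TRUE` = "seagreen", `FALSE` = "grey60"),
                      name = sprintf("p.adj < %g", object$alpha)) +
    labs(x = NULL, y = "Pre-to-post change (%)",
         title = "Outcome changes after resistance training",
         subtitle = "Mean +/- SD of per-participant percent change") +
    theme_minimal()
}
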