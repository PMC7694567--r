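#' Add Brockway metabolic power to a breath series
#'
#' @param breaths A breath tibble with `vo2_mlmin` and `vco2_mlmin`.
#' @param smooth Apply a 5-breath running-median filter to the gas rates
#'   before the power conversion (off by default; breath-by-breath values
#'   are used as reported).
#' @return The tibble with a `power_w` column appended.
#' @examples
#' b <- generate_breath_series("stand", 300, 260, duration = 120, seed = 1)
#' head(breath_power(b))
#' @export
breath_power <- function(breaths, smooth = FALSE) {
  check_columns(breaths, c("vo2_mlmin", "vco2_mlmin"), "breaths")
  vo2 <- breaths$vo2_mlmin
  vco2 <- breaths$vco2_mlmin
  if (isTRUE(smooth) && nrow(breaths) >= 5L) {
    vo2 <- stats::runmed(vo2, 5, endrule = "keep")
    vco2 <- stats::runmed(vco2, 5, endrule = "keep")
  }
  mutate(breaths, power_w = brockway_power(vo2, vco2))
}

#' Classify a metabolic time series as rising, falling, or stable
#'
#' Slides a window of `window` consecutive breaths along the power trace
#' and tests each window for monotone trend against time with Kendall's
#' tau-b. A window is `rising` when `p < alpha` with positive tau,
#' `falling` when negative, and `stable` otherwise — the null hypothesis
#' is that a point lies within a steady-state window, and rejection marks
#' non-steady data. A point is steady when its centred window is stable
#' (the default rule; at the series edges the nearest full window is
#' used), or, under `rule = "all"`, when every window covering it is
#' stable. Steady-state windows are then the maximal runs of steady
#' points at least `window` breaths long. The centred rule is the default
#' because each trend test then vouches only for its own centre point: at
#' the test's own false-positive rate, the stricter all-windows rule lets
#' a single chance rejection disqualify an entire window-length span of
#' genuinely steady breaths.
#'
#' Because tau-b is rank-based, the labels are invariant to affine
#' rescaling of the power trace.
#'
#' @param series A tibble with `time_s` and either `power_w` or the gas
#'   columns needed by [breath_power()].
#' @param window Window length in breaths (>= 5).
#' @param alpha Two-sided significance level for the trend test.
#' @param rule `"centered"` (default) or `"all"`; see Details.
#' @param smooth Passed to [breath_power()] when power must be computed.
#' @return An `exo_steady_state` object: list with `points` (tibble:
#'   `index`, `time_s`, `power_w`, `label`, `steady`, `window_id`),
#'   `windows` (tibble: `window_id`, `start`, `end`, `n`,
#'   `mean_power_w`, `selected`), and the parameters. The selected window
#'   is the longest (ties broken toward the latest).
#' @examples
#' b <- generate_breath_series("walk", 900, 780, noise_sd = 20,
#'                             duration = 360, seed = 1)
#' ss <- classify_steady_state(breath_power(b))
#' ss$windows
#' @export
classify_steady_state <- function(series, window = 20, alpha = 0.05,
                                  rule = c("centered", "all"),
                                  smooth = FALSE) {
  rule <- match.arg(rule)
  check_columns(series, "time_s", "series")
  if (!"power_w" %in% names(series)) series <- breath_power(series, smooth)
  if (!is.numeric(window) || length(window) != 1L || window < 5) {
    stop_invalid("`window` must be a single number >= 5.")
  }
  window <- as.integer(window)
  check_number(alpha, "alpha", min = 0, max = 1,
               strict_min = TRUE, strict_max = TRUE)
  n <- nrow(series)
  if (n < window) {
    abort(sprintf(
      "Series has %d breaths but the trend window needs %d.", n, window
    ), class = "exoresist_insufficient_data")
  }
  if (is.unsorted(series$time_s, strictly = TRUE)) {
    stop_invalid("`time_s` must be strictly increasing.")
  }

  starts <- seq_len(n - window + 1L)
  win_label <- vapply(starts, function(i) {
    idx <- i:(i + window - 1L)
    kt <- kendall_core(series$power_w[idx], series$time_s[idx],
                       exact = FALSE)
    if (kt$p_value < alpha && kt$tau_b > 0) "rising"
    else if (kt$p_value < alpha && kt$tau_b < 0) "falling"
    else "stable"
  }, character(1))

  point_label <- character(n)
  steady <- logical(n)
  for (k in seq_len(n)) {
    covering <- starts[starts <= k & starts + window - 1L >= k]
    if (rule == "centered") {
      centre <- min(max(k - window %/% 2L, 1L), n - window + 1L)
      labs <- win_label[centre]
    } else {
      labs <- win_label[covering]
    }
    if (all(labs == "stable")) {
      steady[k] <- TRUE
      point_label[k] <- "stable"
    } else {
      nr <- sum(labs == "rising")
      nf <- sum(labs == "falling")
      point_label[k] <- if (nr >= nf) "rising" else "falling"
    }
  }

  runs <- rle(steady)
  ends <- cumsum(runs$lengths)
  run_starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= window)
  windows <- tibble(
    window_id = seq_along(keep),
    start = run_starts[keep],
    end = ends[keep],
    n = runs$lengths[keep],
    mean_power_w = vapply(keep, function(i) {
      mean(series$power_w[run_starts[i]:ends[i]])
    }, numeric(1))
  )
  windows$selected <- FALSE
  if (nrow(windows) > 0L) {
    best <- which(windows$n == max(windows$n))
    windows$selected[best[length(best)]] <- TRUE
  }
  window_id <- rep(NA_integer_, n)
  for (i in seq_len(nrow(windows))) {
    window_id[windows$start[i]:windows$end[i]] <- windows$window_id[i]
  }

  structure(
    list(
      points = tibble(
        index = seq_len(n),
        time_s = series$time_s,
        power_w = series$power_w,
        label = point_label,
        steady = steady,
        window_id = window_id
      ),
      windows = windows,
      window = window,
      alpha = alpha,
      rule = rule,
      activity = if ("activity" %in% names(series)) {
        as.character(series$activity[1])
      } else NA_character_
    ),
    class = "exo_steady_state"
  )
}

#' @export
print.exo_steady_state <- function(x, ...) {
  cat(sprintf(
    "<exo_steady_state> %d breaths, window = %d, alpha = %g: %d steady window(s)\n",
    nrow(x$points), x$window, x$alpha, nrow(x$windows)
  ))
  if (nrow(x$windows) > 0L) {
    sel <- x$windows[x$windows$selected, ]
    cat(sprintf(
      "  selected: breaths %d-%d (%.0f-%.0f s), mean power %.1f W\n",
      sel$start, sel$end, x$points$time_s[sel$start],
      x$points$time_s[sel$end], sel$mean_power_w
    ))
  }
  invisible(x)
}

#' @method tidy exo_steady_state
#' @export
tidy.exo_steady_state <- function(x, ...) x$points

#' @method glance exo_steady_state
#' @export
glance.exo_steady_state <- function(x, ...) {
  sel <- steady_state_mean(x, quiet = TRUE)
  tibble(
    n_breaths = nrow(x$points),
    n_steady_windows = nrow(x$windows),
    window = x$window,
    alpha = x$alpha,
    mean_power_w = sel
  )
}

#' Mean power of the selected steady-state window
#'
#' @param x An `exo_steady_state` object.
#' @param quiet Return `NA` silently instead of erroring when no steady
#'   window exists.
#' @return Mean metabolic power of the selected window, W.
#' @export
steady_state_mean <- function(x, quiet = FALSE) {
  stopifnot(inherits(x, "exo_steady_state"))
  if (nrow(x$windows) == 0L) {
    if (quiet) return(NA_real_)
    abort("No steady-state window was found.",
          class = "exoresist_insufficient_data")
  }
  x$windows$mean_power_w[x$windows$selected]
}
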