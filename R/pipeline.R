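#' Configure a full simulated-trial run
#'
#' Collects every tunable of the end-to-end pipeline in one validated
#' list, so a run is fully described by its configuration plus one seed.
#'
#' @param n Cohort size (>= 2).
#' @param effects An [effect_config()].
#' @param sessions Training visits per participant (default 10).
#' @param start_r Starting resistance, Nm/kg.
#' @param increment_nm Progression increment, Nm, in \[0.5, 1\].
#' @param bout_duration Simulated walking bout per visit, s.
#' @param window,alpha_steady Steady-state trend window (breaths) and
#'   significance level.
#' @param alpha Significance level of the outcome battery.
#' @param d_variant Cohen's d variant.
#' @param normality,normality_reps Lilliefors settings for
#'   [analyze_trial()].
#' @param seed Integer seed for the whole run.
#' @param out_dir Optional directory; when set, every artifact is written
#'   as CSV together with a plain-text run log.
#' @return A named list with class `exo_config`.
#' @examples
#' pipeline_config(n = 6, seed = 1)
#' @export
pipeline_config <- function(n = 6,
                            effects = effect_config(),
                            sessions = 10,
                            start_r = 0.05,
                            increment_nm = 0.75,
                            bout_duration = 60,
                            window = 20,
                            alpha_steady = 0.05,
                            alpha = 0.05,
                            d_variant = "dz",
                            normality = TRUE,
                            normality_reps = 10000,
                            seed = 1,
                            out_dir = NULL) {
  stopifnot(inherits(effects, "exo_effects"))
  if (!is.numeric(n) || n < 2) stop_invalid("`n` must be >= 2.")
  structure(
    list(n = as.integer(n), effects = effects, sessions = sessions,
         start_r = start_r, increment_nm = increment_nm,
         bout_duration = bout_duration, window = window,
         alpha_steady = alpha_steady, alpha = alpha,
         d_variant = d_variant, normality = normality,
         normality_reps = normality_reps, seed = seed, out_dir = out_dir),
    class = "exo_config"
  )
}

#' Run the simulated trial end to end
#'
#' Mirrors the study's visit structure: draw a cohort of participant
#' profiles, generate the pre-assessment outcome values, put every
#' participant through the configured number of resistance-training
#' sessions under the progression rules, generate the post-assessment,
#' and run the full statistical battery. Each stage failure aborts with
#' an error naming the stage. The run is a pure function of its
#' configuration (all randomness flows from `config$seed`).
#'
#' @param config An [pipeline_config()] object.
#' @return A list with class `exo_run`: `profiles`, `outcomes` (pre/post
#'   table), `sessions` (all participants' session logs), `stats`
#'   (the [analyze_trial()] fit), `config`, and `log` (character vector
#'   recording package version, seeds, and parameters). With
#'   `config$out_dir` set, all tables plus the log are also written there.
#' @examples
#' run <- run_pipeline(pipeline_config(n = 6, sessions = 2, seed = 1,
#'                                     bout_duration = 20,
#'                                     normality = FALSE))
#' tidy(run$stats)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "exo_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "exoresist_pipeline_error", parent = e)
    })
  }

  cohort <- stage("simulate-cohort", {
    generate_cohort(config$n, config$effects, seed = config$seed)
  })

  sessions <- stage("training", {
    if (config$sessions < 1) {
      tibble(participant = character(0), visit = integer(0),
             resistance_nmkg = numeric(0), resistance_nm = numeric(0),
             engagement = numeric(0), soreness = character(0),
             walk_min = numeric(0))
    } else {
      purrr::map_dfr(seq_len(nrow(cohort$profiles)), function(i) {
        prof <- cohort$profiles[i, ]
        course <- simulate_training_course(
          prof, start_r = config$start_r, sessions = config$sessions,
          increment_nm = config$increment_nm,
          bout_duration = config$bout_duration,
          seed = split_seed(config$seed, paste0("train-", prof$id))
        )
        mutate(as_tibble(course), participant = prof$id,
               soreness = as.character(.data$soreness),
               .before = 1)
      })
    }
  })

  stats <- stage("analyze", {
    analyze_trial(cohort$outcomes, alpha = config$alpha,
                  d_variant = config$d_variant,
                  normality = config$normality,
                  normality_reps = config$normality_reps,
                  seed = split_seed(config$seed, "analyze"))
  })

  log <- c(
    sprintf("exoresist %s", as.character(utils::packageVersion("exoresist"))),
    sprintf("seed: %s", format(config$seed)),
    sprintf("n: %d, sessions: %g, start_r: %g Nm/kg, increment: %g Nm",
            config$n, config$sessions, config$start_r, config$increment_nm),
    sprintf("effects: %s",
            paste(sprintf("%s=%+.2f(sd %.2f)", names(config$effects$effects),
                          config$effects$effects, config$effects$effect_sd),
                  collapse = ", ")),
    sprintf("noise_cv: %g", config$effects$noise_cv),
    sprintf("steady-state window: %d breaths, alpha: %g",
            config$window, config$alpha_steady),
    sprintf("battery alpha: %g, d variant: %s, normality: %s (%d reps)",
            config$alpha, config$d_variant, config$normality,
            config$normality_reps)
  )

  run <- structure(
    list(profiles = cohort$profiles, outcomes = cohort$outcomes,
         sessions = sessions, stats = stats, config = config, log = log),
    class = "exo_run"
  )

  if (!is.null(config$out_dir)) {
    stage("write-outputs", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_outcomes_csv(run$outcomes,
                         file.path(config$out_dir, "outcomes.csv"))
      write_sessions_csv(run$sessions,
                         file.path(config$out_dir, "sessions.csv"))
      readr::write_csv(run$profiles,
                       file.path(config$out_dir, "profiles.csv"))
      results <- tidy(run$stats)
      results$outliers_removed <- vapply(
        results$outliers_removed, paste, character(1), collapse = ";"
      )
      readr::write_csv(results, file.path(config$out_dir, "stat_results.csv"))
      writeLines(run$log, file.path(config$out_dir, "run_log.txt"))
    })
  }
  run
}

#' @export
print.exo_run <- function(x, ...) {
  cat(sprintf(
    "<exo_run> n = %d participants, %g training sessions each, seed %s\n",
    x$config$n, x$config$sessions, format(x$config$seed)
  ))
  print(x$stats)
  invisible(x)
}
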