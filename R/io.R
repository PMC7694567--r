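# Typed CSV readers/writers for every artifact the pipeline exchanges.
# One fixed schema per artifact; readers validate columns, types, and
# monotone time, and fail with the offending column named.

gait_schema <- c(time_s = "d", limb = "c", force_n = "d", moment_nm = "d")
breath_schema <- c(time_s = "d", vo2_mlmin = "d", vco2_mlmin = "d",
                   activity = "c")
outcomes_schema <- c(participant = "c", measure = "c", pre = "d", post = "d")
session_schema <- c(participant = "c", visit = "d", resistance_nmkg = "d",
                    resistance_nm = "d", engagement = "d", soreness = "c",
                    walk_min = "d")

read_typed_csv <- function(path, schema, name) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("File not found: %s", path))
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(names(schema), header)
  if (length(missing) > 0L) {
    abort(sprintf("%s file %s lacks column(s): %s.", name, path,
                  paste0("`", missing, "`", collapse = ", ")),
          class = "exoresist_parse_error")
  }
  cols <- do.call(readr::cols_only, as.list(schema))
  df <- suppressWarnings(
    readr::read_csv(path, col_types = cols, locale = readr::locale(),
                    progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf(
      "%s file %s failed to parse: column `%s` row %d (%s). Note: decimals must use `.`, not `,`.",
      name, path, names(schema)[probs$col[1]], probs$row[1],
      probs$expected[1]
    ), class = "exoresist_parse_error")
  }
  numeric_cols <- names(schema)[schema == "d"]
  bad <- numeric_cols[vapply(numeric_cols, function(cn) anyNA(df[[cn]]),
                             logical(1))]
  bad <- setdiff(bad, "post") # missing post marks a missed assessment
  if (length(bad) > 0L) {
    abort(sprintf("%s file %s has missing values in `%s`.",
                  name, path, bad[1]),
          class = "exoresist_parse_error")
  }
  as_tibble(df)
}

check_monotone_time <- function(df, group_col, path) {
  groups <- if (is.null(group_col)) list(seq_len(nrow(df))) else
    split(seq_len(nrow(df)), df[[group_col]])
  for (idx in groups) {
    if (is.unsorted(df$time_s[idx], strictly = TRUE)) {
      abort(sprintf("`time_s` in %s is not strictly increasing%s.", path,
                    if (is.null(group_col)) "" else " within a limb"),
            class = "exoresist_validation_error")
    }
  }
  invisible(df)
}

#' Read and write pipeline CSV artifacts
#'
#' Fixed, versionless schemas (UTF-8, RFC-4180, dot decimals, time in
#' seconds as floats): gait trials (`time_s, limb, force_n, moment_nm`),
#' breath series (`time_s, vo2_mlmin, vco2_mlmin, activity`), outcome
#' tables (`participant, measure, pre, post`; empty `post` marks a missed
#' assessment), and training-session logs (`visit, resistance_nmkg,
#' resistance_nm, engagement, soreness, walk_min`). Readers validate the
#' header, column types, and strict time monotonicity where required, and
#' raise classed parse/validation errors naming the offending column.
#' Writer/reader pairs round-trip losslessly at full double precision.
#'
#' @param path File path.
#' @param x The tibble to write.
#' @return Readers return a validated tibble; writers return `x`
#'   invisibly.
#' @name exoresist_io
#' @examples
#' f <- tempfile(fileext = ".csv")
#' trial <- generate_gait_trial(participant_profile(), duration = 2, seed = 1)
#' write_gait_csv(trial, f)
#' identical(nrow(read_gait_csv(f)), nrow(trial))
NULL

#' @rdname exoresist_io
#' @export
read_gait_csv <- function(path) {
  df <- read_typed_csv(path, gait_schema, "Gait-trial")
  check_monotone_time(df, "limb", path)
  if (any(df$force_n < 0)) {
    abort(sprintf("`force_n` in %s must be >= 0.", path),
          class = "exoresist_validation_error")
  }
  df
}

#' @rdname exoresist_io
#' @export
write_gait_csv <- function(x, path) {
  check_columns(x, names(gait_schema), "x")
  readr::write_csv(x[names(gait_schema)], path)
  invisible(x)
}

#' @rdname exoresist_io
#' @export
read_breath_csv <- function(path) {
  df <- read_typed_csv(path, breath_schema, "Breath-series")
  check_monotone_time(df, NULL, path)
  df
}

#' @rdname exoresist_io
#' @export
write_breath_csv <- function(x, path) {
  check_columns(x, names(breath_schema), "x")
  readr::write_csv(x[names(breath_schema)], path)
  invisible(x)
}

#' @rdname exoresist_io
#' @export
read_outcomes_csv <- function(path) {
  read_typed_csv(path, outcomes_schema, "Outcome-table")
}

#' @rdname exoresist_io
#' @export
write_outcomes_csv <- function(x, path) {
  check_columns(x, names(outcomes_schema), "x")
  readr::write_csv(x[names(outcomes_schema)], path)
  invisible(x)
}

#' @rdname exoresist_io
#' @export
read_sessions_csv <- function(path) {
  read_typed_csv(path, session_schema, "Session-log")
}

#' @rdname exoresist_io
#' @export
write_sessions_csv <- function(x, path) {
  if (!"participant" %in% names(x)) {
    x$participant <- attr(x, "participant") %||% NA_character_
  }
  check_columns(x, names(session_schema), "x")
  out <- as_tibble(x)[names(session_schema)]
  out$soreness <- as.character(out$soreness)
  readr::write_csv(out, path)
  invisible(x)
}
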