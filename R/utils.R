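# Internal argument checking helpers. All user-facing errors go through
# rlang::abort with a class so callers can condition on them.

stop_invalid <- function(msg, ...) {
  abort(msg, class = "exoresist_invalid_argument", ...)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single non-missing number.", name))
  }
  low_ok <- if (strict_min) x > min else x >= min
  high_ok <- if (strict_max) x < max else x <= max
  if (!low_ok || !high_ok) {
    stop_invalid(sprintf(
      "`%s` must be in %s%s, %s%s; got %g.",
      name, if (strict_min) "(" else "[", format(min),
      format(max), if (strict_max) ")" else "]", x
    ))
  }
  invisible(x)
}

check_numeric_vector <- function(x, name, min_length = 1L, min = -Inf) {
  if (!is.numeric(x) || length(x) < min_length || anyNA(x)) {
    stop_invalid(sprintf(
      "`%s` must be a numeric vector of length >= %d with no missing values.",
      name, min_length
    ))
  }
  if (any(x < min)) {
    stop_invalid(sprintf("`%s` must be >= %g everywhere.", name, min))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_invalid(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic per-stream seed derivation: one user-facing seed feeds many
# independent generator streams without any stream reusing another's draws.
# The map is a fixed affine hash into [1, 2^31 - 2] (valid set.seed() range).
split_seed <- function(seed, stream) {
  check_number(seed, "seed")
  stopifnot(is.character(stream), length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% m
  ((as.double(seed) %% m) * 48271 + h * 16807 + 12345) %% (m - 1) + 1
}
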