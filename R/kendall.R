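#' Kendall's tau-b rank correlation with tie correction
#'
#' Computes tau-b between two vectors together with a two-sided p-value
#' for the null of no monotone association. Concordant/discordant pairs
#' are counted with Knight's O(n log n) merge-sort algorithm rather than
#' pairwise enumeration; ties in either variable enter through the
#' standard tau-b denominator `sqrt((n0 - n1)(n0 - n2))`. The p-value uses
#' the normal approximation with the tie-adjusted variance of S, or exact
#' enumeration of the permutation distribution of S for small samples
#' (`n <= 8` by default), which remains valid under ties.
#'
#' This is the trend test behind steady-state detection in breath-by-breath
#' gas-exchange data: within a sliding window, a significantly positive
#' tau of the metabolic signal against time means the window is still
#' rising, a significantly negative tau falling, and otherwise stable.
#'
#' @param x Numeric vector of values (length >= 3 for a test).
#' @param t Numeric vector of the same length (typically time).
#' @param exact Use exact permutation enumeration for the p-value; default
#'   for `n <= 8`. Ignored (normal approximation) for larger n.
#' @return A one-row tibble: `tau_b`, `p_value`, `s` (C - D), `n`,
#'   `degenerate` (TRUE when either variable is entirely tied, in which
#'   case `tau_b = 0`, `p_value = 1`), `method`.
#' @examples
#' kendall_tau_b(c(1, 2, 2, 3), 1:4)
#' @export
kendall_tau_b <- function(x, t, exact = NULL) {
  check_numeric_vector(x, "x", min_length = 2L)
  check_numeric_vector(t, "t", min_length = 2L)
  if (length(x) != length(t)) {
    stop_invalid("`x` and `t` must have the same length.")
  }
  res <- kendall_core(x, t, exact)
  as_tibble(res)
}

# Computation without validation or tibble overhead; the sliding-window
# steady-state classifier calls this once per window.
kendall_core <- function(x, t, exact = NULL) {
  n <- length(x)
  if (is.null(exact)) exact <- n <= 8L
  n0 <- n * (n - 1) / 2
  n1 <- tie_pairs(t)
  n2 <- tie_pairs(x)

  if (n0 == n1 || n0 == n2) {
    return(list(tau_b = 0, p_value = 1, s = 0, n = n,
                degenerate = TRUE, method = "degenerate"))
  }

  n3 <- tie_pairs_joint(t, x) # pairs tied in both
  # order by (t, then x); inversions of x in that order are discordant
  ord <- order(t, x)
  nd <- count_inversions(x[ord])
  nc <- n0 - nd - n1 - n2 + n3
  s <- nc - nd
  tau_b <- s / sqrt((n0 - n1) * (n0 - n2))

  if (n < 3L) {
    return(list(tau_b = tau_b, p_value = NA_real_, s = s, n = n,
                degenerate = FALSE, method = "too-small"))
  }
  if (exact && n <= 8L) {
    p <- kendall_exact_p(x, t, s)
    method <- "exact"
  } else {
    p <- kendall_normal_p(x, t, s)
    method <- "normal"
  }
  list(tau_b = tau_b, p_value = p, s = s, n = n,
       degenerate = FALSE, method = method)
}

tie_pairs <- function(v) {
  cnt <- tabulate(match(v, unique(v)))
  sum(cnt * (cnt - 1)) / 2
}

tie_pairs_joint <- function(a, b) {
  key <- match(a, unique(a)) * (length(b) + 1) + match(b, unique(b))
  tie_pairs(key)
}

# Merge-sort inversion count: number of pairs i < j with y[i] > y[j]
# (strict; equal values are not inversions).
count_inversions <- function(y) {
  n <- length(y)
  inv <- 0
  width <- 1L
  buf <- numeric(n)
  while (width < n) {
    lo <- 1L
    while (lo + width <= n) {
      mid <- lo + width - 1L
      hi <- min(mid + width, n)
      i <- lo; j <- mid + 1L; k <- lo
      while (i <= mid && j <= hi) {
        if (y[j] < y[i]) {
          inv <- inv + (mid - i + 1L)
          buf[k] <- y[j]; j <- j + 1L
        } else {
          buf[k] <- y[i]; i <- i + 1L
        }
        k <- k + 1L
      }
      if (i <= mid) buf[k:hi] <- y[i:mid]
      if (j <= hi) buf[k:hi] <- y[j:hi]
      y[lo:hi] <- buf[lo:hi]
      lo <- hi + 1L
    }
    width <- width * 2L
  }
  inv
}

# Tie-adjusted variance of S under the null (Kendall's formula), then a
# two-sided normal p-value.
kendall_normal_p <- function(x, t, s) {
  n <- length(x)
  ti <- tabulate(match(t, unique(t)))
  ui <- tabulate(match(x, unique(x)))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(ti * (ti - 1) * (2 * ti + 5))
  vu <- sum(ui * (ui - 1) * (2 * ui + 5))
  v1 <- sum(ti * (ti - 1)) * sum(ui * (ui - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(ti * (ti - 1) * (ti - 2)) * sum(ui * (ui - 1) * (ui - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  if (var_s <= 0) return(1)
  min(1, 2 * pnorm(-abs(s) / sqrt(var_s)))
}

# Exact two-sided p: P(|S_perm| >= |S_obs|) over all n! relabelings of x
# against t. Valid with ties (the multiset of x is fixed).
kendall_exact_p <- function(x, t, s_obs) {
  n <- length(x)
  perms <- perm_matrix(n)
  sx <- sign(outer(x, x, "-"))
  st <- sign(outer(t, t, "-"))
  s_all <- numeric(nrow(perms))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s_all <- s_all + st[i, j] * sx[cbind(perms[, i], perms[, j])]
    }
  }
  mean(abs(s_all) >= abs(s_obs) - 1e-9)
}

perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}
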