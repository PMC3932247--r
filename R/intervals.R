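# Closed-interval helpers shared by area and proportion scoring.
# Intervals are length-2 numeric vectors c(lower, upper); interval sets are
# 2-column matrices with one row per disjoint interval.

# Merge a set of closed intervals into disjoint ones (touching intervals merge).
.merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("lower", "upper"))))
  }
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  lo <- m[1L, 1L]
  hi <- m[1L, 2L]
  out <- list()
  if (nrow(m) > 1L) {
    for (r in 2L:nrow(m)) {
      if (m[r, 1L] <= hi) {
        hi <- max(hi, m[r, 2L])
      } else {
        out[[length(out) + 1L]] <- c(lo, hi)
        lo <- m[r, 1L]
        hi <- m[r, 2L]
      }
    }
  }
  out[[length(out) + 1L]] <- c(lo, hi)
  res <- do.call(rbind, out)
  dimnames(res) <- list(NULL, c("lower", "upper"))
  res
}

# Closed membership of values in a disjoint interval set.
.in_intervals <- function(x, m) {
  if (nrow(m) == 0L) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  for (r in seq_len(nrow(m))) {
    inside <- inside | (x >= m[r, 1L] & x <= m[r, 2L])
  }
  inside
}

# Class processing order for the asymmetric pair formulas: ascending lower
# bound, ties by upper bound, then class index ("sorted" mode), or the
# original label order ("literal" mode).
.class_order <- function(lo, hi, mode) {
  if (mode == "literal") seq_along(lo) else order(lo, hi, seq_along(lo))
}

# Shared inverse-max normalization: 1 - x / max(x), with the convention that
# an all-zero vector maps to 1 everywhere (no feature is penalized).
.inv_max_norm <- function(x) {
  m <- max(x)
  if (m <= 0) rep(1, length(x)) else 1 - x / m
}
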