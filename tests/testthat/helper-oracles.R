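# Independent oracles and instance generators used across the suite.
# Everything here deliberately takes the slow, literal route (per-sample and
# per-pair loops, Monte-Carlo measure) so it shares no code with the package
# internals it checks.

# Random small labeled dataset: l classes with random per-class means and
# standard deviations per feature.
rand_instance <- function(seed, d = 3L, l_range = 2:5, n_range = 3:6) {
  set.seed(seed)
  l <- sample(l_range, 1L)
  n_per <- sample(n_range, l, replace = TRUE)
  cls <- rep(seq_len(l), n_per)
  mu <- matrix(runif(d * l, -3, 3), d, l)
  sd <- matrix(runif(d * l, 0.2, 2), d, l)
  x <- vapply(seq_len(d), function(i) {
    rnorm(length(cls), mu[i, cls], sd[i, cls])
  }, numeric(length(cls)))
  labeled_matrix(x, paste0("C", cls))
}

# Build an effective_range_table directly from interval matrices (for tests
# that exercise the area/region layer with hand-picked geometry).
range_table <- function(lower, upper, gamma = chebyshev_gamma(2 / 3)) {
  lower <- rbind(lower)
  upper <- rbind(upper)
  structure(
    list(lower = lower, upper = upper, gamma = gamma,
         classes = paste0("C", seq_len(ncol(lower))),
         feature_names = paste0("F", seq_len(nrow(lower)))),
    class = "effective_range_table"
  )
}

# Does any sorted class pair of feature i form an inclusion configuration?
has_inclusion <- function(ranges, i) {
  lo <- ranges$lower[i, ]
  hi <- ranges$upper[i, ]
  ord <- order(lo, hi, seq_along(lo))
  l <- length(lo)
  for (a in seq_len(l - 1L)) {
    for (b in (a + 1L):l) {
      if (hi[ord[a]] >= hi[ord[b]]) return(TRUE)
    }
  }
  FALSE
}

# Exact oracle: sum over unordered class pairs of the length of the interval
# intersection (equals the sorted-mode overlapping area when no pair is an
# inclusion configuration).
oa_intersection_sum <- function(ranges, i) {
  lo <- ranges$lower[i, ]
  hi <- ranges$upper[i, ]
  l <- length(lo)
  tot <- 0
  for (j in seq_len(l - 1L)) {
    for (k in (j + 1L):l) {
      tot <- tot + max(0, min(hi[j], hi[k]) - max(lo[j], lo[k]))
    }
  }
  tot
}

# Monte-Carlo interval-measure oracle: sample points uniformly over the hull
# of all class ranges, estimate each pairwise intersection length as hull
# width times the fraction of points inside both intervals.
oa_monte_carlo <- function(ranges, i, m = 5000L) {
  lo <- ranges$lower[i, ]
  hi <- ranges$upper[i, ]
  hl <- min(lo)
  hu <- max(hi)
  if (hu <= hl) return(0)
  x <- runif(m, hl, hu)
  l <- length(lo)
  tot <- 0
  for (j in seq_len(l - 1L)) {
    for (k in (j + 1L):l) {
      inside <- x >= lo[j] & x <= hi[j] & x >= lo[k] & x <= hi[k]
      tot <- tot + mean(inside) * (hu - hl)
    }
  }
  tot
}

# Brute-force overlap counts: for every sample of class j, test membership in
# every pairwise intersection of class j's range with another class's range.
brute_h_counts <- function(data, ranges) {
  lo <- ranges$lower
  hi <- ranges$upper
  d <- nrow(lo)
  l <- ncol(lo)
  cls <- as.integer(data$labels)
  h <- matrix(0L, d, l)
  for (i in seq_len(d)) {
    for (j in seq_len(l)) {
      for (x in data$values[cls == j, i]) {
        for (k in seq_len(l)[-j]) {
          a <- max(lo[i, j], lo[i, k])
          b <- min(hi[i, j], hi[i, k])
          if (a <= b && x >= a && x <= b) {
            h[i, j] <- h[i, j] + 1L
            break
          }
        }
      }
    }
  }
  h
}

# Brute-force inclusion counts under the sorted orientation: enumerate fired
# inclusion pairs per feature, then test each sample of the relevant class
# against the included range.
brute_g_counts <- function(data, ranges, count_includer = FALSE) {
  lo <- ranges$lower
  hi <- ranges$upper
  d <- nrow(lo)
  l <- ncol(lo)
  cls <- as.integer(data$labels)
  g <- matrix(0L, d, l)
  for (i in seq_len(d)) {
    ord <- order(lo[i, ], hi[i, ], seq_len(l))
    pairs <- list()
    for (a in seq_len(l - 1L)) {
      for (b in (a + 1L):l) {
        if (hi[i, ord[a]] >= hi[i, ord[b]]) {
          pairs[[length(pairs) + 1L]] <- c(ord[a], ord[b])
        }
      }
    }
    for (j in seq_len(l)) {
      xs <- data$values[cls == j, i]
      for (x in xs) {
        hit <- FALSE
        for (p in pairs) {
          counted <- p[2L] == j || (count_includer && p[1L] == j)
          if (counted && x >= lo[i, p[2L]] && x <= hi[i, p[2L]]) hit <- TRUE
        }
        g[i, j] <- g[i, j] + hit
      }
    }
  }
  g
}
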