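#' Overlap region of one class for one feature
#'
#' The part of class `class_j`'s effective range that other classes' ranges
#' also cover: the union over all other classes `k` of the pairwise
#' intersections \eqn{R_{ij} \cap R_{ik}}, returned as a set of disjoint
#' closed intervals. Samples of class j falling here are the ones the
#' overlapping-area statistic flags as confusable; they are counted by
#' [proportion_scores()].
#'
#' @param ranges An `effective_range_table`.
#' @param feature Feature index (or name).
#' @param class_j Class index (or class name).
#' @return A 2-column matrix (`lower`, `upper`) of disjoint intervals;
#'   zero rows when the class range is disjoint from all others.
#' @examples
#' d <- labeled_matrix(matrix(c(0, 2, 1, 3), ncol = 1),
#'                     c("A", "A", "B", "B"))
#' r <- effective_ranges(compute_class_stats(d))
#' overlap_region(r, 1, "A")
#' @export
overlap_region <- function(ranges, feature, class_j) {
  stopifnot(inherits(ranges, "effective_range_table"))
  i <- .resolve_index(feature, ranges$feature_names, "feature")
  j <- .resolve_index(class_j, ranges$classes, "class")
  lo <- ranges$lower[i, ]
  hi <- ranges$upper[i, ]
  pieces <- list()
  for (k in seq_along(lo)) {
    if (k == j) next
    a <- max(lo[j], lo[k])
    b <- min(hi[j], hi[k])
    if (a <= b) pieces[[length(pieces) + 1L]] <- c(a, b)
  }
  .merge_intervals(do.call(rbind, pieces))
}

#' Inclusion region of one class for one feature
#'
#' The region in which class `class_j`'s samples sit inside an inclusion
#' configuration: for every oriented class pair whose inclusion test fires
#' (the same orientation as [area_decomposition()]) and whose included class
#' is `class_j`, the included range (class j's own effective range)
#' contributes. With `count_includer = TRUE` pairs where `class_j` is the
#' including class also contribute the nested range, so samples of the outer
#' class falling into the inner class's range are counted too.
#'
#' @inheritParams overlap_region
#' @param mode Pair orientation, as in [area_decomposition()].
#' @param count_includer Also include the nested range for pairs where
#'   `class_j` is the outer (including) class. Default `FALSE`: only the
#'   included class's own membership is counted.
#' @return A 2-column matrix of disjoint closed intervals (possibly a single
#'   zero-width point when the included range is degenerate).
#' @examples
#' d <- labeled_matrix(matrix(c(-4, 4, -1, 1), ncol = 1),
#'                     c("A", "A", "B", "B"))
#' r <- effective_ranges(compute_class_stats(d))
#' inclusion_region(r, 1, "B")  # B's range is nested inside A's
#' @export
inclusion_region <- function(ranges, feature, class_j,
                             mode = c("sorted", "literal"),
                             count_includer = FALSE) {
  stopifnot(inherits(ranges, "effective_range_table"))
  mode <- match.arg(mode)
  i <- .resolve_index(feature, ranges$feature_names, "feature")
  j <- .resolve_index(class_j, ranges$classes, "class")
  lo <- ranges$lower[i, ]
  hi <- ranges$upper[i, ]
  ord <- .class_order(lo, hi, mode)
  l <- length(lo)
  pieces <- list()
  for (a in seq_len(l - 1L)) {
    for (b in (a + 1L):l) {
      ja <- ord[a]
      jb <- ord[b]
      if (hi[ja] >= hi[jb]) {  # inclusion fires; jb is the included class
        if (jb == j || (count_includer && ja == j)) {
          pieces[[length(pieces) + 1L]] <- c(lo[jb], hi[jb])
        }
      }
    }
  }
  .merge_intervals(do.call(rbind, pieces))
}

.resolve_index <- function(x, names, what) {
  if (is.character(x)) {
    i <- match(x, names)
    if (is.na(i)) stop("unknown ", what, ": ", x)
    return(i)
  }
  i <- as.integer(x)
  if (is.na(i) || i < 1L || i > length(names)) {
    stop(what, " index out of range: ", x)
  }
  i
}

#' Sample-proportion scores in overlap and inclusion regions
#'
#' Counts, per feature and class, how many class-j samples fall (closed
#' boundaries) in the class's overlap region (`H`) and inclusion region
#' (`G`), forms the per-feature totals
#' \eqn{H_i = \sum_j H_{ij} / K_j} and \eqn{G_i = \sum_j G_{ij} / K_j},
#' and normalizes them to
#' \eqn{NH_i = 1 - H_i / \max_s H_s}, \eqn{GH_i = 1 - G_i / \max_s G_s}.
#' Features whose regions trap few samples score close to 1 (good); when no
#' feature traps any sample the normalized score is 1 everywhere.
#'
#' @param data The [labeled_matrix()] the statistics were computed from.
#' @param stats Its `class_feature_stats`.
#' @param ranges Its `effective_range_table`.
#' @param mode Pair orientation for the inclusion regions, as in
#'   [area_decomposition()].
#' @param count_includer Passed to [inclusion_region()].
#' @return An object of class `proportion_scores`: `h_counts`, `g_counts`
#'   (`d x l` integer matrices), `h_total`, `g_total` (length-`d`, each in
#'   `[0, l]`), and `nh`, `gh` (length-`d`, in `[0, 1]`).
#' @examples
#' d <- labeled_matrix(matrix(c(0.5, 1.5, 1.6, 2.5), ncol = 1),
#'                     c("A", "A", "B", "B"))
#' s <- compute_class_stats(d)
#' proportion_scores(d, s, effective_ranges(s))
#' @export
proportion_scores <- function(data, stats, ranges,
                              mode = c("sorted", "literal"),
                              count_includer = FALSE) {
  stopifnot(inherits(data, "labeled_matrix"),
            inherits(stats, "class_feature_stats"),
            inherits(ranges, "effective_range_table"))
  mode <- match.arg(mode)
  d <- ncol(data$values)
  l <- length(stats$classes)
  if (nrow(ranges$lower) != d || ncol(ranges$lower) != l ||
      !identical(ranges$classes, levels(data$labels))) {
    stop("`data`, `stats` and `ranges` do not describe the same problem")
  }
  k_j <- stats$class_size
  h <- g <- matrix(0L, nrow = d, ncol = l,
                   dimnames = list(data$feature_names, stats$classes))
  class_rows <- lapply(seq_len(l), function(j) data$labels == stats$classes[j])
  for (i in seq_len(d)) {
    xi <- data$values[, i]
    for (j in seq_len(l)) {
      xj <- xi[class_rows[[j]]]
      ov <- overlap_region(ranges, i, j)
      h[i, j] <- sum(.in_intervals(xj, ov))
      inc <- inclusion_region(ranges, i, j, mode = mode,
                              count_includer = count_includer)
      g[i, j] <- sum(.in_intervals(xj, inc))
    }
  }
  h_total <- as.numeric(h %*% (1 / k_j))
  g_total <- as.numeric(g %*% (1 / k_j))
  nh <- .inv_max_norm(h_total)
  gh <- .inv_max_norm(g_total)
  names(h_total) <- names(g_total) <- names(nh) <- names(gh) <-
    data$feature_names
  structure(
    list(h_counts = h, g_counts = g, h_total = h_total, g_total = g_total,
         nh = nh, gh = gh, mode = mode, count_includer = count_includer),
    class = "proportion_scores"
  )
}

#' @export
print.proportion_scores <- function(x, ...) {
  cat("proportion_scores (", length(x$nh), " features, mode = ", x$mode,
      ")\n", sep = "")
  print(utils::head(data.frame(h = x$h_total, g = x$g_total,
                               nh = x$nh, gh = x$gh)))
  if (length(x$nh) > 6L) cat("... (", length(x$nh) - 6L, " more)\n", sep = "")
  invisible(x)
}
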