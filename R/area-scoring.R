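#' Pairwise overlap length between two class effective ranges
#'
#' The overlap contribution of an ordered pair of class ranges:
#' \eqn{\phi(j, k) = r_j^+ - r_k^-} if \eqn{r_j^+ > r_k^-}, else 0.
#' This is the literal asymmetric formula; inside [area_decomposition()] it is
#' applied after the class pair has been oriented (see `mode` there). For a
#' pair sorted by lower bound and without inclusion it equals the length of
#' the interval intersection; in an inclusion configuration it exceeds it.
#'
#' @param range_j,range_k Length-2 numeric vectors `c(lower, upper)` with
#'   `lower <= upper`.
#' @return Non-negative scalar.
#' @examples
#' pairwise_phi(c(0, 2), c(1, 3))  # 1
#' pairwise_phi(c(0, 1), c(2, 3))  # 0 (disjoint)
#' @export
pairwise_phi <- function(range_j, range_k) {
  .check_interval(range_j)
  .check_interval(range_k)
  if (range_j[2L] > range_k[1L]) range_j[2L] - range_k[1L] else 0
}

#' Pairwise inclusion width between two class effective ranges
#'
#' The inclusion contribution of an ordered pair:
#' \eqn{\psi(j, k) = r_k^+ - r_k^-} (the full width of range k) if
#' \eqn{r_j^+ \ge r_k^+}, else 0. After the pairs are sorted by lower bound
#' the condition \eqn{r_j^+ \ge r_k^+} coincides with range k being nested
#' inside range j, the configuration the overlap measure alone cannot see.
#'
#' @inheritParams pairwise_phi
#' @return Non-negative scalar (0 when range k is not included).
#' @examples
#' pairwise_psi(c(0, 4), c(1, 2))  # 1: range k nested, its width counts
#' pairwise_psi(c(0, 2), c(1, 3))  # 0: partial overlap only
#' @export
pairwise_psi <- function(range_j, range_k) {
  .check_interval(range_j)
  .check_interval(range_k)
  if (range_j[2L] >= range_k[2L]) range_k[2L] - range_k[1L] else 0
}

.check_interval <- function(r) {
  if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1L] > r[2L]) {
    stop("an interval must be c(lower, upper) with lower <= upper")
  }
  invisible(r)
}

#' Per-feature area decomposition of class effective ranges
#'
#' For each feature, sums the pairwise overlap lengths (OA) and inclusion
#' widths (IA) over all class pairs, and normalizes:
#' \deqn{SA_i = OA_i + IA_i, \quad
#'       AC_i = SA_i / (\max_j r_{ij}^+ - \min_j r_{ij}^-), \quad
#'       NAC_i = 1 - AC_i / \max_s AC_s.}
#' Small AC (little overlap/inclusion relative to the hull of all class
#' ranges) means a discriminative feature, so NAC close to 1 is good.
#'
#' @param ranges An `effective_range_table` from [effective_ranges()].
#' @param mode `"sorted"` (default): per feature, classes are processed in
#'   ascending order of lower bound (ties by upper bound, then class index)
#'   before the asymmetric pair formulas are applied, so that overlap is
#'   measured left-to-right and the inclusion condition matches true nesting.
#'   `"literal"`: pairs taken in the original class order, formulas verbatim.
#' @param include_ia If `FALSE`, the inclusion term is dropped (`ia` is all
#'   zeros and `sa = oa`), which is exactly the ERGS scoring.
#' @param exclusive If `TRUE`, when a pair fires both the overlap and the
#'   inclusion formula, the included width is subtracted from the overlap
#'   contribution so the nested region is not counted twice. The default
#'   `FALSE` keeps the formulas as printed.
#'
#' @return An object of class `area_scores`: list of per-feature vectors
#'   `oa`, `ia`, `sa`, `ac`, `nac` (named by feature) plus the `mode` used.
#'   Conventions for degenerate inputs: a zero-width hull (all class ranges
#'   the same single point) gives `ac = 0`; if every feature has `ac = 0`,
#'   `nac` is 1 everywhere.
#' @examples
#' d <- labeled_matrix(matrix(c(0, 2, 4, 6, 1, 2, 3, 4), ncol = 2),
#'                     c("A", "A", "B", "B"))
#' area_decomposition(effective_ranges(compute_class_stats(d)))
#' @seealso [ergs_weights()], [ifser_weights()]
#' @export
area_decomposition <- function(ranges, mode = c("sorted", "literal"),
                               include_ia = TRUE, exclusive = FALSE) {
  stopifnot(inherits(ranges, "effective_range_table"))
  mode <- match.arg(mode)
  d <- nrow(ranges$lower)
  l <- ncol(ranges$lower)
  oa <- ia <- numeric(d)
  hull <- numeric(d)
  for (i in seq_len(d)) {
    lo <- ranges$lower[i, ]
    hi <- ranges$upper[i, ]
    ord <- .class_order(lo, hi, mode)
    lo <- lo[ord]
    hi <- hi[ord]
    s_oa <- 0
    s_ia <- 0
    for (j in seq_len(l - 1L)) {
      for (k in (j + 1L):l) {
        phi <- if (hi[j] > lo[k]) hi[j] - lo[k] else 0
        psi <- if (hi[j] >= hi[k]) hi[k] - lo[k] else 0
        if (exclusive && phi > 0 && psi > 0) phi <- max(phi - psi, 0)
        s_oa <- s_oa + phi
        s_ia <- s_ia + psi
      }
    }
    oa[i] <- s_oa
    ia[i] <- s_ia
    hull[i] <- max(hi) - min(lo)
  }
  if (!include_ia) ia <- numeric(d)
  sa <- oa + ia
  ac <- ifelse(hull > 0, sa / hull, 0)
  nac <- .inv_max_norm(ac)
  names(oa) <- names(ia) <- names(sa) <- names(ac) <- names(nac) <-
    ranges$feature_names
  structure(
    list(oa = oa, ia = ia, sa = sa, ac = ac, nac = nac, mode = mode,
         include_ia = include_ia, exclusive = exclusive),
    class = "area_scores"
  )
}

#' ERGS feature weights
#'
#' The effective-range based gene selection weight: the normalized area
#' coefficient computed from the overlapping area alone (no inclusion term,
#' no sample proportions). Larger is more discriminative.
#'
#' @inheritParams area_decomposition
#' @return Named numeric vector of length `d` with weights in `[0, 1]`.
#' @examples
#' d <- labeled_matrix(matrix(c(0, 2, 4, 6, 1, 2, 3, 4), ncol = 2),
#'                     c("A", "A", "B", "B"))
#' ergs_weights(effective_ranges(compute_class_stats(d)))
#' @export
ergs_weights <- function(ranges, mode = c("sorted", "literal")) {
  mode <- match.arg(mode)
  area_decomposition(ranges, mode = mode, include_ia = FALSE)$nac
}

#' @export
print.area_scores <- function(x, ...) {
  cat("area_scores (", length(x$oa), " features, mode = ", x$mode, ")\n",
      sep = "")
  print(utils::head(data.frame(oa = x$oa, ia = x$ia, ac = x$ac, nac = x$nac)))
  if (length(x$oa) > 6L) cat("... (", length(x$oa) - 6L, " more)\n", sep = "")
  invisible(x)
}
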