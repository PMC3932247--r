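#' IFSER feature weights and ranking
#'
#' Runs the full scoring pipeline on a labeled matrix: class statistics,
#' effective ranges, area decomposition (overlap + inclusion), sample
#' proportions, and the final weight
#' \deqn{W_i = V_i \times Z_i, \quad V_i = NAC_i, \quad Z_i = NH_i + GH_i.}
#' Features are ranked by descending weight, ties broken by ascending
#' feature index, so the result is deterministic for a fixed input and flags.
#'
#' @param data A [labeled_matrix()].
#' @param gamma Effective-range multiplier; default `chebyshev_gamma(2/3)`
#'   = 1.732.
#' @param mode Class-pair orientation, see [area_decomposition()].
#' @param sd_method,prior Passed to [compute_class_stats()].
#' @param include_ia Include the inclusion-area term (`FALSE` drops it).
#' @param use_proportions Multiply by `Z = NH + GH` (`FALSE` fixes `Z = 1`).
#'   With both `include_ia = FALSE` and `use_proportions = FALSE` the result
#'   is exactly the ERGS weighting.
#' @param exclusive,count_includer Scoring variants, see
#'   [area_decomposition()] and [inclusion_region()].
#'
#' @return An object of class `feature_weights`: per-feature vectors `v`,
#'   `z`, `w` (in `[0, 2]` for IFSER, `[0, 1]` for ERGS), the `ranking`
#'   (permutation of feature indices by descending `w`), a `method` tag
#'   (`"ifser"`, `"ergs"` or `"custom"`), and the intermediate `areas` and
#'   `proportions` objects.
#' @examples
#' set.seed(1)
#' x <- cbind(sep = c(rnorm(10, -5), rnorm(10, 5)), noise = rnorm(20))
#' d <- labeled_matrix(x, rep(c("A", "B"), each = 10))
#' w <- ifser_weights(d)
#' w$ranking[1]  # the separated feature ranks first
#' @seealso [select_top_k()], [ergs_weights()], [evaluate_loocv()]
#' @export
ifser_weights <- function(data, gamma = chebyshev_gamma(2 / 3),
                          mode = c("sorted", "literal"),
                          sd_method = c("sample", "population"), prior = NULL,
                          include_ia = TRUE, use_proportions = TRUE,
                          exclusive = FALSE, count_includer = FALSE) {
  mode <- match.arg(mode)
  sd_method <- match.arg(sd_method)
  stats <- compute_class_stats(data, sd_method = sd_method, prior = prior)
  ranges <- effective_ranges(stats, gamma = gamma)
  areas <- area_decomposition(ranges, mode = mode, include_ia = include_ia,
                              exclusive = exclusive)
  v <- areas$nac
  if (use_proportions) {
    props <- proportion_scores(data, stats, ranges, mode = mode,
                               count_includer = count_includer)
    z <- props$nh + props$gh
  } else {
    props <- NULL
    z <- rep(1, length(v))
    names(z) <- names(v)
  }
  w <- v * z
  method <- if (include_ia && use_proportions) {
    "ifser"
  } else if (!include_ia && !use_proportions) {
    "ergs"
  } else {
    "custom"
  }
  structure(
    list(v = v, z = z, w = w,
         ranking = order(-w, seq_along(w)),
         method = method, gamma = gamma, mode = mode,
         areas = areas, proportions = props,
         feature_names = data$feature_names),
    class = "feature_weights"
  )
}

#' Rank features by IFSER or ERGS
#'
#' Convenience front end: `method = "ifser"` is the full pipeline,
#' `method = "ergs"` the overlap-only weighting with `Z` fixed to 1.
#'
#' @inheritParams ifser_weights
#' @param method `"ifser"` or `"ergs"`.
#' @param ... Further arguments passed to [ifser_weights()].
#' @return A `feature_weights` object.
#' @export
rank_features <- function(data, method = c("ifser", "ergs"),
                          gamma = chebyshev_gamma(2 / 3), ...) {
  method <- match.arg(method)
  if (method == "ergs") {
    ifser_weights(data, gamma = gamma, include_ia = FALSE,
                  use_proportions = FALSE, ...)
  } else {
    ifser_weights(data, gamma = gamma, ...)
  }
}

#' Select the top-k ranked features
#'
#' @param weights A `feature_weights` object.
#' @param k Number of features to keep, between 1 and `d`.
#' @return Integer vector of `k` feature indices (1-based), in rank order.
#' @examples
#' set.seed(1)
#' d <- labeled_matrix(matrix(rnorm(40), 20), rep(c("A", "B"), each = 10))
#' select_top_k(ifser_weights(d), 1)
#' @export
select_top_k <- function(weights, k) {
  stopifnot(inherits(weights, "feature_weights"))
  d <- length(weights$w)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) ||
      k < 1 || k > d) {
    stop("`k` must be an integer between 1 and ", d)
  }
  weights$ranking[seq_len(as.integer(k))]
}

#' @export
print.feature_weights <- function(x, ...) {
  cat("feature_weights: method = ", x$method, ", gamma = ", format(x$gamma),
      ", ", length(x$w), " features\n", sep = "")
  top <- utils::head(x$ranking)
  cat("top features: ",
      paste0(x$feature_names[top], " (w=", signif(x$w[top], 4), ")",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.feature_weights <- function(x, ...) {
  d <- length(x$w)
  rank <- integer(d)
  rank[x$ranking] <- seq_len(d)
  df <- data.frame(
    name = x$feature_names,
    index = seq_len(d),
    oa = x$areas$oa,
    ia = x$areas$ia,
    ac = x$areas$ac,
    nac = x$areas$nac,
    nh = if (is.null(x$proportions)) NA_real_ else x$proportions$nh,
    gh = if (is.null(x$proportions)) NA_real_ else x$proportions$gh,
    w = x$w,
    rank = rank,
    row.names = NULL
  )
  df[order(df$rank), ]
}
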