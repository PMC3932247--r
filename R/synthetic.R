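#' Specification for a synthetic class-labeled dataset
#'
#' Describes a dataset in the regime of the gene-expression benchmarks the
#' method targets: few samples (tens per class), many features, and a small
#' minority of class-separating features hidden among noise. Two kinds of
#' informative features are planted: mean-shift features (class means
#' separated by `separation` standard deviations) and inclusion-type features
#' (equal class means but class variances in ratio `variance_ratio`, so one
#' class's effective range nests inside another's — the configuration the
#' inclusion area is designed to detect).
#'
#' @param n_per_class Integer vector of samples per class (length = number of
#'   classes, each at least 2). Default two classes of 50.
#' @param d_total Total number of features (default 200).
#' @param d_informative Number of planted informative features (default 20).
#' @param separation Between-class mean shift of mean-shift features, in
#'   units of `noise_sigma` (default 3).
#' @param noise_sigma Standard deviation of the noise features and of the
#'   narrowest class (default 1).
#' @param inclusion_fraction Fraction of the informative features built as
#'   inclusion-type instead of mean-shift (default 0).
#' @param variance_ratio Variance ratio between consecutive classes of an
#'   inclusion-type feature (default 4, i.e. standard deviations in ratio 2).
#' @param family `"gaussian"` (default) or `"t"` for scaled Student-t noise
#'   (heavy tails, exercising the distribution-free Chebyshev construction).
#' @param t_df Degrees of freedom for `family = "t"` (must exceed 2).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_spec` (a validated list).
#' @seealso [generate_labeled_matrix()]
#' @export
synthetic_spec <- function(n_per_class = c(50, 50), d_total = 200,
                           d_informative = 20, separation = 3,
                           noise_sigma = 1, inclusion_fraction = 0,
                           variance_ratio = 4,
                           family = c("gaussian", "t"), t_df = 3, seed = 1) {
  family <- match.arg(family)
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) < 2L || any(n_per_class < 2L)) {
    stop("`n_per_class` needs at least 2 classes with at least 2 samples each")
  }
  if (d_informative < 0 || d_informative > d_total) {
    stop("`d_informative` must lie in [0, d_total]")
  }
  if (noise_sigma <= 0) stop("`noise_sigma` must be positive")
  if (inclusion_fraction < 0 || inclusion_fraction > 1) {
    stop("`inclusion_fraction` must lie in [0, 1]")
  }
  if (variance_ratio < 1) stop("`variance_ratio` must be >= 1")
  if (family == "t" && t_df <= 2) stop("`t_df` must exceed 2 (finite variance)")
  structure(
    list(n_per_class = n_per_class, d_total = as.integer(d_total),
         d_informative = as.integer(d_informative), separation = separation,
         noise_sigma = noise_sigma, inclusion_fraction = inclusion_fraction,
         variance_ratio = variance_ratio, family = family, t_df = t_df,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic labeled matrix with planted informative features
#'
#' Draws class-conditional continuous features per a [synthetic_spec()]:
#' noise features are identically distributed across classes; mean-shift
#' informative features shift the class means by `separation * noise_sigma`
#' per class; inclusion-type informative features keep equal means but scale
#' the class standard deviation by `sqrt(variance_ratio)` per class, so the
#' population effective ranges are strictly nested. Generation is
#' deterministic in `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `data` (a [labeled_matrix()]),
#'   `informative` (sorted integer indices of all planted features),
#'   `shift_features` and `inclusion_features` (the two subsets).
#' @examples
#' g <- generate_labeled_matrix(synthetic_spec(n_per_class = c(5, 5),
#'                                             d_total = 10, d_informative = 2,
#'                                             seed = 7))
#' g$informative
#' @export
generate_labeled_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  l <- length(spec$n_per_class)
  n <- sum(spec$n_per_class)
  d <- spec$d_total
  labels <- factor(rep(paste0("C", seq_len(l)), spec$n_per_class))

  informative <- sort(sample.int(d, spec$d_informative))
  n_incl <- as.integer(round(spec$inclusion_fraction * spec$d_informative))
  inclusion_features <- if (n_incl > 0L) {
    informative[seq(spec$d_informative - n_incl + 1L, spec$d_informative)]
  } else {
    integer(0)
  }
  shift_features <- setdiff(informative, inclusion_features)

  rnoise <- function(m) {
    if (spec$family == "t") {
      stats::rt(m, df = spec$t_df) / sqrt(spec$t_df / (spec$t_df - 2))
    } else {
      stats::rnorm(m)
    }
  }

  class_of <- as.integer(labels)
  x <- matrix(rnoise(n * d), nrow = n, ncol = d) * spec$noise_sigma
  for (i in shift_features) {
    x[, i] <- x[, i] + (class_of - 1L) * spec$separation * spec$noise_sigma
  }
  sd_scale <- sqrt(spec$variance_ratio)^(class_of - 1L)
  for (i in inclusion_features) {
    x[, i] <- x[, i] * sd_scale
  }
  colnames(x) <- paste0("F", seq_len(d))
  list(
    data = labeled_matrix(x, labels),
    informative = informative,
    shift_features = shift_features,
    inclusion_features = inclusion_features
  )
}
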