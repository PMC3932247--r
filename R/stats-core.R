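#' Per-class, per-feature summary statistics
#'
#' Computes, for every feature and every class, the mean and standard
#' deviation over exactly the samples of that class, together with the class
#' priors and class sizes. These are the ingredients of the effective range
#' \eqn{\mu_{ij} \pm (1 - p_j)\,\gamma\,\sigma_{ij}}.
#'
#' @param data A [labeled_matrix()].
#' @param sd_method `"sample"` (default) for the unbiased n-1 denominator or
#'   `"population"` for the n denominator. With the few samples per class
#'   typical of expression data the sample convention is the safer default.
#' @param prior Optional length-`l` numeric vector of class priors overriding
#'   the empirical frequencies `K_j / N`. Must be non-negative and sum to 1;
#'   order follows `levels(data$labels)`.
#'
#' @return An object of class `class_feature_stats`: list with `mu` and
#'   `sigma` (`d x l` matrices, features in rows, classes in columns),
#'   `prior` (length `l`), `class_size` (integer counts `K_j`), `classes`
#'   (class names), and `feature_names`.
#'
#' @details Every class must contain at least 2 samples so that the standard
#'   deviation is defined; violations raise an error naming the class.
#'
#' @examples
#' d <- labeled_matrix(matrix(c(0, 2, 4, 6), ncol = 1), c("A", "A", "B", "B"))
#' s <- compute_class_stats(d)
#' s$mu     # 1 and 5
#' s$prior  # 0.5 0.5
#' @export
compute_class_stats <- function(data, sd_method = c("sample", "population"),
                                prior = NULL) {
  stopifnot(inherits(data, "labeled_matrix"))
  sd_method <- match.arg(sd_method)
  x <- data$values
  y <- data$labels
  classes <- levels(y)
  l <- length(classes)
  k <- as.integer(table(y))
  if (any(k < 2L)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(classes[k < 2L], collapse = ", "))
  }
  n <- nrow(x)

  sums <- rowsum(x, y)            # l x d, ordered by levels(y)
  mu <- t(sums) / rep(k, each = ncol(x))
  sq <- t(rowsum(x * x, y))       # d x l sums of squares
  css <- sq - mu * mu * rep(k, each = nrow(mu))  # centered sum of squares
  css[css < 0] <- 0               # guard tiny negative round-off
  denom <- if (sd_method == "sample") k - 1L else k
  sigma <- sqrt(css / rep(denom, each = nrow(css)))

  if (is.null(prior)) {
    prior <- k / n
  } else {
    if (length(prior) != l || any(prior < 0) || abs(sum(prior) - 1) > 1e-8) {
      stop("`prior` must be a length-", l,
           " non-negative vector summing to 1 (class order: ",
           paste(classes, collapse = ", "), ")")
    }
    prior <- as.numeric(prior)
  }

  dimnames(mu) <- dimnames(sigma) <- list(data$feature_names, classes)
  structure(
    list(mu = mu, sigma = sigma, prior = prior, class_size = k,
         classes = classes, feature_names = data$feature_names,
         n_samples = n, sd_method = sd_method),
    class = "class_feature_stats"
  )
}

#' Chebyshev multiplier for a guaranteed coverage fraction
#'
#' By the Chebyshev inequality \eqn{P(|X - \mu| \ge \gamma\sigma) \le
#' 1/\gamma^2}, valid for any distribution with finite variance, the interval
#' \eqn{\mu \pm \gamma\sigma} contains at least a fraction `min_fraction` of
#' the probability mass when \eqn{\gamma = \sqrt{1 / (1 -
#' \code{min_fraction})}}. This is the smallest multiplier the bound
#' certifies.
#'
#' @param min_fraction Required coverage, strictly between 0 and 1.
#' @return The multiplier \eqn{\gamma} (positive scalar).
#' @examples
#' chebyshev_gamma(2 / 3)  # 1.732..., the default used for effective ranges
#' chebyshev_gamma(3 / 4)  # 2
#' @export
chebyshev_gamma <- function(min_fraction) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      !is.finite(min_fraction) || min_fraction <= 0 || min_fraction >= 1) {
    stop("`min_fraction` must be a single number strictly between 0 and 1")
  }
  sqrt(1 / (1 - min_fraction))
}

#' Per-class effective ranges
#'
#' Builds the effective range of class \eqn{j} for feature \eqn{i},
#' \deqn{R_{ij} = [\mu_{ij} - (1 - p_j)\gamma\sigma_{ij},\;
#'                 \mu_{ij} + (1 - p_j)\gamma\sigma_{ij}],}
#' the interval where that class's values concentrate. The factor
#' \eqn{1 - p_j} shrinks the interval of high-prior (hence typically
#' high-variance) classes; \eqn{\gamma} comes from the Chebyshev bound and
#' defaults to `chebyshev_gamma(2/3)` = 1.732.
#'
#' @param stats A `class_feature_stats` object from [compute_class_stats()].
#' @param gamma Positive range multiplier.
#' @return An object of class `effective_range_table`: list with `lower` and
#'   `upper` (`d x l` matrices), `gamma`, `classes`, `feature_names`.
#'   Zero-width intervals occur exactly where `sigma` is 0.
#' @examples
#' d <- labeled_matrix(matrix(c(0, 2, 4, 6), ncol = 1), c("A", "A", "B", "B"))
#' effective_ranges(compute_class_stats(d))
#' @export
effective_ranges <- function(stats, gamma = chebyshev_gamma(2 / 3)) {
  stopifnot(inherits(stats, "class_feature_stats"))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0) {
    stop("`gamma` must be a single positive number")
  }
  half <- sweep(stats$sigma, 2L, (1 - stats$prior) * gamma, "*")
  structure(
    list(lower = stats$mu - half, upper = stats$mu + half, gamma = gamma,
         classes = stats$classes, feature_names = stats$feature_names),
    class = "effective_range_table"
  )
}

#' @export
print.effective_range_table <- function(x, ...) {
  cat("effective_range_table: ", nrow(x$lower), " features x ",
      ncol(x$lower), " classes, gamma = ", format(x$gamma), "\n", sep = "")
  invisible(x)
}
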