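#' Construct a labeled feature matrix
#'
#' The universal input container of the package: an `N x d` numeric matrix of
#' feature values (samples in rows) together with one categorical class label
#' per sample. Labels are stored as a factor; the set of factor levels defines
#' the class order used throughout (class statistics, effective ranges,
#' region counts).
#'
#' @param values Numeric matrix, `N` samples by `d` features. A data frame of
#'   numeric columns is accepted and coerced.
#' @param labels Vector of length `N` with the class of each sample (character,
#'   factor, or anything coercible to factor). At least two distinct classes
#'   are required.
#' @param feature_names Character vector of length `d`; defaults to
#'   `colnames(values)` or `F1..Fd` when absent. Must be unique.
#'
#' @return An object of class `labeled_matrix`: a list with elements
#'   `values` (numeric matrix with `feature_names` as column names),
#'   `labels` (factor of length `N`), and `feature_names`.
#'
#' @details Missing or non-finite values are rejected here; imputation is an
#'   explicit ingest option of [read_labeled_matrix()], never a silent default.
#'
#' @examples
#' x <- matrix(rnorm(20), nrow = 10)
#' d <- labeled_matrix(x, rep(c("A", "B"), each = 5))
#' d
#' @seealso [compute_class_stats()], [ifser_weights()], [read_labeled_matrix()]
#' @export
labeled_matrix <- function(values, labels, feature_names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x features)")
  }
  n <- nrow(values)
  d <- ncol(values)
  if (n < 2L) stop("at least 2 samples are required")
  if (d < 1L) stop("at least 1 feature is required")
  if (length(labels) != n) {
    stop("`labels` must have one entry per sample (", n, "), got ", length(labels))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at sample ", bad[1L], ", feature ", bad[2L],
         "; use read_labeled_matrix(impute = TRUE) for missing-value handling")
  }
  labels <- factor(labels)
  if (anyNA(labels)) stop("missing class labels are not allowed")
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("at least 2 distinct classes are required")
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) feature_names <- paste0("F", seq_len(d))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != d) stop("`feature_names` must have length ", d)
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  colnames(values) <- feature_names
  structure(
    list(values = values, labels = labels, feature_names = feature_names),
    class = "labeled_matrix"
  )
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat("labeled_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " features, ", nlevels(x$labels), " classes\n", sep = "")
  tab <- table(x$labels)
  cat("classes: ", paste(names(tab), " (n=", tab, ")", sep = "", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

# Standardize each feature to zero mean / unit sd across all samples
# (constant features are left centered only).
.standardize_features <- function(values) {
  mu <- colMeans(values)
  sd <- apply(values, 2L, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(values, 2L, mu, "-"), 2L, sd, "/")
}
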