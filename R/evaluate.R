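#' Leave-one-out cross-validated accuracy over a grid of subset sizes
#'
#' Evaluates a feature-selection method the way filter selectors are
#' benchmarked: for each left-out sample, features are ranked on the
#' remaining samples only (leakage-safe), the top `k` are kept, a classifier
#' is trained on the reduced training data and the held-out sample is
#' predicted. Accuracy is reported per classifier and per `k`.
#'
#' @param data A [labeled_matrix()].
#' @param k_grid Integer vector of subset sizes (each between 1 and `d`).
#' @param classifiers Character vector naming classifiers from the registry:
#'   `"nn"` (1-nearest-neighbor, via \pkg{class}), `"tree"` (CART decision
#'   tree, via \pkg{rpart}), `"svm"` (linear support-vector machine, via
#'   \pkg{e1071}). The classifiers are external implementations; this
#'   package only supplies the selection step.
#' @param method Ranking method, `"ifser"` or `"ergs"`.
#' @param gamma Effective-range multiplier.
#' @param rank_scope `"fold"` (default): re-rank inside every fold on the
#'   training samples only. `"global"`: rank once on the full data — faster
#'   and common in the literature, but the held-out sample then influences
#'   the ranking, so use it only for comparability.
#' @param ... Further scoring flags passed to [rank_features()].
#' @return A data frame with one row per classifier and one column per `k`
#'   (plus the `classifier` column); entries are accuracies in `[0, 1]`.
#' @examples
#' \donttest{
#' g <- generate_labeled_matrix(synthetic_spec(n_per_class = c(10, 10),
#'                                             d_total = 30, d_informative = 5,
#'                                             seed = 1))
#' evaluate_loocv(g$data, k_grid = c(5, 10), classifiers = "nn")
#' }
#' @export
evaluate_loocv <- function(data, k_grid = c(10, 30, 50),
                           classifiers = c("nn", "tree", "svm"),
                           method = c("ifser", "ergs"),
                           gamma = chebyshev_gamma(2 / 3),
                           rank_scope = c("fold", "global"), ...) {
  stopifnot(inherits(data, "labeled_matrix"))
  method <- match.arg(method)
  rank_scope <- match.arg(rank_scope)
  n <- nrow(data$values)
  d <- ncol(data$values)
  k_grid <- as.integer(k_grid)
  if (any(k_grid < 1L) || any(k_grid > d)) {
    stop("every k must lie between 1 and ", d)
  }
  fits <- lapply(classifiers, .classifier)
  names(fits) <- classifiers

  global_w <- if (rank_scope == "global") {
    rank_features(data, method = method, gamma = gamma, ...)
  }

  correct <- array(0L, dim = c(length(classifiers), length(k_grid)),
                   dimnames = list(classifiers, k_grid))
  for (s in seq_len(n)) {
    train <- labeled_matrix(data$values[-s, , drop = FALSE],
                            data$labels[-s], data$feature_names)
    w <- if (rank_scope == "fold") {
      rank_features(train, method = method, gamma = gamma, ...)
    } else {
      global_w
    }
    for (ki in seq_along(k_grid)) {
      idx <- select_top_k(w, k_grid[ki])
      xtr <- train$values[, idx, drop = FALSE]
      xte <- data$values[s, idx, drop = FALSE]
      for (cl in classifiers) {
        pred <- fits[[cl]](xtr, train$labels, xte)
        if (as.character(pred) == as.character(data$labels[s])) {
          correct[cl, ki] <- correct[cl, ki] + 1L
        }
      }
    }
  }
  acc <- correct / n
  out <- data.frame(classifier = classifiers,
                    acc, check.names = FALSE, row.names = NULL)
  names(out)[-1L] <- paste0("k", k_grid)
  out
}

# Name-keyed classifier registry. Each entry: function(xtr, ytr, xte) -> label.
.classifier <- function(name) {
  switch(
    name,
    nn = {
      .need("class", name)
      function(xtr, ytr, xte) class::knn(xtr, xte, ytr, k = 1L)
    },
    tree = {
      .need("rpart", name)
      function(xtr, ytr, xte) {
        df <- data.frame(.y = ytr, xtr, check.names = TRUE)
        nd <- data.frame(xte, check.names = TRUE)
        names(nd) <- names(df)[-1L]
        fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = rpart::rpart.control(minsplit = 5L,
                                                           cp = 0.01,
                                                           xval = 0L))
        predict(fit, nd, type = "class")
      }
    },
    svm = {
      .need("e1071", name)
      function(xtr, ytr, xte) {
        fit <- e1071::svm(x = xtr, y = ytr, kernel = "linear", scale = FALSE)
        predict(fit, xte)
      }
    },
    stop("unknown classifier '", name, "' (available: nn, tree, svm)")
  )
}

.need <- function(pkg, clf) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("classifier '", clf, "' needs the '", pkg, "' package")
  }
}
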