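#' Read a labeled matrix from delimited text
#'
#' Reads a CSV/TSV feature matrix with class labels. Two layouts are
#' supported: samples in rows (default; one column, named by `label_column`,
#' holds the class labels and every other column is a numeric feature) and
#' features in rows (the common gene-expression layout: first column holds
#' feature names, header holds sample identifiers, and one row named
#' `label_column` holds the class labels; the matrix is transposed on
#' ingest).
#'
#' @param path Path to the delimited file.
#' @param label_column Name of the column (or row, for `features_in_rows`)
#'   holding class labels. Default `"class"`.
#' @param delimiter Field separator; `NULL` (default) infers `","` for
#'   `.csv` and tab otherwise.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @param impute If `TRUE`, missing feature values are replaced by the
#'   feature's mean over the non-missing samples; if `FALSE` (default),
#'   missing values are an error listing the offending cells.
#' @param standardize If `TRUE`, each feature is centered and scaled to unit
#'   standard deviation after ingest (off by default; the scoring itself is
#'   shift-invariant per feature, so this mainly matters for cross-feature
#'   comparability of raw areas).
#' @return A [labeled_matrix()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(g1 = c(1, 2, 3, 4), g2 = c(5, 6, 7, 8),
#'                      class = c("A", "A", "B", "B")), f, row.names = FALSE)
#' read_labeled_matrix(f)
#' @export
read_labeled_matrix <- function(path, label_column = "class",
                                delimiter = NULL,
                                orientation = c("samples_in_rows",
                                                "features_in_rows"),
                                impute = FALSE, standardize = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "#")
  if (orientation == "samples_in_rows") {
    if (!label_column %in% names(raw)) {
      stop("label column '", label_column, "' not found in ", path)
    }
    labels <- raw[[label_column]]
    feature_names <- names(raw)[names(raw) != label_column]
    feat <- raw[, names(raw) != label_column, drop = FALSE]
    names(feat) <- feature_names  # undo the renaming `[` applies to duplicates
    values <- .numeric_matrix(feat, rows_are = "sample", path = path,
                              impute = impute)
  } else {
    feature_names <- raw[[1L]]
    body <- raw[-1L]
    is_label <- feature_names == label_column
    if (sum(is_label) != 1L) {
      stop("expected exactly one row named '", label_column, "' in ", path)
    }
    labels <- as.character(unlist(body[is_label, ], use.names = FALSE))
    feat <- as.data.frame(t(body[!is_label, , drop = FALSE]),
                          stringsAsFactors = FALSE)
    names(feat) <- feature_names[!is_label]
    values <- .numeric_matrix(feat, rows_are = "sample", path = path,
                              impute = impute)
    feature_names <- feature_names[!is_label]
  }
  if (standardize) values <- .standardize_features(values)
  labeled_matrix(values, labels, feature_names)
}

# Convert a character data frame to a numeric matrix, with cell-accurate
# diagnostics for non-numeric entries and explicit missing-value policy.
.numeric_matrix <- function(feat, rows_are, path, impute) {
  d <- length(feat)
  n <- nrow(feat)
  values <- matrix(NA_real_, nrow = n, ncol = d)
  missing_cells <- character(0)
  for (c in seq_len(d)) {
    v <- trimws(feat[[c]])
    empty <- is.na(v) | v == "" | v == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", feat[[c]][bad[1L]], "' at ", rows_are, " ",
           bad[1L], ", feature '", names(feat)[c], "' in ", path)
    }
    if (any(empty)) {
      missing_cells <- c(missing_cells,
                         paste0(rows_are, " ", which(empty), ", feature '",
                                names(feat)[c], "'"))
      if (impute) num[empty] <- mean(num[!empty])
    }
    values[, c] <- num
  }
  if (length(missing_cells) && !impute) {
    stop("missing values (set impute = TRUE to fill with feature means): ",
         paste(utils::head(missing_cells, 10L), collapse = "; "),
         if (length(missing_cells) > 10L) " ...")
  }
  values
}

#' Write a labeled matrix to delimited text
#'
#' Writes samples in rows with a trailing label column, at full double
#' precision (`%.17g`), so that a write/read round trip reproduces the
#' values exactly.
#'
#' @param data A [labeled_matrix()].
#' @param path Output path; `.csv` selects comma separation, anything else
#'   tab (or pass `delimiter`).
#' @param label_column Name for the label column (default `"class"`).
#' @param delimiter Field separator override.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(data, path, label_column = "class",
                                 delimiter = NULL) {
  stopifnot(inherits(data, "labeled_matrix"))
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  txt <- matrix(sprintf("%.17g", data$values), nrow = nrow(data$values))
  df <- as.data.frame(txt, stringsAsFactors = FALSE)
  names(df) <- data$feature_names
  df[[label_column]] <- as.character(data$labels)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a feature-ranking report
#'
#' Tab-separated report with one row per feature, sorted by rank, preceded
#' by a commented header block recording the method, gamma, scoring flags
#' and a fingerprint of the input data. Indices are 1-based.
#'
#' @param weights A `feature_weights` object from [ifser_weights()] or
#'   [rank_features()].
#' @param path Output path.
#' @param data Optional [labeled_matrix()] the weights were computed from;
#'   when given, its dimensions and a content fingerprint go into the header.
#' @return `path`, invisibly.
#' @export
write_ranking_report <- function(weights, path, data = NULL) {
  stopifnot(inherits(weights, "feature_weights"))
  df <- as.data.frame(weights)
  num <- vapply(df, is.numeric, logical(1L)) & names(df) != "index" &
    names(df) != "rank"
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  header <- c(
    paste0("# method: ", weights$method),
    paste0("# gamma: ", sprintf("%.10g", weights$gamma)),
    paste0("# flags: mode=", weights$mode,
           " include_ia=", weights$areas$include_ia,
           " exclusive=", weights$areas$exclusive,
           if (!is.null(weights$proportions)) {
             paste0(" count_includer=", weights$proportions$count_includer)
           } else {
             " proportions=off"
           }),
    if (!is.null(data)) paste0("# data: ", .data_fingerprint(data))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Cheap deterministic content fingerprint: dimensions plus two moments.
.data_fingerprint <- function(data) {
  v <- data$values
  sprintf("N=%d d=%d l=%d sum=%.10e sumsq=%.10e", nrow(v), ncol(v),
          nlevels(data$labels), sum(v), sum(v * v))
}

#' Read a ranking report back as a data frame
#'
#' @param path Path written by [write_ranking_report()].
#' @return A data frame with the report columns; header lines are exposed in
#'   the `"header"` attribute.
#' @export
read_ranking_report <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "header") <- hdr
  df
}
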