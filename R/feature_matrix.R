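#' Construct a feature matrix
#'
#' The basic data container of the package: an `N x d` numeric matrix of
#' sample features (rows are samples, columns are features such as region-mean
#' image intensities), with optional binary class labels.
#'
#' @param values Numeric matrix or data frame, `N x d`, all entries finite.
#' @param sample_ids Optional character vector of `N` sample identifiers;
#'   defaults to existing row names or `s1..sN`.
#' @param feature_names Optional character vector of `d` distinct feature
#'   names; defaults to existing column names or `x1..xd`.
#' @param labels Optional vector of class labels, length `N`.
#' @return An object of class `feature_matrix`: a list with elements `values`
#'   (named numeric matrix) and `labels` (or `NULL`).
#' @examples
#' fm <- feature_matrix(matrix(rnorm(20), 5, 4), labels = c(1, 1, 0, 0, 1))
#' dim(fm$values)
#' @export
feature_matrix <- function(values, sample_ids = NULL, feature_names = NULL,
                           labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("feature values must be finite: offending entry at row %d, column %d",
                 bad[[1L]], bad[[2L]]))
  }
  if (nrow(values) < 2L) stop("a feature matrix needs at least 2 samples")
  if (ncol(values) < 1L) stop("a feature matrix needs at least 1 feature")
  sample_ids <- sample_ids %||% rownames(values) %||%
    paste0("s", seq_len(nrow(values)))
  feature_names <- feature_names %||% colnames(values) %||%
    paste0("x", seq_len(ncol(values)))
  if (length(sample_ids) != nrow(values)) stop("sample_ids length mismatch")
  if (length(feature_names) != ncol(values)) stop("feature_names length mismatch")
  if (anyDuplicated(feature_names)) stop("duplicated feature names")
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_names))
  if (!is.null(labels)) {
    if (length(labels) != nrow(values)) stop("labels length mismatch")
    if (anyNA(labels)) stop("labels must not contain missing values")
  }
  structure(list(values = values, labels = labels), class = "feature_matrix")
}

#' Coerce to a feature matrix
#'
#' @param x A `feature_matrix`, numeric matrix or data frame.
#' @param ... Passed on to [feature_matrix()].
#' @return A `feature_matrix`.
#' @export
as_feature_matrix <- function(x, ...) {
  if (inherits(x, "feature_matrix")) return(x)
  feature_matrix(x, ...)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(", labels: %s",
                        paste(names(table(x$labels)), table(x$labels),
                              sep = "=", collapse = ", "))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Internal: binary label encoding into {-1, +1}. The positive class is the
# lexicographically (or numerically) larger label unless overridden.
encode_labels <- function(labels, positive_class = NULL) {
  if (is.null(labels)) stop("labels are required for this operation")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) {
    stop(sprintf("degenerate labels: need exactly 2 classes, found %d (%s)",
                 length(lev), paste(lev, collapse = ", ")))
  }
  if (!is.null(positive_class)) {
    positive_class <- as.character(positive_class)
    if (!positive_class %in% lev) stop("positive_class not among the labels")
    lev <- c(setdiff(lev, positive_class), positive_class)
  }
  y <- ifelse(as.character(labels) == lev[2L], 1, -1)
  list(y = y, negative = lev[1L], positive = lev[2L])
}
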