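#' Read a feature table from CSV
#'
#' Expects one header row of feature names, one row per sample, and an
#' optional label column. Missing or non-numeric values are rejected with an
#' error naming the offending row and column.
#'
#' @param path Path to a CSV file.
#' @param label_col Name of the label column, default `"label"`; absent
#'   columns simply yield an unlabeled table.
#' @param id_col Optional name of a sample-id column.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path, label_col = "label", id_col = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  sample_ids <- NULL
  if (!is.null(id_col) && id_col %in% names(df)) {
    sample_ids <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
  }
  if (label_col %in% names(df)) {
    labels <- df[[label_col]]
    if (anyNA(labels)) {
      stop(sprintf("missing value in column '%s', row %d", label_col,
                   which(is.na(labels))[1L]))
    }
    df[[label_col]] <- NULL
  }
  for (nm in names(df)) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      suppressWarnings(v2 <- as.numeric(v))
      if (anyNA(v2) && !anyNA(v)) {
        stop(sprintf("non-numeric value in column '%s', row %d", nm,
                     which(is.na(v2))[1L]))
      }
      v <- v2
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s', row %d", nm,
                   which(is.na(v))[1L]))
    }
    df[[nm]] <- v
  }
  feature_matrix(as.matrix(df), sample_ids = sample_ids, labels = labels)
}

#' Write a feature table to CSV
#'
#' Numeric values are written as 17-significant-digit decimal strings, so a
#' write-then-read round trip reproduces every double exactly.
#'
#' @param data A [feature_matrix()].
#' @param path Output CSV path.
#' @param label_col Name for the label column when labels are present.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, label_col = "label") {
  data <- as_feature_matrix(data)
  chr <- apply(data$values, c(1L, 2L), function(v) sprintf("%.17g", v))
  df <- as.data.frame(chr, stringsAsFactors = FALSE)
  names(df) <- colnames(data$values)
  if (!is.null(data$labels)) df[[label_col]] <- as.character(data$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted TSK classifier to JSON
#'
#' The schema stores the antecedent (centers, spreads, activation mask, tau,
#' h), the consequent (mode, lambda, per-rule coefficient arrays), the label
#' map, the full fitting configuration and the package version. Floats are
#' written at full precision, so a save/load round trip reproduces scores
#' exactly.
#'
#' @param model A fitted `tsk_classifier`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tsk_classifier"))
  obj <- list(
    antecedent = list(
      centers = unname(model$antecedent$centers),
      spreads = unname(model$antecedent$spreads),
      active = unname(model$antecedent$active),
      tau = model$antecedent$threshold,
      h = model$antecedent$spread_scale,
      feature_names = model$antecedent$feature_names
    ),
    consequent = list(
      mode = model$consequent$mode,
      lambda = model$consequent$ridge,
      coefficients = lapply(model$consequent$coefficients, unname)
    ),
    labels = list(negative = model$consequent$negative,
                  positive = model$consequent$positive),
    standardize = model$standardize,
    config = model$config,
    software_version = as.character(utils::packageVersion("tskfs"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

as_row_matrix <- function(x, K) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, x))
  matrix(x, nrow = K)  # K = 1 degenerates to a plain vector in JSON
}

#' Load a TSK classifier from JSON
#'
#' @param path Path to a model JSON written by [write_model()].
#' @return A `tsk_classifier` (without the training `clustering` state).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("antecedent", "consequent", "labels")) {
    if (is.null(obj[[field]])) stop(sprintf("malformed model JSON: missing field '%s'", field))
  }
  K <- obj$config$n_rules %||% NROW(obj$antecedent$centers)
  centers <- as_row_matrix(obj$antecedent$centers, K)
  spreads <- as_row_matrix(obj$antecedent$spreads, K)
  active <- as_row_matrix(obj$antecedent$active, K)
  storage.mode(active) <- "logical"
  fn <- obj$antecedent$feature_names
  dimnames(centers) <- dimnames(spreads) <- dimnames(active) <- list(NULL, fn)
  antecedent <- structure(list(centers = centers, spreads = spreads,
                               active = active,
                               threshold = obj$antecedent$tau,
                               spread_scale = obj$antecedent$h,
                               feature_names = fn),
                          class = "antecedent_model")
  coefs <- obj$consequent$coefficients
  if (is.matrix(coefs)) {
    # equal-length per-rule arrays simplify to a matrix, one rule per row
    coefs <- lapply(seq_len(nrow(coefs)), function(k) coefs[k, ])
  } else if (!is.list(coefs)) {
    coefs <- list(coefs)
  }
  consequent <- structure(list(coefficients = lapply(coefs, as.numeric),
                               mode = obj$consequent$mode,
                               ridge = obj$consequent$lambda,
                               negative = obj$labels$negative,
                               positive = obj$labels$positive),
                          class = "consequent_model")
  std <- obj$standardize
  if (is.null(std) || length(std$center) == 0L) {
    std <- NULL
  } else {
    std <- list(center = as.numeric(std$center),
                scale = as.numeric(std$scale))
  }
  structure(list(antecedent = antecedent, consequent = consequent,
                 clustering = NULL, standardize = std, config = obj$config),
            class = "tsk_classifier")
}

#' Serialize a clustering state to JSON
#'
#' Shape metadata (`C`, `N`, `d`) is stored explicitly alongside the matrices.
#'
#' @param state A `clustering_state`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_clustering_state <- function(state, path) {
  obj <- list(shape = list(C = nrow(state$centers), N = ncol(state$memberships),
                           d = ncol(state$centers)),
              memberships = unname(state$memberships),
              centers = unname(state$centers),
              weights = unname(state$weights),
              regularizers = state$regularizers,
              objective = state$objective)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a clustering state from JSON
#'
#' @param path Path written by [write_clustering_state()].
#' @return A `clustering_state`.
#' @export
read_clustering_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  C <- obj$shape$C
  structure(list(memberships = as_row_matrix(obj$memberships, C),
                 centers = as_row_matrix(obj$centers, C),
                 weights = as_row_matrix(obj$weights, C),
                 regularizers = as.numeric(obj$regularizers),
                 objective = obj$objective),
            class = "clustering_state")
}

#' Mean-intensity ROI features from an atlas-labeled volume
#'
#' Pools a voxel intensity grid into per-region mean features using an
#' integer label atlas on the identical grid (for brain imaging: e.g. the 90
#' cerebrum regions of an anatomical parcellation applied to a spatially
#' normalized PET volume). No resampling or registration is performed: the
#' two grids must already be aligned and only their shapes are checked.
#'
#' @param volume 3-D numeric array of intensities (or a NIfTI image).
#' @param atlas 3-D integer array of region labels on the same grid.
#' @param region_labels Integer labels to extract, all of which must occur in
#'   the atlas; defaults to all non-zero atlas labels, sorted.
#' @param statistic Summary statistic; only `"mean"` is supported.
#' @return Named numeric vector, one entry per requested label
#'   (names `roi<label>`).
#' @export
extract_roi_features <- function(volume, atlas, region_labels = NULL,
                                 statistic = "mean") {
  statistic <- match.arg(statistic, "mean")
  volume <- as.array(volume)
  atlas <- as.array(atlas)
  if (!identical(dim(volume), dim(atlas))) {
    stop(sprintf("grids not aligned: volume is %s but atlas is %s",
                 paste(dim(volume), collapse = "x"),
                 paste(dim(atlas), collapse = "x")))
  }
  if (is.null(region_labels)) {
    region_labels <- sort(unique(atlas[atlas != 0]))
  }
  region_labels <- as.integer(region_labels)
  if (length(region_labels) == 0L) stop("region_labels must be non-empty")
  if (anyDuplicated(region_labels)) stop("region_labels must be distinct")
  present <- region_labels %in% atlas
  if (!all(present)) {
    stop(sprintf("label absent from atlas: %s",
                 paste(region_labels[!present], collapse = ", ")))
  }
  out <- vapply(region_labels,
                function(l) mean(volume[atlas == l]), numeric(1L))
  names(out) <- paste0("roi", region_labels)
  out
}

#' Read a NIfTI volume as a plain array
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A numeric array (orientation metadata is not interpreted; voxel
#'   coordinates are 0-based array indices in downstream tools).
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Fisher-score feature selection
#'
#' Ranks features by the ratio of between-class to within-class variance for
#' a binary labeling and keeps the top `k` (ties broken toward the lower
#' feature index). A simple univariate filter used as plumbing ahead of the
#' classifier; constant features score 0 and rank last, features that
#' separate the classes with zero within-class variance score infinite and
#' rank first.
#'
#' @param data A [feature_matrix()] with binary labels.
#' @param k Number of features to keep, `k <= d`.
#' @return A list: `data` (reduced [feature_matrix()], labels kept),
#'   `selected` (column indices in original order) and `scores` (full
#'   ranking scores).
#' @export
fisher_score_select <- function(data, k) {
  data <- as_feature_matrix(data)
  enc <- encode_labels(data$labels)
  d <- ncol(data$values)
  if (k > d) stop(sprintf("too many features requested: k = %d > d = %d", k, d))
  g1 <- enc$y > 0
  n1 <- sum(g1); n2 <- sum(!g1)
  scores <- vapply(seq_len(d), function(j) {
    x <- data$values[, j]
    m <- mean(x); m1 <- mean(x[g1]); m2 <- mean(x[!g1])
    between <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
    within <- n1 * stats::var(x[g1]) * (n1 - 1) / n1 +
      n2 * stats::var(x[!g1]) * (n2 - 1) / n2
    if (within < 1e-24) {
      if (between < 1e-24) 0 else Inf
    } else {
      between / within
    }
  }, numeric(1L))
  ranking <- order(-scores, seq_len(d))
  selected <- sort(ranking[seq_len(k)])
  out <- feature_matrix(data$values[, selected, drop = FALSE],
                        labels = data$labels)
  list(data = out, selected = selected, scores = scores)
}
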