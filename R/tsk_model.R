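#' Build the TSK design vector for one input
#'
#' For each rule `k` the extended input is `(1, x_active)` in `reduced` mode
#' (only the rule's active features) or `(1, x)` in `full` mode; it is scaled
#' by the rule's normalized firing strength and the per-rule blocks are
#' concatenated. The consequent fit is then an ordinary linear model in this
#' vector.
#'
#' @param x Numeric feature vector of length `d`.
#' @param antecedent An `antecedent_model`.
#' @param mode `"reduced"` (default) or `"full"` consequent dimensionality.
#' @return Numeric vector of length `sum_k (d_k + 1)` (reduced) or
#'   `K * (d + 1)` (full).
#' @export
build_design_vector <- function(x, antecedent, mode = c("reduced", "full")) {
  mode <- match.arg(mode)
  as.vector(build_design_matrix(matrix(as.numeric(x), nrow = 1L), antecedent, mode))
}

# Batch version: N x sum_k(block_k) design matrix.
build_design_matrix <- function(X, antecedent, mode = c("reduced", "full")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("inputs must be finite")
  G <- normalize_log_firing(log_firing_matrix(antecedent, X))
  K <- nrow(antecedent$centers)
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    cols <- if (mode == "reduced") which(antecedent$active[k, ]) else
      seq_len(ncol(X))
    xe <- cbind(1, X[, cols, drop = FALSE])
    blocks[[k]] <- xe * G[, k]
  }
  do.call(cbind, blocks)
}

# Per-rule consequent block lengths for a given antecedent/mode.
consequent_block_lengths <- function(antecedent, mode) {
  if (mode == "reduced") rowSums(antecedent$active) + 1L
  else rep(ncol(antecedent$centers) + 1L, nrow(antecedent$centers))
}

#' Fit TSK consequent parameters
#'
#' Solves the ridge-regularized least-squares problem
#' `min_p sum_n (y_n - p' x_g(x_n))^2 + lambda ||p||^2` with labels encoded
#' as `{-1, +1}`, via QR on the lambda-augmented design (plain least squares
#' when `lambda = 0`). A small default ridge is used because the design matrix
#' is rank-deficient when rules overlap heavily.
#'
#' @param data A [feature_matrix()] with binary labels.
#' @param antecedent An `antecedent_model` fitted on compatible features.
#' @param ridge Non-negative ridge penalty `lambda`, default `1e-4`.
#' @param mode `"reduced"` or `"full"` consequent dimensionality.
#' @param positive_class Optional label to map to `+1`; defaults to the
#'   lexicographically larger label.
#' @param targets Optional numeric vector of regression targets replacing the
#'   encoded labels. The system output is linear in the consequents, so
#'   recovery studies regress on a generating model's real-valued output
#'   rather than on its sign.
#' @return An object of class `consequent_model`: per-rule coefficient list
#'   `coefficients` (rule `k` has `d_k + 1` or `d + 1` entries, intercept
#'   first), `mode`, `ridge` and the label map.
#' @export
fit_consequents <- function(data, antecedent, ridge = 1e-4,
                            mode = c("reduced", "full"), positive_class = NULL,
                            targets = NULL) {
  mode <- match.arg(mode)
  data <- as_feature_matrix(data)
  if (ridge < 0) stop("ridge must be >= 0")
  enc <- encode_labels(data$labels, positive_class)
  if (min(table(data$labels)) < 2L) {
    stop("each class needs at least 2 samples")
  }
  if (!is.null(targets)) {
    if (length(targets) != nrow(data$values) || !all(is.finite(targets))) {
      stop("targets must be a finite vector with one entry per sample")
    }
    enc$y <- as.numeric(targets)
  }
  Xg <- build_design_matrix(data$values, antecedent, mode)
  P <- ncol(Xg)
  if (ridge > 0) {
    Xa <- rbind(Xg, sqrt(ridge) * diag(P))
    ya <- c(enc$y, rep(0, P))
  } else {
    Xa <- Xg
    ya <- enc$y
  }
  p <- qr.coef(qr(Xa), ya)
  if (anyNA(p)) {
    # rank-deficient unpenalized solve: unidentifiable directions set to zero
    p[is.na(p)] <- 0
    warning("rank-deficient design; unidentifiable coefficients set to 0")
  }
  lens <- consequent_block_lengths(antecedent, mode)
  coefficients <- split(unname(p), rep(seq_along(lens), lens))
  names(coefficients) <- NULL
  structure(list(coefficients = coefficients, mode = mode, ridge = ridge,
                 negative = enc$negative, positive = enc$positive),
            class = "consequent_model")
}

flatten_coefficients <- function(consequent) unlist(consequent$coefficients)

#' Predict the real-valued TSK score
#'
#' The system output: the inner product of the consequent coefficient vector
#' with the design vector, equivalently the firing-strength-weighted sum of
#' per-rule linear outputs.
#'
#' @param x Numeric feature vector, or an `N x d` matrix / [feature_matrix()]
#'   for batch scoring.
#' @param model A fitted `tsk_classifier`.
#' @return Numeric score(s); the decision threshold is 0.
#' @export
predict_score <- function(x, model) {
  X <- if (inherits(x, "feature_matrix")) x$values
       else if (is.matrix(x)) x
       else matrix(as.numeric(x), nrow = 1L)
  X <- apply_standardization(X, model)
  Xg <- build_design_matrix(X, model$antecedent, model$consequent$mode)
  as.vector(Xg %*% flatten_coefficients(model$consequent))
}

#' Classify inputs with a fitted TSK classifier
#'
#' @param x Input vector, matrix or [feature_matrix()].
#' @param model A fitted `tsk_classifier`.
#' @return Predicted class labels; a score of exactly 0 is assigned to the
#'   positive class.
#' @export
classify <- function(x, model) {
  s <- predict_score(x, model)
  ifelse(s >= 0, model$consequent$positive, model$consequent$negative)
}

#' Classification accuracy
#'
#' The ratio of correctly classified samples to the total number of samples.
#'
#' @param predictions Predicted labels.
#' @param truths True labels, same length.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(predictions, truths) {
  if (length(truths) == 0L) stop("no samples")
  if (length(predictions) != length(truths)) stop("length mismatch")
  mean(as.character(predictions) == as.character(truths))
}

apply_standardization <- function(X, model) {
  if (is.null(model$standardize)) return(X)
  sweep(sweep(X, 2L, model$standardize$center, "-"), 2L,
        model$standardize$scale, "/")
}

#' Fit the full subspace-clustering TSK fuzzy classifier
#'
#' End-to-end training pipeline: feature-weighted fuzzy subspace clustering,
#' Gaussian antecedent parameters from the fitted memberships,
#' threshold-based feature activation, and a ridge least-squares consequent
#' fit over normalized firing strengths. Fully deterministic given the seed.
#'
#' @param data A [feature_matrix()] with binary labels (or a matrix/data
#'   frame plus `labels`).
#' @param n_rules Number of fuzzy rules `K` (= clusters), default 15.
#' @param fuzzifier Clustering fuzzy exponent `m`, default 2.
#' @param tolerance Clustering convergence threshold, default `1e-5`.
#' @param max_iter Maximum clustering sweeps, default 300.
#' @param spread_scale Antecedent width multiplier `h`, default 0.5.
#' @param threshold Feature-activation cutoff `tau` in `[0, 1)`, default 0.06.
#'   `tau = 0` reproduces the unreduced first-order TSK system.
#' @param ridge Consequent ridge penalty, default `1e-4`.
#' @param mode Consequent dimensionality, `"reduced"` (per-rule active
#'   features only; default) or `"full"` (all `d` features in every rule).
#' @param seed Clustering initialization seed, default 0.
#' @param positive_class Optional label mapped to `+1`.
#' @param labels Optional label vector when `data` carries none.
#' @param standardize If `TRUE`, z-score features before clustering; the
#'   transform is stored in the model and applied at prediction time.
#'   Default `FALSE`.
#' @return An object of class `tsk_classifier`: `antecedent`, `consequent`,
#'   `clustering` (the fitted state), label map and a `config` record.
#' @examples
#' tab <- generate_adni_like_table(seed = 1)
#' fit <- fit_tsk_classifier(tab, n_rules = 4, threshold = 0.1, seed = 1)
#' accuracy(classify(tab, fit), tab$labels)
#' @export
fit_tsk_classifier <- function(data, n_rules = 15L, fuzzifier = 2,
                               tolerance = 1e-5, max_iter = 300L,
                               spread_scale = 0.5, threshold = 0.06,
                               ridge = 1e-4, mode = c("reduced", "full"),
                               seed = 0L, positive_class = NULL, labels = NULL,
                               standardize = FALSE) {
  mode <- match.arg(mode)
  data <- as_feature_matrix(data)
  if (!is.null(labels)) data$labels <- labels
  if (is.null(data$labels)) stop("labels are required to fit a classifier")
  std <- NULL
  work <- data
  if (isTRUE(standardize)) {
    ctr <- colMeans(data$values)
    scl <- apply(data$values, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
    std <- list(center = ctr, scale = scl)
    work <- feature_matrix(sweep(sweep(data$values, 2L, ctr, "-"), 2L, scl, "/"),
                           labels = data$labels)
  }
  config <- clustering_config(n_clusters = n_rules, fuzzifier = fuzzifier,
                              tolerance = tolerance, max_iter = max_iter,
                              seed = seed)
  clustering <- fit_subspace_clustering(work, config)
  antecedent <- compute_antecedent_parameters(work, clustering, spread_scale)
  antecedent$active <- activate_features(clustering$weights, threshold)
  antecedent$threshold <- threshold
  tsk_log("feature activation at tau = %g: %s active per rule", threshold,
          paste(rowSums(antecedent$active), collapse = ","))
  consequent <- fit_consequents(work, antecedent, ridge = ridge, mode = mode,
                                positive_class = positive_class)
  structure(list(antecedent = antecedent, consequent = consequent,
                 clustering = clustering, standardize = std,
                 config = list(n_rules = as.integer(n_rules),
                               fuzzifier = fuzzifier, tolerance = tolerance,
                               max_iter = as.integer(max_iter),
                               spread_scale = spread_scale,
                               threshold = threshold, ridge = ridge,
                               mode = mode, seed = as.integer(seed))),
        class = "tsk_classifier")
}

#' @export
print.tsk_classifier <- function(x, ...) {
  cat(sprintf("<tsk_classifier> %d rules, %d features, tau = %g, mode = %s\n",
              nrow(x$antecedent$centers), ncol(x$antecedent$centers),
              x$antecedent$threshold, x$consequent$mode))
  cat(sprintf("  classes: %s (-1) vs %s (+1)\n",
              x$consequent$negative, x$consequent$positive))
  mc <- model_complexity(x$antecedent$active, x$consequent$mode)
  cat(sprintf("  model complexity: %d parameters\n", mc$total))
  invisible(x)
}

#' @rdname predict_score
#' @param object A fitted `tsk_classifier`.
#' @param newdata Inputs to score.
#' @param type `"class"` for labels, `"score"` for real-valued outputs.
#' @param ... Unused.
#' @export
predict.tsk_classifier <- function(object, newdata,
                                   type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") predict_score(newdata, object)
  else classify(newdata, object)
}
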