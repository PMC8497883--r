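#' Gaussian antecedent parameters from a clustering result
#'
#' Each fuzzy rule inherits one cluster: the rule's per-feature Gaussian
#' center is the membership-weighted mean of the data (membership exponent 1)
#' and its spread is `h` times the membership-weighted squared deviation
#' around that center — a variance-like quantity, floored at `1e-8` so that
#' constant features keep the membership function defined.
#'
#' @param data The [feature_matrix()] the clustering was fitted on.
#' @param clustering A fitted `clustering_state` (see
#'   [fit_subspace_clustering()]).
#' @param spread_scale Positive width multiplier `h` on the spreads,
#'   default 0.5.
#' @return An object of class `antecedent_model` with `K x d` matrices
#'   `centers` and `spreads`, an all-true activation mask `active`,
#'   `threshold = 0`, `spread_scale`, and the training feature names.
#' @export
compute_antecedent_parameters <- function(data, clustering, spread_scale = 0.5) {
  data <- as_feature_matrix(data)
  if (spread_scale <= 0) stop("spread_scale must be > 0")
  X <- data$values
  U <- clustering$memberships                       # K x N, exponent 1
  if (ncol(U) != nrow(X)) stop("clustering and data have different sample counts")
  mass <- rowSums(U)
  if (any(mass < 1e-12)) {
    stop(sprintf("empty rule: cluster %d has no membership mass",
                 which(mass < 1e-12)[1L]))
  }
  V <- (U %*% X) / mass
  K <- nrow(U); d <- ncol(X)
  S <- matrix(0, K, d)
  for (k in seq_len(K)) {
    diff2 <- sweep(X, 2L, V[k, ], "-")^2
    S[k, ] <- as.vector(U[k, ] %*% diff2) / mass[k]
  }
  S <- pmax(spread_scale * S, 1e-8)
  dimnames(V) <- dimnames(S) <- list(NULL, colnames(X))
  structure(list(centers = V, spreads = S,
                 active = matrix(TRUE, K, d, dimnames = list(NULL, colnames(X))),
                 threshold = 0, spread_scale = spread_scale,
                 feature_names = colnames(X)),
            class = "antecedent_model")
}

#' Threshold-based feature activation
#'
#' Turns the fitted cluster feature weights into per-rule boolean activation
#' masks: a feature is active in a rule when its weight reaches the threshold.
#' A rule whose mask would be empty keeps its single maximum-weight feature
#' (ties broken toward the lowest feature index), so every rule retains at
#' least one antecedent clause.
#'
#' @param weights `K x d` cluster feature-weight matrix (rows on the simplex).
#' @param threshold Activation cutoff `tau` in `[0, 1)`. At `tau = 0` every
#'   feature is active in every rule and the classifier degenerates to the
#'   unreduced first-order TSK system.
#' @return A `K x d` logical mask.
#' @export
activate_features <- function(weights, threshold) {
  weights <- as.matrix(weights)
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  mask <- weights >= threshold
  for (k in seq_len(nrow(mask))) {
    if (!any(mask[k, ])) mask[k, which.max(weights[k, ])] <- TRUE
  }
  dimnames(mask) <- dimnames(weights)
  mask
}

#' Gaussian membership value
#'
#' `exp(-(x - center)^2 / (2 * spread))` with `spread` a variance-like
#' quantity, vectorized over its arguments.
#'
#' @param x Numeric input value(s).
#' @param center Gaussian center.
#' @param spread Strictly positive variance-like width.
#' @return Membership degree(s) in `(0, 1]`.
#' @export
membership_value <- function(x, center, spread) {
  if (any(spread <= 0)) stop("invalid spread: must be > 0")
  exp(-(x - center)^2 / (2 * spread))
}

# Log firing strengths for a batch: N x K matrix of
# log mu^k(x) = sum over active features of -(x_j - v_kj)^2 / (2 sigma_kj).
log_firing_matrix <- function(antecedent, X) {
  X <- as.matrix(X)
  K <- nrow(antecedent$centers)
  L <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    act <- antecedent$active[k, ]
    if (!any(act)) next
    diff2 <- sweep(X[, act, drop = FALSE], 2L, antecedent$centers[k, act], "-")^2
    L[, k] <- -as.vector(diff2 %*% (1 / (2 * antecedent$spreads[k, act])))
  }
  L
}

# Softmax rows of a log-strength matrix; degenerate rows fall back to uniform.
normalize_log_firing <- function(L) {
  K <- ncol(L)
  t(apply(L, 1L, function(l) {
    mx <- max(l)
    if (!is.finite(mx)) return(rep(1 / K, K))
    e <- exp(l - mx)
    e / sum(e)
  }))
}

#' Rule firing strengths for one input
#'
#' The firing strength of rule `k` is the product of Gaussian memberships over
#' the rule's active features (inactive features contribute a neutral factor
#' 1). The product is accumulated in log space and normalized with the
#' max-subtraction trick, so normalized strengths stay well defined even when
#' every raw product underflows; if all log strengths are degenerate the
#' normalized strengths fall back to uniform `1/K`.
#'
#' @param x Numeric feature vector of length `d`.
#' @param antecedent An `antecedent_model`.
#' @return A list with `strength` (raw firing strengths, length `K`) and
#'   `normalized` (summing to 1).
#' @export
rule_firing_strengths <- function(x, antecedent) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("input vector must be finite")
  if (length(x) != ncol(antecedent$centers)) stop("input length does not match model")
  L <- log_firing_matrix(antecedent, matrix(x, nrow = 1L))
  list(strength = exp(L[1L, ]),
       normalized = normalize_log_firing(L)[1L, ])
}

#' @export
print.antecedent_model <- function(x, ...) {
  cat(sprintf("<antecedent_model> %d rules x %d features, h = %g, tau = %g\n",
              nrow(x$centers), ncol(x$centers), x$spread_scale, x$threshold))
  cat(sprintf("  active features per rule: %s\n",
              paste(rowSums(x$active), collapse = ", ")))
  invisible(x)
}
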