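#' Configuration for feature-weighted fuzzy subspace clustering
#'
#' Bundles the tunable parameters of the clustering stage. The number of
#' clusters equals the number of fuzzy rules of the downstream classifier.
#'
#' @param n_clusters Number of clusters `C` (= number of fuzzy rules), default 15.
#' @param fuzzifier Fuzzy exponent `m > 1` on the memberships, default 2.
#' @param tolerance Convergence threshold on the absolute change of the
#'   objective between sweeps, default `1e-5`.
#' @param max_iter Maximum number of full update sweeps, default 300.
#' @param seed Integer seed for the center initialization, default 0. The
#'   default seed is part of the public contract: the same data and
#'   configuration always yield the same fit.
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(n_clusters = 15L, fuzzifier = 2, tolerance = 1e-5,
                              max_iter = 300L, seed = 0L) {
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L) stop("n_clusters must be a positive integer")
  if (!is.finite(fuzzifier) || fuzzifier <= 1) stop("fuzzifier must be > 1")
  if (tolerance <= 0) stop("tolerance must be > 0")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be a positive integer")
  structure(list(n_clusters = n_clusters, fuzzifier = fuzzifier,
                 tolerance = tolerance, max_iter = max_iter,
                 seed = as.integer(seed)),
            class = "clustering_config")
}

# Euclidean projection onto the probability simplex (sort-and-threshold).
# For a diagonal quadratic objective this is the exact constrained minimizer,
# and it equals the analytic sum-to-one update whenever that is nonnegative.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

# Weighted squared distances D[c, i] = sum_j W[c, j] * (x[i, j] - V[c, j])^2
weighted_sq_dist <- function(X, V, W) {
  C <- nrow(V)
  D <- matrix(0, C, nrow(X))
  for (c in seq_len(C)) {
    diff2 <- sweep(X, 2L, V[c, ], "-")^2
    D[c, ] <- as.vector(diff2 %*% W[c, ])
  }
  D
}

#' Initialize the clustering state
#'
#' Centers are `C` distinct rows of the data chosen by seeded sampling without
#' replacement; feature weights start uniform at `1/d`; per-cluster
#' regularizers start at 1; memberships are computed from the weighted-distance
#' membership update under the uniform weights. Deterministic for a fixed seed.
#'
#' @param data A [feature_matrix()] (or coercible), `N x d`.
#' @param config A [clustering_config()]; requires `N >= n_clusters`.
#' @return An object of class `clustering_state` with elements `memberships`
#'   (`C x N`), `centers` (`C x d`), `weights` (`C x d`), `regularizers`
#'   (length `C`) and `objective`.
#' @export
initialize_state <- function(data, config) {
  data <- as_feature_matrix(data)
  X <- data$values
  N <- nrow(X); d <- ncol(X); C <- config$n_clusters
  if (N < C) {
    stop(sprintf("insufficient samples for requested clusters (N = %d < C = %d)",
                 N, C))
  }
  idx <- with_seed(config$seed, sample.int(N, C, replace = FALSE))
  V <- X[idx, , drop = FALSE]
  rownames(V) <- NULL
  W <- matrix(1 / d, C, d)
  delta <- rep(1, C)
  state <- structure(list(memberships = matrix(1, C, N), centers = V,
                          weights = W, regularizers = delta, objective = NA_real_),
                     class = "clustering_state")
  state$memberships <- update_memberships(data, state, config)
  state$objective <- objective_value(data, state, config)
  state
}

#' Update per-cluster feature weights
#'
#' Coordinate update of the weight matrix `W`: each row moves away from the
#' uniform `1/d` in proportion to how much less a feature disperses around the
#' cluster center than the average feature, damped by the cluster regularizer.
#' The analytic update can go negative; such rows are replaced by the exact
#' Euclidean projection onto the probability simplex, which clips the
#' offending entries at zero and redistributes their mass. The projected row
#' is the true constrained minimizer of the objective in its block (the
#' analytic update already sums to 1, so interior rows pass through
#' unchanged).
#'
#' @param data A [feature_matrix()].
#' @param state A `clustering_state`; all regularizers must be positive.
#' @param config A [clustering_config()].
#' @return A `C x d` weight matrix, rows summing to 1.
#' @export
update_feature_weights <- function(data, state, config) {
  data <- as_feature_matrix(data)
  X <- data$values
  d <- ncol(X)
  U <- state$memberships; V <- state$centers; delta <- state$regularizers
  if (any(delta <= 0)) stop("degenerate regularizer: all delta_c must be > 0")
  m <- config$fuzzifier
  C <- nrow(V)
  W <- matrix(0, C, d)
  for (c in seq_len(C)) {
    a <- U[c, ]^m
    diff2 <- sweep(X, 2L, V[c, ], "-")^2
    b <- as.vector(a %*% diff2)        # sum_i mu^m (x_ij - v_cj)^2, per j
    w <- 1 / d + (sum(b) / d - b) / (2 * delta[c])
    W[c, ] <- if (any(w < 0)) project_simplex(w) else w
  }
  W
}

#' Update per-cluster regularizers
#'
#' Sets each cluster's regularizer to the ratio of its membership-weighted
#' within-cluster dispersion (under the current feature weights) to the sum of
#' squared weights, so the penalty term tracks the scatter term in magnitude.
#' Floored at `1e-12` to keep the weight update well defined.
#'
#' @inheritParams update_feature_weights
#' @return A length-`C` numeric vector of positive regularizers.
#' @export
update_regularizers <- function(data, state, config) {
  data <- as_feature_matrix(data)
  X <- data$values
  U <- state$memberships; V <- state$centers; W <- state$weights
  m <- config$fuzzifier
  D <- weighted_sq_dist(X, V, W)
  num <- rowSums(U^m * D)
  den <- rowSums(W^2)
  if (any(den <= 0)) stop("weight rows must have positive sum of squares")
  pmax(num / den, 1e-12)
}

#' Update fuzzy memberships
#'
#' Standard fuzzy-partition update under per-cluster weighted squared
#' distances: membership of sample `i` in cluster `c` is inversely related to
#' its weighted distance, with softness controlled by the fuzzifier. Samples
#' within `1e-12` of one or more centers receive crisp membership split
#' equally among the tied centers (the limit of the formula).
#'
#' @inheritParams update_feature_weights
#' @return A `C x N` membership matrix with columns summing to 1.
#' @export
update_memberships <- function(data, state, config) {
  data <- as_feature_matrix(data)
  X <- data$values
  V <- state$centers; W <- state$weights
  m <- config$fuzzifier
  if (m <= 1) stop("fuzzifier must be > 1")
  D <- weighted_sq_dist(X, V, W)
  C <- nrow(D); N <- ncol(D)
  U <- matrix(0, C, N)
  expo <- 1 / (m - 1)
  for (i in seq_len(N)) {
    di <- D[, i]
    zero <- di < 1e-12
    if (any(zero)) {
      U[zero, i] <- 1 / sum(zero)
    } else {
      r <- di^(-expo)
      U[, i] <- r / sum(r)
    }
  }
  U
}

#' Update cluster centers
#'
#' Each center coordinate is the membership-weighted mean of the data (the
#' per-feature weight cancels between numerator and denominator of the raw
#' update, so the cancelled form is implemented; this also avoids 0/0 for
#' features whose weight was clipped to zero). A cluster whose total
#' membership mass vanishes is reseeded at the sample farthest (in weighted
#' distance) from its best current center.
#'
#' @inheritParams update_feature_weights
#' @return A `C x d` matrix of centers.
#' @export
update_centers <- function(data, state, config) {
  data <- as_feature_matrix(data)
  X <- data$values
  U <- state$memberships; W <- state$weights
  m <- config$fuzzifier
  Um <- U^m
  mass <- rowSums(Um)
  C <- nrow(U)
  V <- matrix(0, C, ncol(X))
  for (c in seq_len(C)) {
    if (mass[c] < 1e-12) {
      # empty cluster: reseed from the sample worst-served by current centers
      D <- weighted_sq_dist(X, state$centers, W)
      far <- which.max(apply(D, 2L, min))
      tsk_log("empty cluster %d reseeded at sample %d", c, far)
      V[c, ] <- X[far, ]
    } else {
      V[c, ] <- as.vector(Um[c, ] %*% X) / mass[c]
    }
  }
  V
}

#' Clustering objective value
#'
#' The fitted criterion: membership-weighted, feature-weighted within-cluster
#' scatter plus the regularized sum of squared feature weights,
#' `J = sum_c sum_i mu_ci^m sum_j w_cj (x_ij - v_cj)^2 + sum_c delta_c sum_j w_cj^2`.
#'
#' @inheritParams update_feature_weights
#' @return A single non-negative finite number.
#' @export
objective_value <- function(data, state, config) {
  data <- as_feature_matrix(data)
  D <- weighted_sq_dist(data$values, state$centers, state$weights)
  sum(state$memberships^config$fuzzifier * D) +
    sum(state$regularizers * rowSums(state$weights^2))
}

#' Fit the feature-weighted fuzzy subspace clustering
#'
#' Two-phase alternating optimization. Phase one is a plain fuzzy-c-means
#' warm start: memberships and centers are iterated with the feature weights
#' frozen at uniform `1/d` until the objective stabilizes, which localizes
#' the partition before any feature is down-weighted. (Without this phase
#' the most separating features have the largest apparent dispersion under a
#' diffuse partition and are suppressed before the clusters can form — a
#' known failure mode of dispersion-penalizing feature weighting.) Phase two
#' re-calibrates the per-cluster regularizers to the warm-started scatter and
#' then sweeps the four updates — weights, regularizers, memberships,
#' centers — recomputing the objective after each sweep, until the absolute
#' objective change falls below `tolerance` or `max_iter` sweeps are spent.
#' The per-sweep objective trace is kept for diagnostics.
#'
#' @param data A [feature_matrix()] (or coercible), `N x d` with `N >= C`.
#' @param config A [clustering_config()].
#' @param warm_start If `TRUE` (default) run the uniform-weight warm-start
#'   phase; `FALSE` starts the weighted sweeps directly from the seeded
#'   initialization.
#' @return A `clustering_state` with additional elements `objective_trace`
#'   (objective after each weighted sweep, preceded by the phase-entry
#'   value), `iterations` (weighted sweeps), `warm_iterations` and
#'   `converged`.
#' @examples
#' sim <- generate_subspace_clusters(n_samples = 60, n_features = 5,
#'                                   n_clusters = 2, seed = 1)
#' fit <- fit_subspace_clustering(sim$data, clustering_config(n_clusters = 2))
#' round(fit$weights, 3)
#' @export
fit_subspace_clustering <- function(data, config = clustering_config(),
                                    warm_start = TRUE) {
  data <- as_feature_matrix(data)
  state <- initialize_state(data, config)
  warm_iterations <- 0L
  if (warm_start) {
    # fuzzy-c-means phase: weights stay uniform, delta stays at its initial
    # value, so the objective change reduces to the scatter change
    J_warm <- state$objective
    for (t in seq_len(config$max_iter)) {
      state$memberships <- update_memberships(data, state, config)
      state$centers <- update_centers(data, state, config)
      J <- objective_value(data, state, config)
      warm_iterations <- t
      if (abs(J - J_warm) < config$tolerance) break
      J_warm <- J
    }
    tsk_log("warm start: %d fuzzy-c-means sweeps", warm_iterations)
  }
  # calibrate the regularizers to the current scatter before weighting
  state$regularizers <- update_regularizers(data, state, config)
  state$objective <- objective_value(data, state, config)
  J_prev <- state$objective
  trace <- J_prev
  converged <- FALSE
  iterations <- 0L
  for (t in seq_len(config$max_iter)) {
    state$weights <- update_feature_weights(data, state, config)
    state$regularizers <- update_regularizers(data, state, config)
    state$memberships <- update_memberships(data, state, config)
    state$centers <- update_centers(data, state, config)
    J <- objective_value(data, state, config)
    if (!is.finite(J)) {
      stop(sprintf("numerical divergence: objective not finite at iteration %d", t))
    }
    trace <- c(trace, J)
    iterations <- t
    tsk_log("sweep %d: J = %.8g", t, J, level = 2L)
    if (abs(J - J_prev) < config$tolerance) {
      converged <- TRUE
      break
    }
    J_prev <- J
  }
  state$objective <- trace[length(trace)]
  state$objective_trace <- trace
  state$iterations <- iterations
  state$warm_iterations <- warm_iterations
  state$converged <- converged
  tsk_log("subspace clustering: %d sweeps, J = %.6g, converged = %s",
          iterations, state$objective, converged)
  state
}

#' @export
print.clustering_state <- function(x, ...) {
  cat(sprintf("<clustering_state> C = %d clusters, N = %d samples, d = %d features\n",
              nrow(x$centers), ncol(x$memberships), ncol(x$centers)))
  if (!is.null(x$iterations)) {
    cat(sprintf("  %d sweeps, objective %.6g, converged: %s\n",
                x$iterations, x$objective, x$converged))
  }
  invisible(x)
}
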