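#' Generate data with planted feature subspaces
#'
#' Emulates the statistical structure the subspace clustering assumes:
#' samples fall into clusters, and each cluster is compact only on its own
#' small set of informative features (drawn tightly around cluster-specific
#' centers) while the remaining features are broad shared noise. Ground truth
#' (assignments, centers, informative masks) is returned alongside the data so
#' recovery tests never re-derive it. A pure function of its arguments and
#' seed.
#'
#' @param n_samples Number of samples `N`, default 300.
#' @param n_features Number of features `d`, default 10.
#' @param n_clusters Number of planted clusters, default 3.
#' @param informative_per_cluster Informative features per cluster, default 2.
#' @param informative_variance Variance of informative features around their
#'   cluster centers, default 0.01. Must be below `noise_variance` for
#'   weight-recovery tests to be well posed.
#' @param noise_variance Variance of the shared noise features, default 1.
#' @param center_separation Spacing between cluster centers on informative
#'   features, default 5.
#' @param labels `"parity"` to label samples by cluster-index parity (a
#'   learnable binary task), or `"none"`.
#' @param seed Integer seed, default 0.
#' @return A list: `data` ([feature_matrix()]), `assignments` (length `N`),
#'   `centers` (`C x d`, noise features at 0), `informative` (`C x d` logical).
#' @export
generate_subspace_clusters <- function(n_samples = 300L, n_features = 10L,
                                       n_clusters = 3L,
                                       informative_per_cluster = 2L,
                                       informative_variance = 0.01,
                                       noise_variance = 1,
                                       center_separation = 5,
                                       labels = c("parity", "none"),
                                       seed = 0L) {
  labels <- match.arg(labels)
  stopifnot(n_samples >= 2L, n_features >= 1L, n_clusters >= 1L,
            informative_per_cluster >= 1L,
            informative_per_cluster * n_clusters <= n_features * n_clusters)
  with_seed(seed, {
    C <- n_clusters; d <- n_features; N <- n_samples
    assignments <- sort(rep_len(seq_len(C), N))
    informative <- matrix(FALSE, C, d)
    # disjoint blocks where room allows, wrapping otherwise
    slot <- (seq_len(informative_per_cluster * C) - 1L) %% d + 1L
    for (c in seq_len(C)) {
      idx <- slot[((c - 1L) * informative_per_cluster + 1L):
                    (c * informative_per_cluster)]
      informative[c, unique(idx)] <- TRUE
    }
    # every cluster-specific center is displaced from the shared noise
    # distribution (mean 0): offsets c * separation with alternating signs
    centers <- matrix(0, C, d)
    for (c in seq_len(C)) {
      centers[c, informative[c, ]] <- center_separation * c *
        rep_len(c(1, -1), sum(informative[c, ]))
    }
    X <- matrix(stats::rnorm(N * d, sd = sqrt(noise_variance)), N, d)
    for (c in seq_len(C)) {
      rows <- which(assignments == c)
      for (j in which(informative[c, ])) {
        X[rows, j] <- stats::rnorm(length(rows), mean = centers[c, j],
                                   sd = sqrt(informative_variance))
      }
    }
    lab <- if (labels == "parity") {
      ifelse(assignments %% 2L == 0L, "even", "odd")
    } else NULL
    list(data = feature_matrix(X, labels = lab),
         assignments = assignments, centers = centers,
         informative = informative)
  })
}

#' Generate labeled data from a known ground-truth TSK model
#'
#' Samples inputs around the rule centers (Gaussian, with the rule spreads as
#' variances), scores them with the supplied model, adds Gaussian noise to the
#' score and takes the sign as the label. The clean (noise-free) scores are
#' attached as attribute `clean_scores` so callers can filter by margin.
#'
#' @param antecedent An `antecedent_model` (ground truth).
#' @param consequent A `consequent_model` whose block structure matches the
#'   antecedent and mode.
#' @param n Number of samples.
#' @param noise_sd Standard deviation of the additive score noise, default 0.
#' @param seed Integer seed, default 0.
#' @return A [feature_matrix()] with labels `consequent$negative` /
#'   `consequent$positive` and attribute `clean_scores`.
#' @export
generate_tsk_labeled_data <- function(antecedent, consequent, n, noise_sd = 0,
                                      seed = 0L) {
  K <- nrow(antecedent$centers)
  d <- ncol(antecedent$centers)
  if (length(consequent$coefficients) != K) {
    stop("antecedent and consequent rule counts differ")
  }
  if (n < 2) stop("empty table: need at least 2 samples")
  with_seed(seed, {
    rule <- sample.int(K, n, replace = TRUE)
    X <- matrix(0, n, d)
    for (i in seq_len(n)) {
      X[i, ] <- stats::rnorm(d, mean = antecedent$centers[rule[i], ],
                             sd = sqrt(antecedent$spreads[rule[i], ]))
    }
    Xg <- build_design_matrix(X, antecedent, consequent$mode)
    clean <- as.vector(Xg %*% flatten_coefficients(consequent))
    noisy <- clean + if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
    lab <- ifelse(noisy >= 0, consequent$positive, consequent$negative)
    out <- feature_matrix(X, labels = lab)
    attr(out, "clean_scores") <- clean
    out
  })
}

#' Generate a region-intensity-like demonstration table
#'
#' A 200-sample, 15-feature table of positive, intensity-like values with 15
#' latent clusters of unequal size (each compact on a small random feature
#' subset, displaced from the shared background) and two classes assigned by
#' cluster parity. Mirrors the shape of a region-mean brain-image feature
#' table after selection to 15 features; used in end-to-end examples and
#' interface tests. Synthetic data: it does not emulate real disease effect
#' sizes.
#'
#' @param seed Integer seed, default 0.
#' @param n_samples Number of samples, default 200.
#' @param n_features Number of features, default 15.
#' @param n_clusters Number of latent clusters, default 15.
#' @return A [feature_matrix()] with labels `"case"` / `"control"` and
#'   attribute `assignments`.
#' @export
generate_adni_like_table <- function(seed = 0L, n_samples = 200L,
                                     n_features = 15L, n_clusters = 15L) {
  with_seed(seed, {
    C <- n_clusters; d <- n_features; N <- n_samples
    sizes <- stats::rmultinom(1L, N - C, prob = seq_len(C))[, 1L] + 1L
    assignments <- rep(seq_len(C), sizes)
    base <- 100
    X <- matrix(stats::rnorm(N * d, mean = base, sd = 5), N, d)
    n_info <- min(4L, d)
    for (c in seq_len(C)) {
      rows <- which(assignments == c)
      info <- sample.int(d, n_info)
      offs <- sample(c(-1, 1), n_info, replace = TRUE) *
        stats::runif(n_info, 25, 45)
      for (a in seq_along(info)) {
        X[rows, info[a]] <- stats::rnorm(length(rows),
                                         mean = base + offs[a], sd = 2)
      }
    }
    X <- pmax(X, 1)
    lab <- ifelse(assignments %% 2L == 0L, "case", "control")
    out <- feature_matrix(X, feature_names = paste0("x", seq_len(d)),
                          labels = lab)
    attr(out, "assignments") <- assignments
    out
  })
}
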