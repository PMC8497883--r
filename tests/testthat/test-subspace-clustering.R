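test_that("initialization is seeded, uniform-weighted and simplex-valid", {
  sim <- generate_subspace_clusters(n_samples = 30, n_features = 4,
                                    n_clusters = 3, seed = 2)
  cfg <- clustering_config(n_clusters = 3, seed = 7)
  st1 <- initialize_state(sim$data, cfg)
  st2 <- initialize_state(sim$data, cfg)
  expect_identical(st1, st2)
  expect_true(all(st1$weights == 1 / 4))
  expect_equal(st1$regularizers, rep(1, 3))
  expect_equal(colSums(st1$memberships), rep(1, 30), tolerance = 1e-10)
  # centers are rows of the data
  expect_true(all(apply(st1$centers, 1L, function(v) {
    any(apply(sim$data$values, 1L, function(x) all(x == v)))
  })))

  one <- initialize_state(sim$data, clustering_config(n_clusters = 1, seed = 0))
  expect_true(all(one$memberships == 1))

  expect_error(initialize_state(sim$data, clustering_config(n_clusters = 31)),
               "insufficient samples")
})

test_that("weight update reduces to uniform under feature symmetry and flags degenerate regularizers", {
  # every feature column identical and centers constant across features:
  # all features disperse identically, so the update stays at 1/d
  x <- rnorm(6)
  X <- matrix(rep(x, 4), ncol = 4)
  st <- structure(list(memberships = matrix(c(0.3, 0.7), 2, 6),
                       centers = matrix(c(0.5, -1), 2, 4),
                       weights = matrix(1 / 4, 2, 4),
                       regularizers = c(1, 1)),
                  class = "clustering_state")
  cfg <- clustering_config(n_clusters = 2)
  W <- update_feature_weights(feature_matrix(X), st, cfg)
  expect_equal(W, matrix(1 / 4, 2, 4), tolerance = 1e-12)

  st$regularizers <- c(1, 0)
  expect_error(update_feature_weights(feature_matrix(X), st, cfg),
               "degenerate regularizer")
})

test_that("a high-dispersion feature is down-weighted", {
  set.seed(3)
  X <- cbind(rnorm(20, sd = 0.1), rnorm(20, sd = 0.1), rnorm(20, sd = 4))
  inst <- random_instance(3, N = 20, d = 3, C = 2)
  st <- inst$state
  st$centers <- matrix(0, 2, 3)
  W <- update_feature_weights(feature_matrix(X), st, inst$config)
  expect_true(all(W[, 3] < 1 / 3))
  expect_equal(rowSums(W), c(1, 1), tolerance = 1e-10)
})

test_that("regularizer update matches direct evaluation, floors at zero scatter and is linear in membership mass", {
  # 3-sample, 1-cluster instance evaluated by hand-written loops
  X <- matrix(c(0, 1, 3, 2, -1, 0.5), nrow = 3)
  U <- matrix(c(0.9, 0.5, 0.2), 1, 3)
  V <- matrix(c(1, 0.5), 1, 2)
  W <- matrix(c(0.6, 0.4), 1, 2)
  st <- structure(list(memberships = U, centers = V, weights = W,
                       regularizers = 1),
                  class = "clustering_state")
  cfg <- clustering_config(n_clusters = 1, fuzzifier = 2)
  num <- 0
  for (i in 1:3) {
    num <- num + U[1, i]^2 * sum(W[1, ] * (X[i, ] - V[1, ])^2)
  }
  expect_equal(update_regularizers(feature_matrix(X), st, cfg),
               num / sum(W[1, ]^2), tolerance = 1e-12)

  # doubling mu^m doubles delta
  st2 <- st
  st2$memberships <- U * sqrt(2)
  expect_equal(update_regularizers(feature_matrix(X), st2, cfg),
               2 * num / sum(W[1, ]^2), tolerance = 1e-12)

  # all samples at the center -> floor
  st3 <- st
  st3$centers <- matrix(0, 1, 2)
  zero_data <- feature_matrix(matrix(0, 3, 2))
  expect_equal(update_regularizers(zero_data, st3, cfg), 1e-12)
})

test_that("membership update honors closed forms and the zero-distance convention", {
  cfg <- clustering_config(n_clusters = 1)
  X <- matrix(rnorm(10), 5, 2)
  st1 <- structure(list(memberships = matrix(1, 1, 5),
                        centers = matrix(0, 1, 2),
                        weights = matrix(0.5, 1, 2), regularizers = 1),
                   class = "clustering_state")
  expect_true(all(update_memberships(feature_matrix(X), st1, cfg) == 1))

  # two clusters at weighted squared distances r and 3r with m = 2
  r <- 0.7
  st2 <- structure(list(memberships = matrix(0.5, 2, 2),
                        centers = matrix(c(sqrt(r), sqrt(3 * r)), 2, 1),
                        weights = matrix(1, 2, 1), regularizers = c(1, 1)),
                   class = "clustering_state")
  U <- update_memberships(feature_matrix(matrix(c(0, 10), 2, 1)), st2,
                          clustering_config(n_clusters = 2, fuzzifier = 2))
  expect_equal(U[, 1], c(0.75, 0.25), tolerance = 1e-12)

  # sample coinciding with a center takes crisp membership there
  st3 <- st2
  st3$centers <- matrix(c(0, 2), 2, 1)
  U3 <- update_memberships(feature_matrix(matrix(c(0, 10), 2, 1)), st3,
                           clustering_config(n_clusters = 2))
  expect_equal(U3[, 1], c(1, 0))
  expect_equal(colSums(U3), c(1, 1), tolerance = 1e-10)
})

test_that("center update reduces to cluster means and reseeds empty clusters", {
  set.seed(4)
  X <- matrix(rnorm(24), 8, 3)
  cfg <- clustering_config(n_clusters = 2)
  crisp <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0), c(0, 0, 0, 0, 1, 1, 1, 1))
  st <- structure(list(memberships = crisp, centers = matrix(0, 2, 3),
                       weights = matrix(1 / 3, 2, 3), regularizers = c(1, 1)),
                  class = "clustering_state")
  V <- update_centers(feature_matrix(X), st, cfg)
  expect_equal(V[1, ], colMeans(X[1:4, ]), tolerance = 1e-12)
  expect_equal(V[2, ], colMeans(X[5:8, ]), tolerance = 1e-12)

  st$memberships <- matrix(0.5, 2, 8)
  V2 <- update_centers(feature_matrix(X), st, cfg)
  expect_equal(V2[1, ], colMeans(X), tolerance = 1e-12)
  expect_equal(V2[2, ], colMeans(X), tolerance = 1e-12)

  # zero-mass cluster is reseeded at the worst-served sample
  st$memberships <- rbind(rep(1, 8), rep(0, 8))
  st$centers <- rbind(colMeans(X), colMeans(X))
  V3 <- update_centers(feature_matrix(X), st, cfg)
  D <- oracle_weighted_dists(X, st$centers, st$weights)
  far <- which.max(apply(D, 2L, min))
  expect_equal(V3[2, ], X[far, ])
})

test_that("objective value matches the hand-computed instance and is non-negative", {
  # x = {0, 2}, v = 1, mu = 1, m = 2, w = 1, delta = 1 -> J = 2 + 1 = 3
  st <- structure(list(memberships = matrix(1, 1, 2),
                       centers = matrix(1, 1, 1), weights = matrix(1, 1, 1),
                       regularizers = 1),
                  class = "clustering_state")
  cfg <- clustering_config(n_clusters = 1, fuzzifier = 2)
  expect_equal(objective_value(feature_matrix(matrix(c(0, 2), 2, 1)), st, cfg), 3)

  for (s in 1:3) {
    inst <- random_instance(s)
    expect_gte(objective_value(inst$data, inst$state, inst$config), 0)
  }
})

test_that("each block update matches an independent numerical minimizer on small instances", {
  for (s in 1:5) {
    inst <- random_instance(100 + s, N = sample(5:10, 1), d = sample(2:4, 1),
                            C = sample(2:3, 1))
    X <- inst$data$values
    st <- inst$state
    cfg <- inst$config
    C <- cfg$n_clusters

    W <- update_feature_weights(inst$data, st, cfg)
    for (c in seq_len(C)) {
      w_star <- oracle_weight_row(X, st$memberships[c, ], st$centers[c, ],
                                  st$regularizers[c], cfg$fuzzifier)
      expect_equal(W[c, ], w_star, tolerance = 1e-6)
    }

    D <- oracle_weighted_dists(X, st$centers, st$weights)
    U <- update_memberships(inst$data, st, cfg)
    for (i in seq_len(ncol(U))) {
      mu_star <- oracle_membership_col(D[, i], cfg$fuzzifier)
      expect_equal(U[, i], mu_star, tolerance = 1e-6)
    }

    V <- update_centers(inst$data, st, cfg)
    for (c in seq_len(C)) {
      v_star <- oracle_center_row(X, st$memberships[c, ], st$weights[c, ],
                                  cfg$fuzzifier)
      expect_equal(V[c, ], v_star, tolerance = 1e-6)
    }

    # delta: independent direct evaluation of the update formula
    delta <- update_regularizers(inst$data, st, cfg)
    for (c in seq_len(C)) {
      num <- 0
      for (i in seq_len(nrow(X))) {
        num <- num + st$memberships[c, i]^cfg$fuzzifier *
          sum(st$weights[c, ] * (X[i, ] - st$centers[c, ])^2)
      }
      expect_equal(delta[c], max(num / sum(st$weights[c, ]^2), 1e-12),
                   tolerance = 1e-10)
    }
  }
})

test_that("fitting converges deterministically and keeps the simplex constraints", {
  sim <- generate_subspace_clusters(n_samples = 90, n_features = 5,
                                    n_clusters = 3, seed = 11)
  cfg <- clustering_config(n_clusters = 3, seed = 11)
  f1 <- fit_subspace_clustering(sim$data, cfg)
  f2 <- fit_subspace_clustering(sim$data, cfg)
  expect_identical(f1, f2)
  expect_true(f1$converged)
  expect_equal(colSums(f1$memberships), rep(1, 90), tolerance = 1e-10)
  expect_equal(rowSums(f1$weights), rep(1, 3), tolerance = 1e-10)
  expect_true(all(f1$regularizers > 0))
  expect_true(is.finite(f1$objective) && f1$objective >= 0)
  expect_length(f1$objective_trace, f1$iterations + 1L)

  # infinite tolerance stops after a single sweep
  lazy <- fit_subspace_clustering(sim$data,
                                  clustering_config(n_clusters = 3, seed = 11,
                                                    tolerance = Inf))
  expect_equal(lazy$iterations, 1L)
})

test_that("informative features receive larger fitted weights than noise features", {
  sim <- generate_subspace_clusters(n_samples = 150, n_features = 6,
                                    n_clusters = 3,
                                    informative_per_cluster = 2,
                                    informative_variance = 0.01,
                                    noise_variance = 1,
                                    center_separation = 5, seed = 21)
  fit <- fit_subspace_clustering(sim$data, clustering_config(n_clusters = 3,
                                                             seed = 21))
  # match fitted clusters to planted ones by nearest center
  for (c in 1:3) {
    k <- which.min(colSums((t(fit$centers) - sim$centers[c, ])^2))
    info <- sim$informative[c, ]
    expect_gt(min(fit$weights[k, info]), max(fit$weights[k, !info]))
  }
})

test_that("well-separated spherical clusters are recovered to within 0.1", {
  set.seed(31)
  mu <- rbind(rep(0, 3), rep(5, 3))
  X <- rbind(matrix(rnorm(150, sd = 0.1), 50, 3) ,
             matrix(rnorm(150, sd = 0.1), 50, 3) + 5)
  fit <- fit_subspace_clustering(feature_matrix(X),
                                 clustering_config(n_clusters = 2, seed = 31))
  for (c in 1:2) {
    k <- which.min(colSums((t(fit$centers) - mu[c, ])^2))
    expect_lt(max(abs(fit$centers[k, ] - mu[c, ])), 0.1)
  }
})

test_that("updates are equivariant under sample permutation", {
  inst <- random_instance(55, N = 9, d = 3, C = 3)
  cfg <- inst$config
  perm <- c(4, 1, 9, 2, 7, 3, 8, 5, 6)
  data_p <- feature_matrix(inst$data$values[perm, ])
  st_p <- inst$state
  st_p$memberships <- inst$state$memberships[, perm]

  U <- update_memberships(inst$data, inst$state, cfg)
  expect_equal(update_memberships(data_p, st_p, cfg), U[, perm],
               tolerance = 1e-12)
  expect_equal(update_centers(data_p, st_p, cfg),
               update_centers(inst$data, inst$state, cfg), tolerance = 1e-12)
  expect_equal(update_feature_weights(data_p, st_p, cfg),
               update_feature_weights(inst$data, inst$state, cfg),
               tolerance = 1e-12)
  expect_equal(update_regularizers(data_p, st_p, cfg),
               update_regularizers(inst$data, inst$state, cfg),
               tolerance = 1e-12)
})

test_that("with uniform frozen weights the updates reproduce textbook fuzzy c-means", {
  set.seed(41)
  X <- rbind(matrix(rnorm(40, sd = 0.5), 20, 2),
             matrix(rnorm(40, mean = 4, sd = 0.5), 20, 2))
  cfg <- clustering_config(n_clusters = 2, fuzzifier = 2, seed = 41)
  data <- feature_matrix(X)
  st <- initialize_state(data, cfg)   # weights are uniform 1/d
  U_ref <- st$memberships
  U_pkg <- st$memberships
  V_pkg <- st$centers
  for (sweep_i in 1:8) {
    ref <- fcm_sweep(X, U_ref, 2)
    st$memberships <- U_pkg
    V_pkg <- update_centers(data, st, cfg)
    st$centers <- V_pkg
    U_pkg <- update_memberships(data, st, cfg)
    U_ref <- ref$U
    expect_equal(V_pkg, ref$V, tolerance = 1e-8)
    expect_equal(U_pkg, ref$U, tolerance = 1e-8)
  }
  cm <- e1071::cmeans(X, centers = 2, m = 2, iter.max = 200)
  for (c in 1:2) {
    k <- which.min(colSums((t(V_pkg) - cm$centers[c, ])^2))
    expect_lt(max(abs(V_pkg[k, ] - cm$centers[c, ])), 1e-2)
  }
})
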