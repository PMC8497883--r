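# Independent numerical oracles and instance builders shared across tests.
# Nothing here calls into the package's own update formulas: block oracles go
# through generic numerical optimization (softmax reparameterization / BFGS)
# and the FCM reference is a textbook fuzzy-c-means step written from the
# plain-distance formulas.

# Random but valid clustering instance: data plus a state satisfying the
# simplex constraints, with delta scaled so the weight optimum is interior.
random_instance <- function(seed, N = 8, d = 3, C = 2, interior_delta = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(N * d), N, d)
  U <- matrix(runif(C * N, 0.1, 1), C, N)
  U <- sweep(U, 2L, colSums(U), "/")
  V <- X[sample.int(N, C), , drop = FALSE] + matrix(rnorm(C * d, sd = 0.1), C, d)
  W <- matrix(runif(C * d, 0.2, 1), C, d)
  W <- sweep(W, 1L, rowSums(W), "/")
  delta <- runif(C, 0.5, 2)
  if (interior_delta) {
    # scale delta up until the analytic weight update stays positive, so the
    # simplex constraint is inactive and numerical optimizers are comparable
    for (c in seq_len(C)) {
      repeat {
        b <- as.vector((U[c, ]^2) %*% sweep(X, 2L, V[c, ], "-")^2)
        w <- 1 / d + (sum(b) / d - b) / (2 * delta[c])
        if (all(w > 1e-3)) break
        delta[c] <- delta[c] * 2
      }
    }
  }
  list(data = feature_matrix(X),
       state = structure(list(memberships = U, centers = V, weights = W,
                              regularizers = delta, objective = NA_real_),
                         class = "clustering_state"),
       config = clustering_config(n_clusters = C, fuzzifier = 2, seed = seed))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Numerical minimizer of the objective over one weight row on the simplex
# (softmax reparameterization; valid when the optimum is interior).
oracle_weight_row <- function(X, U_row, v_row, delta_c, m) {
  diff2 <- sweep(X, 2L, v_row, "-")^2
  b <- as.vector((U_row^m) %*% diff2)
  d <- length(b)
  # convex in the first d-1 coordinates with w_d = 1 - sum(w)
  obj <- function(w) {
    wd <- 1 - sum(w)
    sum(w * b[-d]) + wd * b[d] + delta_c * (sum(w^2) + wd^2)
  }
  grad <- function(w) {
    wd <- 1 - sum(w)
    b[-d] - b[d] + 2 * delta_c * (w - wd)
  }
  fit <- optim(rep(1 / d, d - 1L), obj, grad, method = "L-BFGS-B",
               lower = 0, upper = 1,
               control = list(maxit = 2000, factr = 10))
  w <- unname(fit$par)
  c(w, 1 - sum(w))
}

# Numerical minimizer over one membership column on the simplex.
oracle_membership_col <- function(dists_col, m) {
  C <- length(dists_col)
  obj <- function(mu) {
    muC <- 1 - sum(mu)
    sum(mu^m * dists_col[-C]) + muC^m * dists_col[C]
  }
  grad <- function(mu) {
    muC <- 1 - sum(mu)
    m * mu^(m - 1) * dists_col[-C] - m * muC^(m - 1) * dists_col[C]
  }
  fit <- optim(rep(1 / C, C - 1L), obj, grad, method = "L-BFGS-B",
               lower = 1e-12, upper = 1,
               control = list(maxit = 2000, factr = 10))
  mu <- unname(fit$par)
  c(mu, 1 - sum(mu))
}

# Numerical minimizer over one center row (unconstrained BFGS).
oracle_center_row <- function(X, U_row, w_row, m) {
  a <- U_row^m
  obj <- function(v) {
    diff2 <- sweep(X, 2L, v, "-")^2
    sum(a * as.vector(diff2 %*% w_row))
  }
  fit <- optim(unname(colMeans(X)) + 0.5, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  unname(fit$par)
}

# Plain-distance weighted squared distances used by the oracles.
oracle_weighted_dists <- function(X, V, W) {
  C <- nrow(V)
  D <- matrix(0, C, nrow(X))
  for (c in seq_len(C)) {
    for (i in seq_len(nrow(X))) {
      D[c, i] <- sum(W[c, ] * (X[i, ] - V[c, ])^2)
    }
  }
  D
}

# One textbook fuzzy-c-means sweep (memberships from plain squared Euclidean
# distances, then centers), written independently of the package.
fcm_sweep <- function(X, U, m) {
  Um <- U^m
  V <- sweep(Um %*% X, 1L, rowSums(Um), "/")
  C <- nrow(U); N <- nrow(X)
  D <- matrix(0, C, N)
  for (c in seq_len(C)) D[c, ] <- colSums((t(X) - V[c, ])^2)
  U_new <- matrix(0, C, N)
  for (i in seq_len(N)) {
    if (any(D[, i] < 1e-12)) {
      U_new[D[, i] < 1e-12, i] <- 1 / sum(D[, i] < 1e-12)
    } else {
      r <- D[, i]^(-1 / (m - 1))
      U_new[, i] <- r / sum(r)
    }
  }
  list(U = U_new, V = V)
}

# Small ground-truth TSK model with a given activation pattern.
make_true_tsk <- function(seed, K = 3, d = 4, active_counts = NULL,
                          mode = "reduced") {
  set.seed(seed)
  centers <- matrix(rnorm(K * d, sd = 3), K, d)
  spreads <- matrix(runif(K * d, 0.3, 1), K, d)
  active <- matrix(TRUE, K, d)
  if (!is.null(active_counts)) {
    active <- matrix(FALSE, K, d)
    for (k in seq_len(K)) active[k, seq_len(active_counts[k])] <- TRUE
  }
  antecedent <- structure(list(centers = centers, spreads = spreads,
                               active = active, threshold = 0,
                               spread_scale = 0.5,
                               feature_names = paste0("x", seq_len(d))),
                          class = "antecedent_model")
  lens <- if (mode == "reduced") rowSums(active) + 1L else rep(d + 1L, K)
  coefficients <- lapply(lens, function(L) round(rnorm(L), 2))
  consequent <- structure(list(coefficients = coefficients, mode = mode,
                               ridge = 0, negative = "neg", positive = "pos"),
                          class = "consequent_model")
  list(antecedent = antecedent, consequent = consequent)
}

# Rule-wise TSK output (weighted sum of per-rule linear consequents), the
# defuzzification route, written independently of the design-vector route.
rulewise_score <- function(x, antecedent, consequent) {
  K <- nrow(antecedent$centers)
  raw <- numeric(K)
  for (k in seq_len(K)) {
    prod_k <- 1
    for (j in which(antecedent$active[k, ])) {
      prod_k <- prod_k * exp(-(x[j] - antecedent$centers[k, j])^2 /
                               (2 * antecedent$spreads[k, j]))
    }
    raw[k] <- prod_k
  }
  g <- raw / sum(raw)
  total <- 0
  for (k in seq_len(K)) {
    p <- consequent$coefficients[[k]]
    feats <- if (consequent$mode == "reduced") {
      x[antecedent$active[k, ]]
    } else {
      x
    }
    total <- total + g[k] * (p[1L] + sum(p[-1L] * feats))
  }
  total
}
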