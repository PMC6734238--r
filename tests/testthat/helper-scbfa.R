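# Shared fixtures and oracles, all generated in code.

# Random small count matrix.
random_counts <- function(N, G, lambda = 2, seed = 1) {
  scbfa:::with_seed(seed, {
    m <- matrix(rpois(N * G, lambda), N, G)
    CountMatrix(m)
  })
}

# Detection matrix sampled directly from the Bernoulli factor model with
# cluster-structured embeddings; returns data plus the generating pieces.
gen_model_detection <- function(N, G, K, n_types = 2, signal = 2.5,
                                a_scale = 1, seed = 1) {
  scbfa:::with_seed(seed, {
    centroids <- matrix(rnorm(n_types * K, 0, signal), n_types, K)
    lab <- rep_len(seq_len(n_types), N)
    Z <- centroids[lab, , drop = FALSE] + matrix(rnorm(N * K, 0, 0.3), N, K)
    A <- matrix(rnorm(K * G, 0, a_scale / sqrt(K)), K, G)
    u <- rnorm(N, 0, 0.3)
    v <- rnorm(G, 0, 0.5)
    eta <- Z %*% A + u
    eta <- sweep(eta, 2, v, "+")
    mu <- plogis(eta)
    B <- matrix(rbinom(N * G, 1, as.vector(mu)), N, G)
    list(B = B, Z = Z, A = A, u = u, v = v, mu = mu, labels = lab)
  })
}

# Keep only features with both outcomes present (fit_scbfa requirement).
drop_degenerate_features <- function(B) {
  gm <- colMeans(B)
  B[, gm > 0 & gm < 1, drop = FALSE]
}

# Rank-based AUROC oracle (midranks).
auroc_oracle <- function(scores, truth) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Central finite differences of penalized_loglik over the flattened
# (Z, A, u, v) parameters — the independent oracle for the analytic gradient.
fd_gradient <- function(B, fit, hyper, eps = 1e-6) {
  N <- nrow(fit$Z); K <- ncol(fit$Z); G <- ncol(fit$A)
  flat <- c(fit$Z, fit$A, fit$u, fit$v)
  f <- function(p) {
    fp <- fit
    i <- 0
    fp$Z <- matrix(p[i + seq_len(N * K)], N, K); i <- i + N * K
    fp$A <- matrix(p[i + seq_len(K * G)], K, G); i <- i + K * G
    fp$u <- p[i + seq_len(N)]; i <- i + N
    fp$v <- p[i + seq_len(G)]
    penalized_loglik(B, fp, hyper = hyper)
  }
  vapply(seq_along(flat), function(j) {
    p1 <- flat; p1[j] <- p1[j] + eps
    p2 <- flat; p2[j] <- p2[j] - eps
    (f(p1) - f(p2)) / (2 * eps)
  }, numeric(1))
}

random_param_point <- function(N, G, K, seed) {
  scbfa:::with_seed(seed, list(
    Z = matrix(rnorm(N * K, 0, 0.7), N, K),
    A = matrix(rnorm(K * G, 0, 0.7), K, G),
    beta = matrix(0, 0, G),
    u = rnorm(N, 0, 0.5),
    v = rnorm(G, 0, 0.5)))
}
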