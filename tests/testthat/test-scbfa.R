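test_that("standardize_covariates z-scores with sample sd", {
  d <- standardize_covariates(cbind(a = c(1, 2, 3)))
  expect_equal(as.vector(d$X), c(-1, 0, 1))          # sample sd of 1:3 is 1
  two <- cbind(x = c(-1.5, 0.5, 1), y = c(2, -2, 0))
  z <- standardize_covariates(two)$X
  expect_equal(colMeans(z), c(x = 0, y = 0))
  expect_equal(apply(z, 2, sd), c(x = 1, y = 1))
  # already standardized -> unchanged
  expect_equal(standardize_covariates(z)$X, z, tolerance = 1e-12)
  expect_error(standardize_covariates(cbind(ok = 1:3, k = rep(2, 3))), "k")
})

test_that("penalized_loglik evaluates the stated objective", {
  N <- 4; G <- 3
  B <- matrix(rep(c(0, 1), 6), N, G)
  zero_fit <- list(Z = matrix(0, N, 2), A = matrix(0, 2, G),
                   beta = matrix(0, 0, G), u = rep(0, N), v = rep(0, G))
  hy <- ScbfaHyper(K = 2, eps0 = 0)
  expect_equal(penalized_loglik(B, zero_fit, hyper = hy), N * G * log(0.5))

  one <- list(Z = matrix(0, 1, 1), A = matrix(0, 1, 1),
              beta = matrix(0, 0, 1), u = qlogis(0.9), v = 0)
  expect_equal(penalized_loglik(matrix(1, 1, 1), one,
                                hyper = ScbfaHyper(K = 1, eps0 = 0)),
               log(0.9))

  # adding eps2 > 0 with nonzero Z lowers the value by exactly eps2 ||Z||^2
  fit <- random_param_point(N, G, 2, seed = 4)
  l0 <- penalized_loglik(B, fit, hyper = ScbfaHyper(K = 2, eps0 = 0))
  l2 <- penalized_loglik(B, fit, hyper = ScbfaHyper(K = 2, eps0 = 0,
                                                    eps2 = 0.3))
  expect_equal(l0 - l2, 0.3 * sum(fit$Z^2))
  fit$u[1] <- NaN
  expect_error(penalized_loglik(B, fit, hyper = hy), "NaN")
})

test_that("analytic gradient matches central finite differences", {
  for (seed in 1:6) {
    scbfa:::with_seed(100 + seed, {
      N <- sample(4:9, 1); G <- sample(4:9, 1); K <- sample(1:3, 1)
      B <- matrix(rbinom(N * G, 1, 0.5), N, G)
    })
    fit <- random_param_point(N, G, K, seed = 200 + seed)
    hy <- scbfa:::resolve_hyper(ScbfaHyper(K = K), N, G)
    g <- scbfa_gradient(B, fit, hyper = hy)
    an <- c(g$Z, g$A, g$u, g$v)
    fd <- fd_gradient(B, fit, hy)
    expect_lt(max(abs(an - fd) / pmax(abs(fd), 1)), 1e-5)
  }
})

test_that("gradient vanishes at a numerically-found optimum", {
  scbfa:::with_seed(55, {
    N <- 5; G <- 4; K <- 1
    B <- matrix(rbinom(N * G, 1, 0.5), N, G)
  })
  B <- drop_degenerate_features(B)
  G <- ncol(B)
  hy <- scbfa:::resolve_hyper(ScbfaHyper(K = 1), N, G)
  nll <- function(p) {
    fit <- list(Z = matrix(p[1:N], N, 1), A = matrix(p[N + 1:G], 1, G),
                beta = matrix(0, 0, G), u = p[N + G + 1:N],
                v = p[2 * N + G + 1:G])
    -penalized_loglik(B, fit, hyper = hy)
  }
  opt <- optim(rep(0.01, 2 * N + 2 * G), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  p <- opt$par
  fit <- list(Z = matrix(p[1:N], N, 1), A = matrix(p[N + 1:G], 1, G),
              beta = matrix(0, 0, G), u = p[N + G + 1:N],
              v = p[2 * N + G + 1:G])
  g <- scbfa_gradient(B, fit, hyper = hy)
  expect_lt(max(abs(c(g$Z, g$A, g$u, g$v))), 1e-4)
})

test_that("intercept gradients are zero on complementary-row data at zero", {
  B <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))      # paired complementary rows
  fit <- list(Z = matrix(0, 2, 1), A = matrix(0, 1, 4),
              beta = matrix(0, 0, 4), u = rep(0, 2), v = rep(0, 4))
  g <- scbfa_gradient(B, fit, hyper = ScbfaHyper(K = 1, eps0 = 0))
  expect_equal(g$u, rep(0, 2))
  expect_equal(g$v, rep(0, 4))
})

test_that("fit_scbfa recovers model-generated detection structure", {
  gen <- gen_model_detection(N = 120, G = 80, K = 2, a_scale = 2, seed = 8)
  B <- DetectionMatrix(drop_degenerate_features(gen$B))
  fit <- fit_scbfa(B, hyper = ScbfaHyper(K = 2, seed = 1))
  expect_true(fit$converged)
  expect_false(is.unsorted(fit$objective_trace))
  mu <- fitted_detection_prob(fit)
  expect_gt(auroc_oracle(as.vector(mu), as.vector(B$values)), 0.9)
})

test_that("fit depends only on the detection pattern (scale invariance)", {
  cm <- random_counts(40, 25, lambda = 1, seed = 14)
  keep <- colMeans(cm$values > 0) > 0 & colMeans(cm$values > 0) < 1
  cm <- CountMatrix(cm$values[, keep])
  f1 <- fit_scbfa(cm, hyper = ScbfaHyper(K = 2, seed = 3))
  f7 <- fit_scbfa(CountMatrix(cm$values * 7), hyper = ScbfaHyper(K = 2, seed = 3))
  expect_identical(f1$Z, f7$Z)
  expect_identical(f1$objective, f7$objective)
})

test_that("two seeds reach objectives within the multi-start tolerance", {
  gen <- gen_model_detection(N = 100, G = 60, K = 2, seed = 17)
  B <- DetectionMatrix(drop_degenerate_features(gen$B))
  fa <- fit_scbfa(B, hyper = ScbfaHyper(K = 2, seed = 1))
  fb <- fit_scbfa(B, hyper = ScbfaHyper(K = 2, seed = 99))
  expect_lt(abs(fa$objective - fb$objective) / abs(fa$objective), 1e-3)
})

test_that("||Z|| shrinks monotonically as eps2 grows", {
  gen <- gen_model_detection(N = 60, G = 40, K = 2, seed = 23)
  B <- DetectionMatrix(drop_degenerate_features(gen$B))
  # raw (pre-orthogonalization) norm: rebalancing equalizes ||Z|| and ||A||,
  # but the eps2 penalty acts on the raw optimizer Z
  nz <- sapply(c(1, 50, 2000), function(e2) {
    f <- fit_scbfa(B, hyper = ScbfaHyper(K = 2, eps2 = e2, seed = 1))
    f$raw_frobenius[["Z"]]
  })
  expect_true(all(diff(nz) < 0))
})

test_that("one factor separates complementary gene-block cell types", {
  # type 1 detects the first gene block, type 2 the second; the per-cell
  # intercepts absorb overall detection rate, so Z must carry the contrast
  scbfa:::with_seed(29, {
    N <- 60; G <- 40
    blockA <- cbind(matrix(rbinom(30 * 20, 1, 0.9), 30, 20),
                    matrix(rbinom(30 * 20, 1, 0.1), 30, 20))
    blockB <- cbind(matrix(rbinom(30 * 20, 1, 0.1), 30, 20),
                    matrix(rbinom(30 * 20, 1, 0.9), 30, 20))
  })
  B <- DetectionMatrix(drop_degenerate_features(rbind(blockA, blockB)))
  fit <- fit_scbfa(B, hyper = ScbfaHyper(K = 1, seed = 1))
  z <- fit$Z[, 1]
  lab <- rep(1:2, each = 30)
  expect_true(max(z[lab == 1]) < min(z[lab == 2]) ||
              min(z[lab == 1]) > max(z[lab == 2]))
})

test_that("degenerate inputs are rejected with guidance", {
  expect_error(fit_scbfa(DetectionMatrix(matrix(1, 4, 4))), "degenerate")
  Bm <- matrix(rep(c(0, 1), 8), 4, 4)
  Bm[, 2] <- 1
  expect_error(fit_scbfa(DetectionMatrix(Bm)), "qc_filter")
})

test_that("orthogonalize splits the SVD and preserves the product", {
  o <- orthogonalize(2 * diag(2), diag(2))
  expect_equal(o$Z, sqrt(2) * diag(2))
  expect_equal(o$A, sqrt(2) * diag(2))

  scbfa:::with_seed(41, {
    Z <- matrix(rnorm(30), 10, 3)
    A <- matrix(rnorm(24), 3, 8)
  })
  o2 <- orthogonalize(Z, A)
  expect_lt(norm(o2$Z %*% o2$A - Z %*% A, "F"), 1e-10 * norm(Z %*% A, "F"))
  expect_lt(abs(norm(o2$Z, "F") - norm(o2$A, "F")), 1e-10)
  ZtZ <- crossprod(o2$Z)
  expect_lt(max(abs(ZtZ[upper.tri(ZtZ)])), 1e-10)
  # singular values ordered decreasing
  expect_false(is.unsorted(rev(diag(ZtZ))))

  # already balanced orthogonal pair is a fixed point up to sign
  o3 <- orthogonalize(o2$Z, o2$A)
  expect_equal(abs(o3$Z), abs(o2$Z), tolerance = 1e-8)
  # sign convention: largest-magnitude loading per factor positive
  for (k in 1:3) expect_gt(o3$A[k, which.max(abs(o3$A[k, ]))], 0)
})

test_that("orthogonalization preserves the linear predictor of a fit", {
  gen <- gen_model_detection(N = 50, G = 30, K = 2, seed = 43)
  B <- drop_degenerate_features(gen$B)
  fit <- fit_scbfa(DetectionMatrix(B), hyper = ScbfaHyper(K = 2, seed = 1))
  # refit pieces: orthogonalize again and compare predictors
  o <- orthogonalize(fit$Z, fit$A)
  expect_lt(max(abs(o$Z %*% o$A - fit$Z %*% fit$A)), 1e-8)
})

test_that("binary_pca equals PCA of the detection matrix", {
  cm <- random_counts(10, 8, lambda = 1, seed = 47)
  res_counts <- binary_pca(cm, 3)
  res_B <- binary_pca(binarize(cm), 3)
  expect_identical(res_counts$embeddings, res_B$embeddings)

  # dense eigendecomposition oracle
  B <- binarize(cm)$values
  Bc <- sweep(B, 2, colMeans(B))
  eig <- eigen(crossprod(Bc) / (nrow(B) - 1), symmetric = TRUE)
  emb_oracle <- Bc %*% eig$vectors[, 1:3]
  for (k in 1:3) {
    a <- res_counts$embeddings[, k]; b <- emb_oracle[, k]
    expect_equal(abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))), 1,
                 tolerance = 1e-8)
    expect_equal(sd(a), sd(b), tolerance = 1e-8)
  }
  expect_equal(res_counts$explained_variance[1:3], eig$values[1:3],
               tolerance = 1e-8)

  # constant detection column contributes nothing
  m <- cbind(matrix(rpois(40, 2), 10, 4), rep(1, 10))
  r <- binary_pca(CountMatrix(m), 2)
  expect_equal(unname(r$loadings[, 5]), c(0, 0), tolerance = 1e-12)
  expect_error(binary_pca(cm, 10), "K exceeds")
})

test_that("including a true batch covariate decorrelates Z from batch", {
  # batch enters as a gene-wise detection offset
  scbfa:::with_seed(53, {
    N <- 120; G <- 60; K <- 2
    gen <- gen_model_detection(N = N, G = G, K = K, seed = 53)
    batch <- rep(c(0, 1), length.out = N)
    shift <- matrix(rnorm(G, 0, 1.5), N, G, byrow = TRUE) * batch
    eta <- qlogis(pmin(pmax(gen$mu, 1e-6), 1 - 1e-6)) + shift
    B <- matrix(rbinom(N * G, 1, as.vector(plogis(eta))), N, G)
  })
  keep <- colMeans(B) > 0 & colMeans(B) < 1
  B <- B[, keep]
  Bd <- DetectionMatrix(B)
  X <- standardize_covariates(cbind(batch = batch))
  f0 <- fit_scbfa(Bd, hyper = ScbfaHyper(K = K, seed = 1))
  f1 <- fit_scbfa(Bd, X = X, hyper = ScbfaHyper(K = K, seed = 1))
  cor0 <- max(abs(cor(f0$Z, batch)))
  cor1 <- max(abs(cor(f1$Z, batch)))
  expect_lt(cor1, cor0)
})
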