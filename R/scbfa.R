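#' Hyperparameters of the detection-pattern factor model
#'
#' The penalized Bernoulli factor model shrinks loadings A, embeddings Z
#' and covariate coefficients beta with ridge penalties eps1, eps2, eps3.
#' Defaults follow the scale heuristic eps0 = max(N, G), eps1 = eps3 =
#' eps0 / G, eps2 = eps0 / N, computed from the dimensions of the matrix
#' the model actually sees (post-QC, post-gene-selection). Pass `NULL` for
#' the eps values to use the defaults.
#'
#' @param K number of latent factors (>= 1).
#' @param eps0 regularization scale; `NULL` = `max(N, G)` at fit time.
#' @param eps1,eps2,eps3 ridge penalties on A, Z, beta; `NULL` = derived
#'   from `eps0` at fit time.
#' @param max_iter maximum quasi-Newton iterations (default 500).
#' @param tol relative objective-change convergence tolerance (default 1e-8).
#' @param seed RNG seed for factor initialization.
#' @return list of class `ScbfaHyper`.
#' @export
ScbfaHyper <- function(K, eps0 = NULL, eps1 = NULL, eps2 = NULL,
                       eps3 = NULL, max_iter = 500, tol = 1e-8, seed = 1L) {
  stopifnot(K >= 1, max_iter >= 1, tol > 0)
  for (e in list(eps0, eps1, eps2, eps3))
    if (!is.null(e) && e < 0) stop("penalties must be nonnegative")
  structure(list(K = as.integer(K), eps0 = eps0, eps1 = eps1, eps2 = eps2,
                 eps3 = eps3, max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "ScbfaHyper")
}

# Resolve NULL penalties against the data dimensions.
resolve_hyper <- function(hyper, N, G) {
  eps0 <- hyper$eps0 %||% max(N, G)
  hyper$eps0 <- eps0
  hyper$eps1 <- hyper$eps1 %||% (eps0 / G)
  hyper$eps2 <- hyper$eps2 %||% (eps0 / N)
  hyper$eps3 <- hyper$eps3 %||% (eps0 / G)
  hyper
}

#' Standardize a cell-level covariate matrix
#'
#' Per-column z-scoring (sample standard deviation). The means and scales
#' are stored so the same transform — or a fresh standardization, as the
#' plug-in batch correction requires — can be applied to subsets.
#'
#' @param X numeric N x C matrix of raw covariates.
#' @param column_names optional column names.
#' @return list of class `CovariateDesign` with `X` (standardized),
#'   `column_names`, `center`, `scale`, `standardized = TRUE`.
#' @export
standardize_covariates <- function(X, column_names = NULL) {
  X <- as.matrix(X)
  column_names <- column_names %||% colnames(X) %||%
    paste0("covariate", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0))
    stop("constant covariate column: ",
         paste(column_names[scl == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  colnames(Xs) <- column_names
  structure(list(X = Xs, column_names = column_names,
                 center = ctr, scale = scl, standardized = TRUE),
            class = "CovariateDesign")
}

# Stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x < 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

CLIP_LOGIT <- 30

# Linear predictor eta_ij = x_i' beta_j + z_i' a_j + u_i + v_j, clipped.
linear_predictor <- function(Z, A, beta, u, v, X) {
  eta <- Z %*% A + u
  eta <- sweep(eta, 2L, v, "+")
  if (!is.null(X) && length(beta)) eta <- eta + X %*% beta
  pmin(pmax(eta, -CLIP_LOGIT), CLIP_LOGIT)
}

#' Penalized Bernoulli log-likelihood of a fit
#'
#' Evaluates `sum_ij [B_ij log mu_ij + (1 - B_ij) log(1 - mu_ij)] -
#' eps1 ||A||_F^2 - eps2 ||Z||_F^2 - eps3 ||beta||_F^2`, where
#' `logit(mu_ij) = x_i' beta_j + z_i' a_j + u_i + v_j`. Logits are clipped
#' to +/-30 before the sigmoid so the log terms stay finite.
#'
#' @param B a [DetectionMatrix()] or binary matrix.
#' @param fit a [ScbfaFit] (or any list with `Z`, `A`, `beta`, `u`, `v`).
#' @param X a [standardize_covariates()] design, or `NULL`.
#' @param hyper a [ScbfaHyper()]; `NULL` penalties are resolved from the
#'   data dimensions.
#' @return scalar penalized log-likelihood (larger is better).
#' @export
penalized_loglik <- function(B, fit, X = NULL, hyper = NULL) {
  Bm <- if (inherits(B, "DetectionMatrix")) B$values else as.matrix(B)
  N <- nrow(Bm); G <- ncol(Bm)
  hyper <- resolve_hyper(hyper %||% ScbfaHyper(K = ncol(fit$Z)), N, G)
  pars <- list(fit$Z, fit$A, fit$beta, fit$u, fit$v)
  if (any(vapply(pars, function(p) length(p) && anyNA(p), logical(1))))
    stop("NaN/NA in model parameters")
  Xm <- if (is.null(X)) NULL else X$X
  eta <- linear_predictor(fit$Z, fit$A, fit$beta, fit$u, fit$v, Xm)
  ll <- sum(Bm * eta) - sum(log1pexp(eta))
  ll - hyper$eps1 * sum(fit$A^2) - hyper$eps2 * sum(fit$Z^2) -
    hyper$eps3 * sum(fit$beta^2)
}

#' Analytic gradient of the penalized log-likelihood
#'
#' Returns the partial derivatives of [penalized_loglik()] with respect to
#' every parameter block, in the same shapes: with residual
#' `R_ij = B_ij - mu_ij`, `dZ = R A' - 2 eps2 Z`, `dA = Z' R - 2 eps1 A`,
#' `dbeta = X' R - 2 eps3 beta`, `du = rowSums(R)`, `dv = colSums(R)`.
#'
#' @inheritParams penalized_loglik
#' @return list with elements `Z`, `A`, `beta`, `u`, `v`.
#' @export
scbfa_gradient <- function(B, fit, X = NULL, hyper = NULL) {
  Bm <- if (inherits(B, "DetectionMatrix")) B$values else as.matrix(B)
  N <- nrow(Bm); G <- ncol(Bm)
  hyper <- resolve_hyper(hyper %||% ScbfaHyper(K = ncol(fit$Z)), N, G)
  Xm <- if (is.null(X)) NULL else X$X
  eta <- linear_predictor(fit$Z, fit$A, fit$beta, fit$u, fit$v, Xm)
  R <- Bm - stats::plogis(eta)
  list(Z = R %*% t(fit$A) - 2 * hyper$eps2 * fit$Z,
       A = crossprod(fit$Z, R) - 2 * hyper$eps1 * fit$A,
       beta = if (is.null(Xm) || !length(fit$beta)) fit$beta
              else crossprod(Xm, R) - 2 * hyper$eps3 * fit$beta,
       u = rowSums(R),
       v = colSums(R))
}

# ---- parameter vector packing -------------------------------------------

pack_params <- function(Z, A, beta, u, v) c(Z, A, beta, u, v)

unpack_params <- function(par, N, G, K, C) {
  i <- 0L
  Z <- matrix(par[i + seq_len(N * K)], N, K); i <- i + N * K
  A <- matrix(par[i + seq_len(K * G)], K, G); i <- i + K * G
  beta <- if (C > 0) matrix(par[i + seq_len(C * G)], C, G) else
    matrix(0, 0, G)
  i <- i + C * G
  u <- par[i + seq_len(N)]; i <- i + N
  v <- par[i + seq_len(G)]
  list(Z = Z, A = A, beta = beta, u = u, v = v)
}

#' Fit the detection-pattern factor model
#'
#' Maximizes the penalized Bernoulli likelihood jointly over all parameter
#' blocks (one flattened vector) with the L-BFGS-B quasi-Newton routine and
#' the analytic gradient. Initialization: cell intercepts at the logit of
#' each cell's detection rate, gene intercepts at the logit of each gene's
#' detection rate minus the grand-mean logit, factors and coefficients from
#' Normal(0, 0.1^2) under `hyper$seed`. After convergence, Z and A are
#' orthogonalized (see [orthogonalize()]), which leaves every fitted
#' probability unchanged.
#'
#' Features detected in no cell, or in every cell, make the corresponding
#' unpenalized gene intercepts diverge; such features are rejected — run
#' [qc_filter()] first.
#'
#' @param B a [DetectionMatrix()] (a [CountMatrix()] is binarized first).
#' @param X optional [standardize_covariates()] design for nuisance
#'   correction, or `NULL`.
#' @param hyper a [ScbfaHyper()].
#' @param beta_fixed optional C x G matrix: freeze the covariate
#'   coefficients at these values (plug-in batch correction) and estimate
#'   only Z, A, u, v.
#' @return object of class `ScbfaFit`: list with `Z` (N x K), `A` (K x G),
#'   `beta` (C x G), `u`, `v`, `hyper` (resolved), `raw_frobenius`
#'   (Frobenius norms of Z and A before rebalancing — the quantities the
#'   penalties act on), `objective_trace` (penalized log-likelihood at
#'   accepted improvements), `converged`, `n_iter`.
#' @export
fit_scbfa <- function(B, X = NULL, hyper = ScbfaHyper(K = 2), beta_fixed = NULL) {
  B <- binarize(B)
  Bm <- B$values
  N <- nrow(Bm); G <- ncol(Bm)
  if (all(Bm == 0) || all(Bm == 1))
    stop("degenerate detection matrix: needs at least one 0 and one 1")
  gmean <- colMeans(Bm)
  if (any(gmean == 0) || any(gmean == 1))
    stop("features with all-zero or all-one detection present; ",
         "run qc_filter first")
  if (hyper$K >= min(N, G)) stop("K must be smaller than min(N, G)")
  hyper <- resolve_hyper(hyper, N, G)
  K <- hyper$K

  Xm <- if (is.null(X)) NULL else X$X
  C <- if (is.null(Xm)) 0L else ncol(Xm)
  estimate_beta <- C > 0L && is.null(beta_fixed)
  offset_beta <- if (!is.null(beta_fixed)) beta_fixed else NULL

  cmean <- pmin(pmax(rowMeans(Bm), 1e-6), 1 - 1e-6)
  gm <- pmin(pmax(gmean, 1e-6), 1 - 1e-6)
  u0 <- pmin(pmax(stats::qlogis(cmean), -CLIP_LOGIT), CLIP_LOGIT)
  v0 <- pmin(pmax(stats::qlogis(gm) - stats::qlogis(mean(Bm)),
                  -CLIP_LOGIT), CLIP_LOGIT)
  init <- with_seed(hyper$seed, {
    list(Z = matrix(stats::rnorm(N * K, 0, 0.1), N, K),
         A = matrix(stats::rnorm(K * G, 0, 0.1), K, G),
         beta = if (estimate_beta)
           matrix(stats::rnorm(C * G, 0, 0.1), C, G) else matrix(0, 0, G))
  })

  Cfree <- if (estimate_beta) C else 0L
  trace_env <- new.env(parent = emptyenv())
  trace_env$vals <- numeric(0)

  negobj <- function(par) {
    p <- unpack_params(par, N, G, K, Cfree)
    eta <- Z_eta(p, Xm, offset_beta)
    ll <- sum(Bm * eta) - sum(log1pexp(eta))
    pen <- hyper$eps1 * sum(p$A^2) + hyper$eps2 * sum(p$Z^2) +
      (if (Cfree > 0) hyper$eps3 * sum(p$beta^2) else 0)
    val <- ll - pen
    n <- length(trace_env$vals)
    if (n == 0L || val > trace_env$vals[n])
      trace_env$vals <- c(trace_env$vals, val)
    -val
  }
  Z_eta <- function(p, Xm, offset_beta) {
    eta <- p$Z %*% p$A + p$u
    eta <- sweep(eta, 2L, p$v, "+")
    if (Cfree > 0) eta <- eta + Xm %*% p$beta
    if (!is.null(offset_beta)) eta <- eta + Xm %*% offset_beta
    pmin(pmax(eta, -CLIP_LOGIT), CLIP_LOGIT)
  }
  neggrad <- function(par) {
    p <- unpack_params(par, N, G, K, Cfree)
    eta <- Z_eta(p, Xm, offset_beta)
    R <- Bm - stats::plogis(eta)
    gZ <- R %*% t(p$A) - 2 * hyper$eps2 * p$Z
    gA <- crossprod(p$Z, R) - 2 * hyper$eps1 * p$A
    gB <- if (Cfree > 0) crossprod(Xm, R) - 2 * hyper$eps3 * p$beta else
      numeric(0)
    -c(gZ, gA, gB, rowSums(R), colSums(R))
  }

  par0 <- pack_params(init$Z, init$A, init$beta, u0, v0)
  opt <- stats::optim(par0, fn = negobj, gr = neggrad, method = "L-BFGS-B",
                      control = list(maxit = hyper$max_iter,
                                     factr = hyper$tol / .Machine$double.eps))
  p <- unpack_params(opt$par, N, G, K, Cfree)
  raw_frob <- c(Z = sqrt(sum(p$Z^2)), A = sqrt(sum(p$A^2)))
  orth <- orthogonalize(p$Z, p$A)

  beta_out <- if (!is.null(beta_fixed)) beta_fixed else p$beta
  structure(list(Z = orth$Z, A = orth$A, beta = beta_out, u = p$u, v = p$v,
                 cell_ids = B$cell_ids, feature_ids = B$feature_ids,
                 hyper = hyper,
                 raw_frobenius = raw_frob,
                 objective_trace = trace_env$vals,
                 objective = -opt$value,
                 converged = opt$convergence == 0L,
                 n_iter = opt$counts[["function"]]),
            class = "ScbfaFit")
}

#' @export
print.ScbfaFit <- function(x, ...) {
  cat(sprintf(
    "ScbfaFit: %d cells x %d features, K = %d, objective %.4g, %s\n",
    nrow(x$Z), ncol(x$A), ncol(x$Z), x$objective,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fitted detection probabilities of a model
#' @param fit a [ScbfaFit].
#' @param X optional covariate design used at fit time.
#' @return N x G matrix of fitted Bernoulli means.
#' @export
fitted_detection_prob <- function(fit, X = NULL) {
  Xm <- if (is.null(X)) NULL else X$X
  stats::plogis(linear_predictor(fit$Z, fit$A, fit$beta, fit$u, fit$v, Xm))
}

#' Orthogonalize an embedding/loading pair
#'
#' Rebalances Z and A without changing their product: take the SVD
#' `Z A = U D V'` (rank <= K) and return `Z' = U D^(1/2)`,
#' `A' = D^(1/2) V'`. The columns of Z' are mutually orthogonal, factors
#' are ordered by decreasing singular value, `||Z'||_F = ||A'||_F`, and the
#' sign of each factor is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param Z N x K matrix.
#' @param A K x G matrix.
#' @return list with rebalanced `Z` and `A`.
#' @export
orthogonalize <- function(Z, A) {
  K <- ncol(Z)
  stopifnot(nrow(A) == K)
  qz <- qr(Z)
  s <- svd(qr.R(qz) %*% A, nu = K, nv = K)
  U <- qr.Q(qz) %*% s$u
  d <- s$d[seq_len(K)]
  sq <- sqrt(pmax(d, 0))
  Zn <- U %*% diag(sq, K)
  An <- diag(sq, K) %*% t(s$v)
  for (k in seq_len(K)) {
    j <- which.max(abs(An[k, ]))
    if (An[k, j] < 0) {
      An[k, ] <- -An[k, ]
      Zn[, k] <- -Zn[, k]
    }
  }
  rownames(Zn) <- rownames(Z)
  colnames(An) <- colnames(A)
  list(Z = Zn, A = An)
}

#' Binary PCA: principal components of the detection pattern
#'
#' The fast approximation to the Bernoulli factor model: binarize the
#' counts, column-center the detection matrix (no unit-variance scaling —
#' genes with more variable detection should contribute more, since
#' detection variance tracks marker status), and take the top K principal
#' components.
#'
#' @param counts_or_B a [CountMatrix()] or [DetectionMatrix()].
#' @param K number of components; must satisfy `K <= min(N - 1, G)`.
#' @return list with `embeddings` (N x K), `loadings` (K x G),
#'   `explained_variance` (K component variances) and
#'   `explained_variance_ratio`.
#' @export
binary_pca <- function(counts_or_B, K) {
  B <- binarize(counts_or_B)
  N <- nrow(B$values); G <- ncol(B$values)
  if (K > min(N - 1, G))
    stop("K exceeds min(N - 1, G)")
  pc <- stats::prcomp(B$values, center = TRUE, scale. = FALSE, rank. = K)
  ev <- pc$sdev^2
  list(embeddings = pc$x[, seq_len(K), drop = FALSE],
       loadings = t(pc$rotation[, seq_len(K), drop = FALSE]),
       explained_variance = ev[seq_len(K)],
       explained_variance_ratio = ev[seq_len(K)] / sum(ev))
}
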