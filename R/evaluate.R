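#' Matthews correlation coefficient from a confusion matrix
#'
#' Two classes use the classical formula
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; more classes use
#' the Gorodkin multiclass generalization. A zero denominator returns 0.
#'
#' @param confusion square L x L matrix of nonnegative counts, true classes
#'   in rows, predicted classes in columns.
#' @return scalar in `[-1, 1]`.
#' @export
mcc_from_confusion <- function(confusion) {
  C <- as.matrix(confusion)
  if (nrow(C) != ncol(C)) stop("confusion matrix must be square")
  if (any(C < 0)) stop("confusion matrix entries must be nonnegative")
  if (sum(rowSums(C) > 0) < 2L && sum(colSums(C) > 0) < 2L)
    stop("need at least two classes with nonzero totals")
  if (nrow(C) == 2L) {
    tp <- C[1, 1]; tn <- C[2, 2]; fp <- C[2, 1]; fn <- C[1, 2]
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) return(0)
    return((tp * tn - fp * fn) / den)
  }
  s <- sum(C)
  c0 <- sum(diag(C))
  t <- rowSums(C)   # true-class totals
  p <- colSums(C)   # predicted-class totals
  num <- c0 * s - sum(t * p)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) return(0)
  num / den
}

# Multinomial (softmax) logistic regression with a tiny ridge to guarantee
# termination on linearly separable embeddings.
fit_multinom_logit <- function(x, y, ridge = 1e-6, maxit = 200) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  L <- length(classes)
  if (L < 2L) stop("need at least two classes")
  yi <- match(y, classes)
  n <- nrow(x); p <- ncol(x)
  Xd <- cbind(1, x)
  Y <- matrix(0, n, L); Y[cbind(seq_len(n), yi)] <- 1

  nll <- function(w) {
    W <- matrix(w, p + 1L, L - 1L)
    eta <- cbind(Xd %*% W, 0)
    eta <- eta - apply(eta, 1L, max)
    logZ <- log(rowSums(exp(eta)))
    -sum(eta[cbind(seq_len(n), yi)] - logZ) + ridge * sum(W^2)
  }
  grad <- function(w) {
    W <- matrix(w, p + 1L, L - 1L)
    eta <- cbind(Xd %*% W, 0)
    eta <- eta - apply(eta, 1L, max)
    P <- exp(eta); P <- P / rowSums(P)
    as.vector(crossprod(Xd, (P - Y)[, -L, drop = FALSE])) + 2 * ridge * w
  }
  w0 <- numeric((p + 1L) * (L - 1L))
  opt <- stats::optim(w0, nll, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(W = matrix(opt$par, p + 1L, L - 1L), classes = classes)
}

predict_multinom_logit <- function(model, x) {
  eta <- cbind(cbind(1, as.matrix(x)) %*% model$W, 0)
  model$classes[max.col(eta, ties.method = "first")]
}

#' Repeated cross-validated MCC of an embedding
#'
#' How well a low-dimensional embedding separates known cell types:
#' stratified five-fold cross-validation of a multinomial logistic
#' classifier (tiny ridge 1e-6 for termination on separable data), with the
#' test-fold predictions of each repeat pooled into one confusion matrix
#' and summarized as a Matthews correlation coefficient. The mean over
#' repeats is the headline accuracy.
#'
#' @param Z N x K embedding matrix.
#' @param labels N class labels.
#' @param folds number of CV folds (default 5).
#' @param repeats number of CV repetitions (default 15).
#' @param seed RNG seed; fold assignments are reproducible bitwise.
#' @return list of class `EvalReport` with `mcc_per_repeat`, `mcc_mean`,
#'   `config`.
#' @export
crossval_mcc <- function(Z, labels, folds = 5, repeats = 15, seed = 1L) {
  Z <- as.matrix(Z)
  labels <- as.character(labels)
  stopifnot(nrow(Z) == length(labels))
  classes <- sort(unique(labels))
  tab <- table(labels)
  if (any(tab < folds))
    stop("class smaller than fold count: ",
         paste(names(tab)[tab < folds], collapse = ", "))
  n <- nrow(Z)
  mccs <- with_seed(seed, vapply(seq_len(repeats), function(r) {
    fold <- integer(n)
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    pred <- character(n)
    for (f in seq_len(folds)) {
      test <- fold == f
      model <- fit_multinom_logit(Z[!test, , drop = FALSE], labels[!test])
      pred[test] <- predict_multinom_logit(model, Z[test, , drop = FALSE])
    }
    conf <- table(factor(labels, classes), factor(pred, classes))
    mcc_from_confusion(unclass(conf))
  }, numeric(1)))
  structure(list(mcc_per_repeat = mccs, mcc_mean = mean(mccs),
                 config = list(folds = folds, repeats = repeats, seed = seed,
                               K = ncol(Z), n = n,
                               classes = classes)),
            class = "EvalReport")
}

#' Averaged within-group sum of squares of an embedding
#'
#' Homogeneity of an embedding of technical replicates: with W the
#' column-centered embedding, `AWSS = trace(W'W) / (N - 1)`, i.e. the sum
#' of the per-column sample variances. Smaller is more homogeneous.
#'
#' @param Z N x K embedding matrix, N >= 2.
#' @return nonnegative scalar.
#' @export
awss <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2L) stop("awss requires at least 2 rows")
  W <- sweep(Z, 2L, colMeans(Z))
  sum(W^2) / (nrow(Z) - 1L)
}

#' Marker-gene enrichment of factor loadings (AUROC)
#'
#' For each factor, genes are scored by the absolute value of their
#' loading and the AUROC of marker membership against that score is
#' computed (midrank tie handling; a total tie gives 0.5). High values mean
#' the factor concentrates its weight on the known markers.
#'
#' @param A K x G loading matrix with feature ids as column names.
#' @param marker_ids character vector of marker feature ids; the
#'   intersection with the analyzed features is used and its size reported.
#' @return numeric vector of K AUROCs with attribute `n_markers_used`.
#' @export
marker_auroc <- function(A, marker_ids) {
  A <- as.matrix(A)
  feats <- colnames(A)
  if (is.null(feats)) stop("loading matrix must carry feature ids as colnames")
  if (length(marker_ids) == 0L) stop("empty marker set")
  is_marker <- feats %in% marker_ids
  n1 <- sum(is_marker); n0 <- sum(!is_marker)
  if (n1 == 0L) stop("no markers intersect the analyzed features")
  if (n0 == 0L) stop("marker set covers all features; AUROC undefined")
  out <- apply(A, 1L, function(a) {
    r <- rank(abs(a), ties.method = "average")
    (sum(r[is_marker]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  attr(out, "n_markers_used") <- n1
  out
}

# Shannon entropy (nats) of a count vector.
entropy_counts <- function(k) {
  p <- k[k > 0] / sum(k)
  -sum(p * log(p))
}

#' Normalized mutual information of two partitions
#'
#' Square-root normalization: `NMI = I(u, v) / sqrt(H(u) H(v))`. Returns 0
#' when either partition is trivial (zero entropy).
#'
#' @param a,b label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  hu <- entropy_counts(rowSums(tab))
  hv <- entropy_counts(colSums(tab))
  if (hu == 0 || hv == 0) return(0)
  pij <- tab / n
  pi_ <- rowSums(tab) / n
  pj_ <- colSums(tab) / n
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  I / sqrt(hu * hv)
}

#' Adjusted Rand index of two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions, approximately 0
#' for independent ones. A degenerate denominator returns 0.
#'
#' @param a,b label vectors of equal length.
#' @return scalar (at most 1).
#' @export
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_ <- si * sj / choose(n, 2)
  max_ <- (si + sj) / 2
  if (max_ == exp_) return(0)
  (sij - exp_) / (max_ - exp_)
}

#' Clustering agreement of an embedding with known labels
#'
#' Agglomerative clustering with Ward linkage (the `ward.D2` dialect on
#' Euclidean distances), cut at `n_clusters`, scored against the labels by
#' NMI (square-root normalization) and ARI.
#'
#' @param Z N x K embedding matrix.
#' @param labels N class labels.
#' @param n_clusters number of clusters; default = number of label classes.
#' @return list with `nmi`, `ari` and the cluster `assignment`.
#' @export
cluster_score <- function(Z, labels, n_clusters = NULL) {
  Z <- as.matrix(Z)
  labels <- as.character(labels)
  n_clusters <- n_clusters %||% length(unique(labels))
  if (n_clusters < 2L) stop("n_clusters must be at least 2")
  if (n_clusters > nrow(Z)) stop("n_clusters exceeds number of cells")
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  cl <- stats::cutree(hc, k = n_clusters)
  list(nmi = nmi(cl, labels), ari = ari(cl, labels), assignment = cl)
}

#' Plug-in batch correction for confounded designs
#'
#' When some batches lack some cell types, batch coefficients cannot be
#' estimated on the full data without absorbing biology. The plug-in
#' scheme: (1) find the largest subset of cell types present in every
#' batch; (2) fit the detection model on that subset (with its own
#' standardized design) to obtain the coefficient estimate `beta_hat`
#' only; (3) refit on the full data with beta frozen at `beta_hat`,
#' estimating Z, A, u, v.
#'
#' @param B a [DetectionMatrix()].
#' @param X raw (unstandardized) N x C covariate matrix encoding the
#'   nuisance factors; standardized internally on the subset and on the
#'   full data separately.
#' @param labels N cell-type labels.
#' @param batches N batch labels.
#' @param hyper a [ScbfaHyper()].
#' @return a [fit_scbfa()] result on the full data with frozen beta;
#'   attribute `plugin` records the subset cell types and `beta_hat`.
#' @export
batch_plugin_fit <- function(B, X, labels, batches, hyper = ScbfaHyper(K = 2)) {
  B <- binarize(B)
  labels <- as.character(labels)
  batches <- as.character(batches)
  stopifnot(nrow(B$values) == length(labels),
            length(labels) == length(batches))
  tab <- table(labels, batches)
  common <- rownames(tab)[apply(tab > 0, 1L, all)]
  if (length(common) == 0L)
    stop("no cell type is present in every batch; ",
         "use the direct covariate path instead")
  sub <- labels %in% common
  X <- as.matrix(X)

  if (all(X == 0)) {
    # null design: nothing to correct; beta_hat = 0 and the plug-in fit
    # reduces to the plain fit
    fit <- fit_scbfa(B, X = NULL, hyper = hyper)
    attr(fit, "plugin") <- list(common_types = common,
                                beta_hat = matrix(0, ncol(X), ncol(B$values)))
    return(fit)
  }

  X_sub <- standardize_covariates(X[sub, , drop = FALSE])
  B_sub <- DetectionMatrix(B$values[sub, , drop = FALSE])
  # subset may re-degenerate some features; drop them from the beta fit only
  gm <- colMeans(B_sub$values)
  ok <- gm > 0 & gm < 1
  beta_hat <- matrix(0, ncol(X), ncol(B$values))
  fit_sub <- fit_scbfa(DetectionMatrix(B_sub$values[, ok, drop = FALSE]),
                       X = X_sub, hyper = hyper)
  beta_hat[, ok] <- fit_sub$beta

  X_full <- standardize_covariates(X)
  fit <- fit_scbfa(B, X = X_full, hyper = hyper, beta_fixed = beta_hat)
  attr(fit, "plugin") <- list(common_types = common, beta_hat = beta_hat)
  fit
}

#' Plug-in batch correction, linear-residual path for PCA
#'
#' The analog of [batch_plugin_fit()] for methods without a covariate
#' slot: regress the standardized subset design out of the subset
#' observations by least squares, apply the learned coefficients to
#' residualize the full observation matrix, then run PCA on the residuals.
#'
#' @param M N x G observation matrix (normalized counts or detection).
#' @param X raw N x C covariate matrix.
#' @param labels,batches as in [batch_plugin_fit()].
#' @param K number of principal components.
#' @return list with `embeddings`, `loadings`, `beta_hat`, `common_types`.
#' @export
batch_plugin_pca <- function(M, X, labels, batches, K) {
  M <- as.matrix(M)
  labels <- as.character(labels)
  batches <- as.character(batches)
  tab <- table(labels, batches)
  common <- rownames(tab)[apply(tab > 0, 1L, all)]
  if (length(common) == 0L) stop("no cell type is present in every batch")
  sub <- labels %in% common
  Xs <- standardize_covariates(as.matrix(X)[sub, , drop = FALSE])
  beta_hat <- qr.solve(Xs$X, M[sub, , drop = FALSE])  # C x G
  Xf <- standardize_covariates(as.matrix(X))
  R <- M - Xf$X %*% beta_hat
  pc <- stats::prcomp(R, center = TRUE, scale. = FALSE, rank. = K)
  list(embeddings = pc$x[, seq_len(K), drop = FALSE],
       loadings = t(pc$rotation[, seq_len(K), drop = FALSE]),
       beta_hat = beta_hat, common_types = common)
}
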