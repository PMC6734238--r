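#' Synthetic ground truth for the two-channel count simulator
#'
#' Builds the "hatted" generative parameters that a fit of a zero-inflated
#' negative binomial factor model to real data would supply: a
#' cluster-structured shared embedding (cell-type centroids plus
#' within-type jitter), independent loading matrices for the detection
#' (dropout) and count channels, and cell/gene intercepts. The global
#' detection intercept is calibrated by 1-d root finding so that, with no
#' channel noise and no global dropout shift (delta = 0), the expected gene
#' detection rate — including the chance of a sampling zero from the
#' negative binomial at reference dispersion `r_ref` — matches
#' `baseline_detection`.
#'
#' @param N,G numbers of cells and features.
#' @param K latent dimensions (default 5).
#' @param n_celltypes number of cell types; cells are assigned in
#'   near-equal blocks.
#' @param baseline_detection target expected GDR at delta = 0 (in (0, 1)).
#' @param seed RNG seed; the truth is bitwise reproducible.
#' @param centroid_sd,jitter_sd between-type and within-type spread of the
#'   shared embedding (defaults 1.5 and 0.3).
#' @param logit_sd,logmu_sd target standard deviations of the factor
#'   contribution to the dropout logit and the log count mean (defaults 1.5
#'   and 1.0).
#' @param logmu_center center of the gene-level log mean expression
#'   (default log(2)).
#' @param r_ref reference NB size used in the GDR calibration (default 1,
#'   the middle of the simulation grid).
#' @return list of class `SimulationTruth` with `Z_hat` (N x K), `A_mu`,
#'   `A_pi` (K x G), `u_mu`, `u_pi` (N), `v_mu`, `v_pi` (G), `labels` (N).
#' @export
make_ground_truth <- function(N, G, K = 5, n_celltypes = 4,
                              baseline_detection = 0.3, seed = 1L,
                              centroid_sd = 1.5, jitter_sd = 0.3,
                              logit_sd = 1.5, logmu_sd = 1.0,
                              logmu_center = log(2), r_ref = 1) {
  stopifnot(n_celltypes <= N, K >= 1)
  if (baseline_detection <= 0 || baseline_detection >= 1)
    stop("baseline_detection must lie strictly in (0, 1)")
  with_seed(seed, {
    centroids <- matrix(stats::rnorm(n_celltypes * K, 0, centroid_sd),
                        n_celltypes, K)
    labels <- sort(rep_len(seq_len(n_celltypes), N))
    Z_hat <- centroids[labels, , drop = FALSE] +
      matrix(stats::rnorm(N * K, 0, jitter_sd), N, K)

    # scale loadings so Var(z' a) matches the requested logit/log-mean sd
    z_var <- mean(Z_hat^2)
    a_sd_pi <- logit_sd / sqrt(K * z_var)
    a_sd_mu <- logmu_sd / sqrt(K * z_var)
    A_pi <- matrix(stats::rnorm(K * G, 0, a_sd_pi), K, G)
    A_mu <- matrix(stats::rnorm(K * G, 0, a_sd_mu), K, G)

    u_pi <- stats::rnorm(N, 0, 0.5)
    v_pi <- stats::rnorm(G, 0, 0.5)
    u_mu <- stats::rnorm(N, 0, 0.3)
    v_mu <- stats::rnorm(G, logmu_center, 0.7)

    l_pi <- Z_hat %*% A_pi + u_pi
    l_pi <- sweep(l_pi, 2L, v_pi, "+")
    l_mu <- Z_hat %*% A_mu + u_mu
    l_mu <- sweep(l_mu, 2L, v_mu, "+")
    mu <- exp(pmin(l_mu, 30))
    p_nb_zero <- (r_ref / (r_ref + mu))^r_ref

    expected_gdr <- function(c0)
      mean((1 - stats::plogis(l_pi + c0)) * (1 - p_nb_zero))
    max_gdr <- expected_gdr(-30)  # dropout suppressed at the low extreme
    if (baseline_detection >= max_gdr)
      stop(sprintf(
        "baseline_detection %.3f infeasible: NB sampling zeros cap GDR at %.3f",
        baseline_detection, max_gdr))
    c0 <- stats::uniroot(function(c0) expected_gdr(c0) - baseline_detection,
                         c(-30, 30), tol = 1e-8)$root
    v_pi <- v_pi + c0

    structure(list(Z_hat = Z_hat, A_mu = A_mu, A_pi = A_pi,
                   u_mu = u_mu, u_pi = u_pi, v_mu = v_mu, v_pi = v_pi,
                   labels = paste0("type", labels),
                   K = K, baseline_detection = baseline_detection,
                   r_ref = r_ref, seed = as.integer(seed)),
              class = "SimulationTruth")
  })
}

#' One setting of the simulation noise grid
#'
#' @param delta global dropout shift; enters the dropout logit with a minus
#'   sign, so larger delta means fewer dropouts and a higher detection rate.
#' @param sigma2_pi detection-channel embedding noise variance.
#' @param sigma2_mu count-channel embedding noise variance.
#' @param r shared NB size (dispersion) parameter; variance mu + mu^2 / r.
#' @param replicate replicate index.
#' @param seed RNG seed driving all randomness of [simulate_dataset()].
#' @return list of class `NoiseSetting`.
#' @export
NoiseSetting <- function(delta, sigma2_pi, sigma2_mu, r, replicate = 1L,
                         seed = 1L) {
  stopifnot(sigma2_pi >= 0, sigma2_mu >= 0, r > 0)
  structure(list(delta = delta, sigma2_pi = sigma2_pi,
                 sigma2_mu = sigma2_mu, r = r,
                 replicate = as.integer(replicate), seed = as.integer(seed)),
            class = "NoiseSetting")
}

#' Simulate a count dataset with separate detection and count noise
#'
#' The two-channel generative model: each cell's shared embedding is
#' perturbed independently for the count channel
#' (`z_mu(i) ~ N(z_hat_i, sigma2_mu I)`) and the detection channel
#' (`z_pi(i) ~ N(z_hat_i, sigma2_pi I)`). Dropout probabilities follow
#' `logit(pi_ij) = z_pi(i)' a_pi(j) + u_pi(i) + v_pi(j) - delta`; count
#' means follow `log(mu_ij) = z_mu(i)' a_mu(j) + u_mu(i) + v_mu(j)`.
#' A dropout indicator `Pi_ij ~ Bernoulli(pi_ij)` zeroes the observation;
#' otherwise `O_ij ~ NB(mean mu_ij, size r)`.
#'
#' @param truth a [make_ground_truth()] object.
#' @param setting a [NoiseSetting()].
#' @return list of class `SimulatedDataset` with `counts` ([CountMatrix()]),
#'   `dropout_indicators`, `pi`, `mu`, `Z_pi`, `Z_mu`, `truth`, `setting`.
#' @export
simulate_dataset <- function(truth, setting) {
  stopifnot(inherits(truth, "SimulationTruth"),
            inherits(setting, "NoiseSetting"))
  N <- nrow(truth$Z_hat); G <- ncol(truth$A_mu); K <- truth$K
  with_seed(setting$seed, {
    Z_mu <- truth$Z_hat +
      matrix(stats::rnorm(N * K, 0, sqrt(setting$sigma2_mu)), N, K)
    Z_pi <- truth$Z_hat +
      matrix(stats::rnorm(N * K, 0, sqrt(setting$sigma2_pi)), N, K)

    l_pi <- Z_pi %*% truth$A_pi + truth$u_pi
    l_pi <- sweep(l_pi, 2L, truth$v_pi, "+") - setting$delta
    pi_mat <- stats::plogis(l_pi)

    l_mu <- Z_mu %*% truth$A_mu + truth$u_mu
    l_mu <- sweep(l_mu, 2L, truth$v_mu, "+")
    if (max(l_mu) > 30)
      stop("overflow in exp(log mu); rescale the ground truth ",
           "(reduce logmu_sd or logmu_center)")
    mu <- exp(l_mu)

    Pi <- matrix(stats::rbinom(N * G, 1L, as.vector(pi_mat)), N, G)
    O <- matrix(stats::rnbinom(N * G, size = setting$r,
                               mu = as.vector(mu)), N, G)
    O[Pi == 1L] <- 0L

    counts <- CountMatrix(O,
                          cell_ids = paste0("cell", seq_len(N)),
                          feature_ids = paste0("gene", seq_len(G)))
    structure(list(counts = counts, dropout_indicators = Pi,
                   pi = pi_mat, mu = mu, Z_pi = Z_pi, Z_mu = Z_mu,
                   labels = truth$labels, truth = truth, setting = setting),
              class = "SimulatedDataset")
  })
}

#' Quality-control a simulated dataset
#'
#' Drops features detected in fewer than `min_frac` of cells, then cells
#' detecting fewer than `min_frac` of the remaining features, subsetting
#' the attached ground truth, labels and latent matrices consistently.
#'
#' @param data a [simulate_dataset()] result.
#' @param min_frac detection fraction threshold for both passes
#'   (default 0.01).
#' @return the filtered `SimulatedDataset`.
#' @export
qc_filter_simulated <- function(data, min_frac = 0.01) {
  stopifnot(inherits(data, "SimulatedDataset"))
  O <- data$counts$values
  keep_g <- colMeans(O >= 1) >= min_frac
  if (!any(keep_g)) stop("empty after QC: all features removed")
  O2 <- O[, keep_g, drop = FALSE]
  keep_c <- rowMeans(O2 >= 1) >= min_frac
  if (!any(keep_c)) stop("empty after QC: all cells removed")

  sub_truth <- data$truth
  sub_truth$Z_hat <- sub_truth$Z_hat[keep_c, , drop = FALSE]
  sub_truth$A_mu <- sub_truth$A_mu[, keep_g, drop = FALSE]
  sub_truth$A_pi <- sub_truth$A_pi[, keep_g, drop = FALSE]
  sub_truth$u_mu <- sub_truth$u_mu[keep_c]
  sub_truth$u_pi <- sub_truth$u_pi[keep_c]
  sub_truth$v_mu <- sub_truth$v_mu[keep_g]
  sub_truth$v_pi <- sub_truth$v_pi[keep_g]
  sub_truth$labels <- sub_truth$labels[keep_c]

  structure(list(
    counts = CountMatrix(O2[keep_c, , drop = FALSE]),
    dropout_indicators = data$dropout_indicators[keep_c, keep_g, drop = FALSE],
    pi = data$pi[keep_c, keep_g, drop = FALSE],
    mu = data$mu[keep_c, keep_g, drop = FALSE],
    Z_pi = data$Z_pi[keep_c, , drop = FALSE],
    Z_mu = data$Z_mu[keep_c, , drop = FALSE],
    labels = data$labels[keep_c],
    truth = sub_truth,
    setting = data$setting), class = "SimulatedDataset")
}

#' Enumerate the simulation noise grid
#'
#' Cartesian product of the dropout shift, the two channel noise variances,
#' the NB size and the replicate index, with a deterministic per-setting
#' seed derived by hashing the base seed together with the grid
#' coordinates (so settings can be simulated independently in any order).
#' The default grids give 5 x 5 x 5 x 3 = 375 unique settings and, with 3
#' replicates, 1125 datasets.
#'
#' @param deltas grid of dropout shifts.
#' @param sigmas2_pi,sigmas2_mu grids of channel noise variances.
#' @param rs grid of NB sizes.
#' @param replicates replicates per setting (default 3).
#' @param base_seed seed the per-setting seeds are derived from.
#' @return list of [NoiseSetting()] objects, length
#'   `length(deltas) * length(sigmas2_pi) * length(sigmas2_mu) * length(rs)
#'   * replicates`.
#' @export
simulation_grid <- function(deltas = c(-2, -0.5, 1, 2.5, 4),
                            sigmas2_pi = c(0.1, 0.5, 1, 2, 3),
                            sigmas2_mu = c(0.1, 0.5, 1, 2, 3),
                            rs = c(0.5, 1, 5),
                            replicates = 3, base_seed = 1L) {
  grid <- expand.grid(di = seq_along(deltas), pi = seq_along(sigmas2_pi),
                      mi = seq_along(sigmas2_mu), ri = seq_along(rs),
                      rep = seq_len(replicates))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    NoiseSetting(delta = deltas[g$di],
                 sigma2_pi = sigmas2_pi[g$pi],
                 sigma2_mu = sigmas2_mu[g$mi],
                 r = rs[g$ri],
                 replicate = g$rep,
                 seed = hash_seed(c(base_seed, g$di, g$pi, g$mi, g$ri, g$rep)))
  })
}

#' Poisson resampling of imputed expression rates
#'
#' Imputation outputs dense rate estimates that destroy the sparsity the
#' detection model relies on; resampling counts from
#' `O_ij ~ Poisson(s_i * lambda_ij)` restores a sparse count matrix with
#' the imputed means. `s_i` is the cell's library size divided by the mean
#' library size across cells.
#'
#' @param rates N x G matrix of positive imputed rates.
#' @param size_factors N positive cell size factors.
#' @param seed RNG seed.
#' @return a [CountMatrix()].
#' @export
poisson_resample <- function(rates, size_factors, seed = 1L) {
  rates <- as.matrix(rates)
  if (any(rates <= 0)) stop("rates must be strictly positive")
  if (any(size_factors <= 0)) stop("size_factors must be strictly positive")
  stopifnot(length(size_factors) == nrow(rates))
  with_seed(seed, {
    O <- matrix(stats::rpois(length(rates), size_factors * rates),
                nrow(rates), ncol(rates))
    dimnames(O) <- dimnames(rates)
    CountMatrix(O)
  })
}
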