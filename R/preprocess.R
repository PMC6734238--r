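#' Quality-control parameters
#'
#' Thresholds of the standard scRNA-seq QC cascade applied by [qc_filter()]:
#' drop cells dominated by mitochondrial counts, drop genes detected in too
#' few cells, drop cells with very small library sizes.
#'
#' @param mito_fraction_max drop cells whose mitochondrial count fraction
#'   exceeds this (default 0.50).
#' @param min_cell_fraction_per_gene drop genes detected (count >= 1) in
#'   fewer than this fraction of the remaining cells (default 0.01).
#' @param library_quantile_min drop cells whose library size is strictly
#'   below this quantile of remaining cells' library sizes (default 0.125,
#'   the one-eighth quantile).
#' @return a list of class `QcParams`.
#' @export
QcParams <- function(mito_fraction_max = 0.50,
                     min_cell_fraction_per_gene = 0.01,
                     library_quantile_min = 0.125) {
  for (v in c(mito_fraction_max, min_cell_fraction_per_gene,
              library_quantile_min))
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop("QcParams values must lie in (0, 1]")
  structure(list(mito_fraction_max = mito_fraction_max,
                 min_cell_fraction_per_gene = min_cell_fraction_per_gene,
                 library_quantile_min = library_quantile_min),
            class = "QcParams")
}

#' Apply standard quality-control filters to a count matrix
#'
#' Filters are applied in a fixed order: (1) cells with mitochondrial count
#' fraction above `mito_fraction_max`; (2) genes detected in fewer than
#' `min_cell_fraction_per_gene` of the remaining cells; (3) cells whose
#' library size falls strictly below the `library_quantile_min` quantile
#' (type-7, linear interpolation) of the remaining cells' library sizes.
#' Provenance — the ids removed at each step — is attached as the
#' `"qc_provenance"` attribute.
#'
#' @param counts a [CountMatrix()].
#' @param params a [QcParams()].
#' @return the filtered [CountMatrix()] with a `qc_provenance` attribute
#'   (list with `cells_mito`, `genes_rare`, `cells_small_library`).
#' @export
qc_filter <- function(counts, params = QcParams()) {
  stopifnot(inherits(counts, "CountMatrix"), inherits(params, "QcParams"))
  O <- counts$values

  lib <- rowSums(O)
  mito_frac <- if (any(counts$feature_is_mito)) {
    rowSums(O[, counts$feature_is_mito, drop = FALSE]) / pmax(lib, 1)
  } else rep(0, nrow(O))
  keep_cells1 <- mito_frac <= params$mito_fraction_max
  dropped_mito <- counts$cell_ids[!keep_cells1]
  O <- O[keep_cells1, , drop = FALSE]
  if (nrow(O) == 0L) stop("empty after QC: all cells removed (mito filter)")

  det_frac <- colMeans(O >= 1)
  keep_genes <- det_frac >= params$min_cell_fraction_per_gene
  dropped_genes <- colnames(O)[!keep_genes]
  O <- O[, keep_genes, drop = FALSE]
  if (ncol(O) == 0L) stop("empty after QC: all genes removed")

  lib <- rowSums(O)
  cut <- stats::quantile(lib, params$library_quantile_min, type = 7,
                         names = FALSE)
  keep_cells2 <- lib >= cut
  dropped_small <- rownames(O)[!keep_cells2]
  O <- O[keep_cells2, , drop = FALSE]
  if (nrow(O) == 0L) stop("empty after QC: all cells removed (library filter)")

  out <- CountMatrix(O,
                     feature_is_mito = counts$feature_is_mito[
                       match(colnames(O), counts$feature_ids)])
  attr(out, "qc_provenance") <- list(cells_mito = dropped_mito,
                                     genes_rare = dropped_genes,
                                     cells_small_library = dropped_small,
                                     library_size_cutoff = cut)
  out
}

#' Binarize counts into a detection pattern
#'
#' `B[i, j] = 1` iff `O[i, j] >= 1`. The detection matrix is the only data
#' the Bernoulli factor model sees, so any strictly positive rescaling of
#' the counts leaves downstream fits unchanged.
#'
#' @param counts a [CountMatrix()] (a [DetectionMatrix()] passes through).
#' @return a [DetectionMatrix()].
#' @export
binarize <- function(counts) {
  if (inherits(counts, "DetectionMatrix")) return(counts)
  stopifnot(inherits(counts, "CountMatrix"))
  DetectionMatrix((counts$values >= 1) * 1,
                  counts$cell_ids, counts$feature_ids)
}

#' Library-size log normalization
#'
#' scRNA-seq mode computes `log(O[i,j] / c_i + 1)` with `c_i` the library
#' size of cell i (natural log); scATAC-seq mode computes `log(O[i,j] + 1)`
#' with no library scaling.
#'
#' @param counts a [CountMatrix()].
#' @param mode `"scrna"` or `"scatac"`.
#' @return numeric matrix of the same shape with dimnames.
#' @export
normalize_log_library <- function(counts, mode = c("scrna", "scatac")) {
  stopifnot(inherits(counts, "CountMatrix"))
  mode <- match.arg(mode)
  O <- counts$values
  if (mode == "scatac") return(log1p(O))
  lib <- rowSums(O)
  if (any(lib == 0))
    stop("zero library size in scrna mode for cells: ",
         paste(counts$cell_ids[lib == 0], collapse = ", "))
  log1p(O / lib)
}

#' Gene detection rate of a detection matrix
#'
#' The grand mean of B: the fraction of cell-feature pairs detected. It is
#' identically the mean over cells of the per-cell detected fraction and
#' the mean over genes of the per-gene detection rate; both marginals are
#' attached as attributes.
#'
#' @param B a [DetectionMatrix()] (or a [CountMatrix()], binarized first).
#' @return scalar in `[0, 1]`, with attributes `per_cell` and `per_gene`.
#' @export
gene_detection_rate <- function(B) {
  B <- binarize(B)
  g <- mean(B$values)
  attr(g, "per_cell") <- rowMeans(B$values)
  attr(g, "per_gene") <- colMeans(B$values)
  g
}

#' Select highly expressed genes (HEG)
#'
#' Ranks genes by the sample variance of their raw counts across cells and
#' returns the top `n_genes`. Ties are broken by feature id lexicographic
#' order so the selection is fully deterministic.
#'
#' @param counts a [CountMatrix()].
#' @param n_genes number of genes to keep (default 2000).
#' @return integer vector of feature indices (into `counts$feature_ids`).
#' @export
select_heg <- function(counts, n_genes = 2000) {
  stopifnot(inherits(counts, "CountMatrix"))
  G <- ncol(counts$values)
  if (n_genes > G) stop("n_genes exceeds number of features")
  v <- apply(counts$values, 2L, stats::var)
  ord <- order(-v, counts$feature_ids)
  ord[seq_len(n_genes)]
}

#' Select highly variable genes (HVG)
#'
#' Deterministic standardized-variance procedure: fit a mean-variance trend
#' on log10 scale by local (loess) regression across genes, standardize each
#' gene's counts by its trend-expected standard deviation, clip the
#' standardized values at `sqrt(N)`, and rank genes by the variance of the
#' clipped values. Genes with zero variance score 0. Rankings approximate,
#' but are not guaranteed to match, external variance-stabilizing HVG tools.
#'
#' @param counts a [CountMatrix()].
#' @param n_genes number of genes to keep (default 2000).
#' @param loess_span span of the trend fit (default 0.3).
#' @return integer vector of feature indices, most variable first.
#' @export
select_hvg <- function(counts, n_genes = 2000, loess_span = 0.3) {
  stopifnot(inherits(counts, "CountMatrix"))
  O <- counts$values
  N <- nrow(O); G <- ncol(O)
  if (n_genes > G) stop("n_genes exceeds number of features")
  m <- colMeans(O)
  v <- apply(O, 2L, stats::var)
  usable <- m > 0 & v > 0
  if (length(unique(m[usable])) < 3L)
    stop("fewer than 3 distinct gene means: mean-variance trend unfittable")
  # widen the span when few genes are usable so the local fit has enough
  # points per neighborhood
  span_eff <- max(loess_span, min(1, 8 / sum(usable)))
  fit <- stats::loess(log10(v[usable]) ~ log10(m[usable]),
                      span = span_eff, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  exp_sd <- rep(NA_real_, G)
  exp_sd[usable] <- sqrt(10^stats::predict(fit, log10(m[usable])))
  clip <- sqrt(N)
  std_var <- vapply(seq_len(G), function(j) {
    if (!usable[j]) return(0)
    z <- (O[, j] - m[j]) / exp_sd[j]
    z <- pmin(z, clip)
    stats::var(z)
  }, numeric(1))
  ord <- order(-std_var, counts$feature_ids)
  ord[seq_len(n_genes)]
}

#' Per-gene mean and dispersion with a fitted trend
#'
#' Computes per-gene counts-per-million means (no transcript-length
#' correction: appropriate for UMI data), per-gene negative-binomial
#' dispersion by method of moments on size-factor-normalized counts
#' (`alpha_j = max(0, (s2_j - m_j) / m_j^2)`), trims the top and bottom
#' `trimmed_fraction` of genes by mean to avoid local-regression border
#' effects, and fits a local linear regression of dispersion on log10 mean.
#'
#' @param counts a [CountMatrix()] (ideally post-QC).
#' @param trimmed_fraction fraction trimmed from each tail of the gene-mean
#'   distribution before trend fitting (default 0.025).
#' @param loess_span span of the local regression (default 0.75).
#' @return a list of class `DispersionProfile` with `gene_mean_tpm`,
#'   `gene_dispersion`, `trend` (callable mean -> dispersion, input clamped
#'   to the trimmed mean range) and `trimmed_fraction`.
#' @export
dispersion_trend <- function(counts, trimmed_fraction = 0.025,
                             loess_span = 0.75) {
  stopifnot(inherits(counts, "CountMatrix"))
  O <- counts$values
  if (ncol(O) < 20L) stop("dispersion_trend requires at least 20 genes")
  lib <- rowSums(O)
  if (any(lib == 0)) stop("cells with zero library size; run qc_filter first")
  tpm <- colMeans(O / lib * 1e6)
  sf <- lib / mean(lib)
  Q <- O / sf
  m <- colMeans(Q)
  s2 <- apply(Q, 2L, stats::var)
  if (length(unique(m)) < 2L) stop("degenerate input: all gene means identical")
  alpha <- pmax(0, (s2 - m) / m^2)

  qs <- stats::quantile(m, c(trimmed_fraction, 1 - trimmed_fraction),
                        type = 7, names = FALSE)
  keep <- m >= qs[1] & m <= qs[2]
  lx <- log10(m[keep])
  fit <- stats::loess(alpha[keep] ~ lx, span = loess_span, degree = 1,
                      control = stats::loess.control(surface = "direct"))
  rng <- range(m[keep])
  trend <- function(mu) {
    mu <- pmin(pmax(mu, rng[1]), rng[2])
    pmax(0, stats::predict(fit, log10(mu)))
  }
  structure(list(gene_mean_tpm = tpm[keep],
                 gene_dispersion = alpha[keep],
                 gene_mean_norm = m[keep],
                 trend = trend,
                 trimmed_fraction = trimmed_fraction),
            class = "DispersionProfile")
}

#' Should this dataset be analyzed with a detection model?
#'
#' Reports the gene detection rate and a dispersion summary, and recommends
#' the detection-pattern factor model whenever the GDR falls strictly below
#' 90% — the regime in which detection patterns carry most of the usable
#' signal. At GDR exactly 0.90 the recommendation is `FALSE` (strict
#' inequality).
#'
#' @param counts a [CountMatrix()].
#' @param gdr_threshold recommendation threshold (default 0.90).
#' @return list with `gdr`, `dispersion_summary` (median trend dispersion,
#'   `NA` if the trend cannot be fit), `recommend_detection_model`.
#' @export
diagnose <- function(counts, gdr_threshold = 0.90) {
  stopifnot(inherits(counts, "CountMatrix"))
  gdr <- as.numeric(gene_detection_rate(binarize(counts)))
  disp_med <- tryCatch(suppressWarnings({
    prof <- dispersion_trend(counts)
    stats::median(prof$trend(prof$gene_mean_norm))
  }), error = function(e) NA_real_)
  list(gdr = gdr,
       dispersion_summary = disp_med,
       recommend_detection_model = gdr < gdr_threshold)
}
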