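# scbfa — detection-pattern factor analysis for single-cell genomics

Single-cell RNA-seq and ATAC-seq count matrices are mostly zeros. When
the gene detection rate (GDR — the fraction of cell×feature pairs with at
least one read or UMI) is low, the counts carry more technical noise than
signal, but the binary *pattern* of which features are detected in which
cells still tracks cell identity. This package embeds cells by modeling
only that pattern, for analysts working with sparse droplet-style
scRNA-seq or inherently near-binary scATAC-seq data.

## The model

With `B[i,j] = 1[O[i,j] >= 1]` the detection matrix of counts `O`
(N cells × G features), the package fits the penalized Bernoulli factor
model

    logit(mu_ij) = x_i' beta_j + z_i' a_j + u_i + v_j,
    B_ij ~ Bernoulli(mu_ij)

maximizing `sum_ij log P(B_ij) − eps1‖A‖² − eps2‖Z‖² − eps3‖beta‖²`
(defaults `eps0 = max(N,G)`, `eps1 = eps3 = eps0/G`, `eps2 = eps0/N`)
jointly by L-BFGS-B with the analytic gradient, followed by an
SVD-rebalancing of `Z` and `A` that leaves every fitted probability
unchanged. `binary_pca()` is the one-line approximation: PCA on the
column-centered `B` without unit-variance scaling.

Alongside the model the package ships the standard preprocessing cascade
(QC filters, log-library normalization, HVG/HEG gene selection,
`diagnose()` which recommends the detection model when GDR < 90%), a
two-channel count simulator that separates detection noise (`sigma2_pi`)
from quantification noise (`sigma2_mu`, NB size `r`, dropout shift
`delta`), and the evaluation suite (repeated cross-validated Matthews
correlation coefficient, AWSS replicate homogeneity, marker-gene AUROC,
Ward/NMI/ARI clustering agreement, plug-in batch correction for
confounded designs).

## Worked example

Simulate a dataset in the detection-favorable regime (low detection
noise, high count noise), fit the model, and compare cell-type separation
against PCA on log-normalized counts:

```r
library(scbfa)

truth <- make_ground_truth(N = 600, G = 300, K = 5, n_celltypes = 4,
                           baseline_detection = 0.3, seed = 1)
data  <- simulate_dataset(truth, NoiseSetting(delta = 1, sigma2_pi = 0.5,
                                              sigma2_mu = 3, r = 1, seed = 2))
data  <- qc_filter_simulated(data)
data$counts
#> CountMatrix: 600 cells x 300 features, 38.8% nonzero

diagnose(data$counts)[c("gdr", "recommend_detection_model")]
#> $gdr                        [1] 0.3878
#> $recommend_detection_model  [1] TRUE

fit <- fit_scbfa(binarize(data$counts), hyper = ScbfaHyper(K = 5, seed = 1))
fit
#> ScbfaFit: 600 cells x 300 features, K = 5, objective -9.78e+04, converged

crossval_mcc(fit$Z, data$labels, seed = 1)$mcc_mean
#> [1] 0.9

Zpca <- prcomp(normalize_log_library(data$counts, "scrna"),
               center = TRUE, scale. = FALSE, rank. = 5)$x
crossval_mcc(Zpca, data$labels, seed = 1)$mcc_mean
#> [1] 0.5266
```

Only 39% of entries are detected, so `diagnose()` recommends the
detection model; its embedding separates the four simulated cell types
far better (mean MCC 0.90 vs 0.53) because the count channel is the noisy
one here. Swapping the two noise variances reverses the outcome —
`run_regime_experiment()` scripts that comparison across replicates (in
our run: scBFA 0.81 vs count-PCA 0.47 at `sigma2_pi = 0.5, sigma2_mu =
3`; 0.71 vs 0.75 with the variances swapped).

## Command line

A thin wrapper around the same functions (installed at
`inst/bin/scbfa`, or call `cli_main()` directly):

```sh
scbfa fixture --profile two_types_clean --seed 1 --out fx/
scbfa diagnose --counts fx/counts.mtx
scbfa fit --counts fx/counts.mtx --k 5 --seed 1 --out run1
scbfa evaluate --embeddings run1.Z.tsv --labels fx/labels.txt --out report.json
```

Subcommands: `preprocess`, `diagnose`, `fit`, `binary-pca`, `simulate`,
`simulate-grid`, `evaluate`, `markers-auroc`, `cluster-score`, `fixture`,
`regime-experiment`. Every command writes a JSON run manifest (resolved
config, seeds, input digests, versions) sufficient to reproduce the run
bit-identically.

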