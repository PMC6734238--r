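#' Construct a cell-by-feature count matrix
#'
#' The canonical raw-data container of the package: a dense nonnegative
#' integer matrix with cells in rows and features (genes or loci) in
#' columns, carrying unique cell and feature identifiers and an optional
#' mitochondrial-feature mask used by [qc_filter()].
#'
#' @param values numeric matrix, N cells x G features, nonnegative integers.
#' @param cell_ids character vector of N unique cell identifiers. Defaults to
#'   existing rownames or `cell1..cellN`.
#' @param feature_ids character vector of G unique feature identifiers.
#'   Defaults to existing colnames or `gene1..geneG`.
#' @param feature_is_mito logical vector of length G flagging mitochondrial
#'   features; defaults to all `FALSE`. See [mito_mask_from_prefix()].
#' @return An object of class `CountMatrix`: a list with elements `values`
#'   (integer storage), `cell_ids`, `feature_ids`, `feature_is_mito`.
#' @seealso [binarize()], [qc_filter()], [read_counts()]
#' @export
CountMatrix <- function(values, cell_ids = NULL, feature_ids = NULL,
                        feature_is_mito = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("CountMatrix requires at least one cell and one feature")
  if (anyNA(values)) stop("CountMatrix values must not contain NA")
  if (any(values < 0)) stop("CountMatrix values must be nonnegative")
  nonint <- which(values != round(values))
  if (length(nonint) > 0L) {
    ij <- arrayInd(nonint[1L], dim(values))
    stop(sprintf("non-integer count at cell %d, feature %d: %g",
                 ij[1L], ij[2L], values[nonint[1L]]))
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("gene", seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length does not match number of rows")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length does not match number of columns")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell id: ", cell_ids[duplicated(cell_ids)][1L])
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ", feature_ids[duplicated(feature_ids)][1L])
  if (is.null(feature_is_mito)) feature_is_mito <- rep(FALSE, ncol(values))
  stopifnot(is.logical(feature_is_mito),
            length(feature_is_mito) == ncol(values))
  storage.mode(values) <- "double"
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(list(values = values, cell_ids = cell_ids,
                 feature_ids = feature_ids,
                 feature_is_mito = feature_is_mito),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d features, %.1f%% nonzero\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$values > 0)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' Construct a binary detection matrix
#'
#' Container for the detection pattern B, the sole data input of the
#' Bernoulli factor model: `B[i, j] = 1` iff feature j received at least one
#' read or UMI in cell i. Usually produced by [binarize()].
#'
#' @param values numeric matrix with entries in `{0, 1}`.
#' @param cell_ids,feature_ids identifiers, as for [CountMatrix()].
#' @return An object of class `DetectionMatrix`.
#' @export
DetectionMatrix <- function(values, cell_ids = NULL, feature_ids = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1)))
    stop("DetectionMatrix values must be 0 or 1")
  cm <- CountMatrix(values, cell_ids, feature_ids)
  structure(list(values = cm$values, cell_ids = cm$cell_ids,
                 feature_ids = cm$feature_ids),
            class = "DetectionMatrix")
}

#' @export
print.DetectionMatrix <- function(x, ...) {
  cat(sprintf("DetectionMatrix: %d cells x %d features, GDR %.3f\n",
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

#' @export
dim.DetectionMatrix <- function(x) dim(x$values)

#' Flag mitochondrial features by identifier prefix
#'
#' Convenience rule for building the `feature_is_mito` mask when the data
#' uses conventional gene symbols ("MT-" for human, "mt-" for mouse).
#'
#' @param feature_ids character vector of feature identifiers.
#' @param prefixes prefixes identifying mitochondrial genes.
#' @return logical vector of the same length.
#' @export
mito_mask_from_prefix <- function(feature_ids, prefixes = c("MT-", "mt-")) {
  Reduce(`|`, lapply(prefixes, function(p) startsWith(feature_ids, p)))
}

# Run expr with a temporarily-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 32-bit-safe integer hash of a vector of nonnegative integers,
# used to derive per-setting simulation seeds from a base seed.
hash_seed <- function(parts) {
  h <- 0
  for (p in as.numeric(parts)) {
    h <- (h * 69069 + p + 1) %% 2147483647
  }
  as.integer(h)
}
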