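#' Read a count matrix from disk
#'
#' Reads either MatrixMarket coordinate format (with plain-text row/column
#' name sidecar files, 10x style) or a delimited text matrix with a header
#' row and a first identifier column. The returned matrix is always cells x
#' features; files stored features-by-cells (the 10x convention) are
#' transposed on read.
#'
#' @param path path to the `.mtx` or delimited file.
#' @param format `"mtx"` or `"delimited"`.
#' @param orientation `"cells_by_features"` or `"features_by_cells"`; the
#'   on-disk layout.
#' @param row_ids_file,col_ids_file sidecar files holding one identifier per
#'   line for the MTX rows and columns. Default: `barcodes.tsv` /
#'   `features.tsv` next to `path` when orientation is features_by_cells is
#'   *not* assumed — the row sidecar names MTX rows, the column sidecar MTX
#'   columns, whatever they are.
#' @param sep field separator for delimited input; `NULL` auto-detects
#'   between tab and comma from the header line.
#' @return A [CountMatrix()].
#' @export
read_counts <- function(path,
                        format = c("mtx", "delimited"),
                        orientation = c("cells_by_features", "features_by_cells"),
                        row_ids_file = NULL, col_ids_file = NULL,
                        sep = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file: ",
                                           conditionMessage(e)))
    m <- as.matrix(m)
    dir <- dirname(path)
    stem <- sub("\\.mtx$", "", path)
    row_ids_file <- row_ids_file %||% first_existing(
      paste0(path, ".rownames"), paste0(stem, ".rownames"),
      file.path(dir, "barcodes.tsv"))
    col_ids_file <- col_ids_file %||% first_existing(
      paste0(path, ".colnames"), paste0(stem, ".colnames"),
      file.path(dir, "features.tsv"))
    if (is.null(row_ids_file) || is.null(col_ids_file))
      stop("MTX input requires row/column name sidecar files")
    rn <- readLines(row_ids_file)
    cn <- readLines(col_ids_file)
    # 10x features.tsv may carry extra columns; keep the first field
    rn <- vapply(strsplit(rn, "\t"), `[[`, character(1), 1L)
    cn <- vapply(strsplit(cn, "\t"), `[[`, character(1), 1L)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar id counts do not match matrix dimensions")
    rownames(m) <- rn
    colnames(m) <- cn
  } else {
    header <- readLines(path, n = 1L)
    if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed delimited matrix: fewer than 2 columns")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in delimited matrix")
    rownames(m) <- ids
  }

  if (orientation == "features_by_cells") m <- t(m)
  CountMatrix(m)
}

first_existing <- function(...) {
  for (p in c(...)) if (file.exists(p)) return(p)
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a count matrix as MatrixMarket plus sidecars
#'
#' @param counts a [CountMatrix()] or [DetectionMatrix()].
#' @param prefix path prefix; writes `<prefix>.mtx`, `<prefix>.mtx.rownames`,
#'   `<prefix>.mtx.colnames`.
#' @return invisibly, the `.mtx` path.
#' @export
write_counts_mtx <- function(counts, prefix) {
  path <- paste0(prefix, ".mtx")
  Matrix::writeMM(Matrix::Matrix(counts$values, sparse = TRUE), path)
  writeLines(counts$cell_ids, paste0(path, ".rownames"))
  writeLines(counts$feature_ids, paste0(path, ".colnames"))
  invisible(path)
}

#' Write a numeric matrix as tab-delimited text with ids
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_delim_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a run manifest for provenance
#'
#' Every CLI command records the resolved configuration, seeds, input file
#' digests and package version so a run can be reproduced bit-identically.
#'
#' @param command subcommand name.
#' @param config named list of resolved parameters.
#' @param seeds named list/vector of seeds used.
#' @param input_paths character vector of input files to digest (md5).
#' @return a list of class `RunManifest`.
#' @export
run_manifest <- function(command, config, seeds = list(), input_paths = character()) {
  hashes <- if (length(input_paths))
    as.list(tools::md5sum(input_paths)) else list()
  structure(list(
    command = command,
    config = config,
    seeds = seeds,
    input_hashes = hashes,
    versions = list(scbfa = as.character(utils::packageVersion("scbfa")),
                    R = R.version.string),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "RunManifest")
}

#' Write a manifest (or any report list) as JSON
#' @param x list to serialize.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
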