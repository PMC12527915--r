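#' Construct a cell-by-gene count matrix
#'
#' The sole primary input of the pipeline: a raw integer count matrix with
#' cells in rows and genes in columns. Cells with zero total count are
#' dropped with a warning because every downstream step divides by the
#' per-cell total.
#'
#' @param counts Non-negative integer matrix, cells x genes. Dimnames, if
#'   present, are used when `cell_ids`/`gene_ids` are missing.
#' @param cell_ids Character vector of cell identifiers (one per row).
#' @param gene_ids Character vector of unique gene identifiers (one per
#'   column).
#' @return An object of class `cell_counts` with fields `counts`,
#'   `cell_ids`, `gene_ids`.
#' @export
cell_counts <- function(counts, cell_ids = rownames(counts),
                        gene_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) stop("gene_ids are required")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts))
    stop("length(cell_ids) != nrow(counts)")
  if (length(gene_ids) != ncol(counts))
    stop("length(gene_ids) != ncol(counts)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integral")
  storage.mode(counts) <- "double"
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    drop <- which(totals == 0)
    warning(sprintf("dropping %d cell(s) with zero total count: %s",
                    length(drop),
                    paste(utils::head(cell_ids[drop], 5), collapse = ", ")))
    counts <- counts[-drop, , drop = FALSE]
    cell_ids <- cell_ids[-drop]
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d cells x %d genes, %.1f%% non-zero\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts > 0)))
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Supports MatrixMarket coordinate files with `genes.tsv` / `cells.tsv`
#' sidecars (one id per line, matrix stored cells x genes) and dense TSV
#' with a header row of gene ids and cell ids in the first column.
#'
#' @param path Path to the `.mtx` file or the dense TSV.
#' @param format `"auto"` (by extension), `"mtx"` or `"tsv"`.
#' @return A [cell_counts] object; zero-total cells are dropped with a
#'   warning.
#' @export
read_count_matrix <- function(path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file '",
                                           path, "': ", conditionMessage(e)))
    dir <- dirname(path)
    gene_file <- file.path(dir, "genes.tsv")
    cell_file <- file.path(dir, "cells.tsv")
    if (!file.exists(gene_file) || !file.exists(cell_file))
      stop("expected sidecar files genes.tsv and cells.tsv next to ", path)
    gene_ids <- readLines(gene_file)
    cell_ids <- readLines(cell_file)
    counts <- as.matrix(m)
    if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids))
      stop("matrix dimensions do not match sidecar id files")
    cell_counts(counts, cell_ids, gene_ids)
  } else {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("dense TSV needs a cell id column plus genes: ",
                           path)
    cell_ids <- as.character(df[[1]])
    counts <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("invalid entry at data line %d of %s", bad[1, 1], path))
    cell_counts(counts, cell_ids, colnames(df)[-1])
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_count_matrix()]; the write/read round trip is the
#' identity on valid matrices.
#'
#' @param x A [cell_counts] object.
#' @param path Output path (`.mtx` or `.tsv`).
#' @param format `"auto"`, `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("auto", "mtx", "tsv")) {
  stopifnot(inherits(x, "cell_counts"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(x$gene_ids, file.path(dirname(path), "genes.tsv"))
    writeLines(x$cell_ids, file.path(dirname(path), "cells.tsv"))
  } else {
    df <- data.frame(cell_id = x$cell_ids, x$counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Shifted-log normalization
#'
#' Per-cell proportions are scaled by a fixed factor `L`, shifted by one
#' and natural-log transformed:
#' \deqn{\tilde X_{n,g} = \log(L \, X_{n,g} / \sum_{g'} X_{n,g'} + 1).}
#' Zero counts map to exactly zero and the transform is strictly
#' increasing in the raw count for a fixed cell total.
#'
#' @param x A [cell_counts] object (all cell totals positive).
#' @param L Positive scale factor; the conventional depth of 1e4 by
#'   default.
#' @return A `normalized_matrix` object with fields `values`, `cell_ids`,
#'   `gene_ids`, `scale_factor`.
#' @export
shifted_log_normalize <- function(x, L = 1e4) {
  stopifnot(inherits(x, "cell_counts"))
  if (!is.numeric(L) || length(L) != 1 || L <= 0) stop("L must be > 0")
  totals <- rowSums(x$counts)
  if (any(totals == 0))
    stop("cell(s) with zero total count; drop them at load time")
  values <- log1p(L * x$counts / totals)
  dimnames(values) <- dimnames(x$counts)
  structure(list(values = values, cell_ids = x$cell_ids,
                 gene_ids = x$gene_ids, scale_factor = L),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes (L = %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Binomial downsampling of counts
#'
#' Thins every entry independently as
#' \eqn{X^{(ds)}_{n,g} \sim \mathrm{Binomial}(X_{n,g}, 1/r)}, emulating a
#' shallower sequencing run of the same library. `rate = 1` returns the
#' input unchanged; entries can never increase.
#'
#' @param x A [cell_counts] object.
#' @param rate Downsampling rate r >= 1 (the pretraining task draws r
#'   uniformly from \[1, 20)).
#' @param seed Integer seed; the same seed always yields the same draw.
#' @return A [cell_counts] object of thinned counts. Cells whose total
#'   drops to zero are retained here (the pretraining loop skips them),
#'   so the output may violate the positive-total invariant; it is a raw
#'   draw, not a validated dataset.
#' @export
binomial_downsample <- function(x, rate, seed) {
  stopifnot(inherits(x, "cell_counts"))
  if (!is.numeric(rate) || length(rate) != 1 || rate < 1)
    stop("rate must be a single number >= 1")
  if (rate == 1) return(x)
  set.seed(as.integer(seed))
  counts <- x$counts
  nz <- which(counts > 0)
  thinned <- counts
  thinned[nz] <- stats::rbinom(length(nz), size = as.integer(counts[nz]),
                               prob = 1 / rate)
  out <- x
  out$counts <- thinned
  out
}

#' Sample non-zero genes for one cell
#'
#' During training the encoder sees a uniform random subset of at most
#' `max_genes` of the cell's non-zero genes (a speed-up that doubles as
#' data augmentation); at inference every non-zero gene is included. The
#' returned indices are sorted ascending so batches are deterministic;
#' the encoder itself is permutation-invariant in token order.
#'
#' @param cell Numeric vector of raw counts for one cell.
#' @param max_genes Cap on the training subset size (default 2048).
#' @param seed Integer seed for the training subsample.
#' @param training If `TRUE` subsample, else return all non-zero genes.
#' @return Sorted integer vector of gene indices.
#' @export
sample_nonzero_genes <- function(cell, max_genes = 2048, seed = 1,
                                 training = FALSE) {
  nz <- which(cell > 0)
  if (length(nz) == 0) stop("cell has no non-zero gene")
  if (!training || length(nz) <= max_genes) return(nz)
  set.seed(as.integer(seed))
  sort(sample(nz, max_genes))
}
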