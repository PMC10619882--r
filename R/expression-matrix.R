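#' Cell-by-gene count container
#'
#' Bundles a sparse raw count matrix (cells in rows, genes in columns) with
#' per-cell and per-gene annotation tables. Per-cell totals, detected-gene
#' counts and mitochondrial fractions are always recomputed from the counts so
#' the metadata can never drift out of step with the matrix.
#'
#' @param counts matrix or `Matrix::dgCMatrix` of non-negative integer counts,
#'   cells in rows and genes in columns. Dimnames are used as cell and gene
#'   ids when `cell_ids`/`gene_ids` are not given.
#' @param cell_meta optional data frame of per-cell annotation; must contain a
#'   `cell_id` column (or have one row per cell in matrix order). A `batch`
#'   column, when present, is used by [batch_contribution_filter()].
#' @param gene_meta optional data frame of per-gene annotation with a
#'   `gene_id` column; an `is_mitochondrial` logical column drives the
#'   mitochondrial-fraction computation (genes named `mt-*` are flagged
#'   automatically when the column is absent).
#' @param cell_ids,gene_ids optional character vectors overriding dimnames.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `counts` (dgCMatrix), `cell_meta` (tibble with `cell_id`, `batch`,
#'   `total_counts`, `n_genes`, `mito_fraction`) and `gene_meta` (tibble with
#'   `gene_id`, `is_mitochondrial`, `marker_of`).
#' @export
#' @examples
#' m <- matrix(rpois(20, 2) + 1, nrow = 4,
#'             dimnames = list(paste0("c", 1:4), paste0("g", 1:5)))
#' expression_matrix(m)
expression_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL,
                              cell_ids = NULL, gene_ids = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts@x != round(counts@x))) {
    stop("counts must be integers", call. = FALSE)
  }
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%04d", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(ncol(counts)))
  dimnames(counts) <- list(cell_ids, gene_ids)

  if (is.null(gene_meta)) {
    gene_meta <- tibble::tibble(gene_id = gene_ids)
  } else {
    gene_meta <- tibble::as_tibble(gene_meta)
    if (!"gene_id" %in% names(gene_meta)) gene_meta$gene_id <- gene_ids
    gene_meta <- gene_meta[match(gene_ids, gene_meta$gene_id), , drop = FALSE]
  }
  if (!"is_mitochondrial" %in% names(gene_meta)) {
    gene_meta$is_mitochondrial <- startsWith(gene_meta$gene_id, "mt-")
  }
  if (!"marker_of" %in% names(gene_meta)) gene_meta$marker_of <- NA_integer_

  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(cell_id = cell_ids)
  } else {
    cell_meta <- tibble::as_tibble(cell_meta)
    if (!"cell_id" %in% names(cell_meta)) cell_meta$cell_id <- cell_ids
    cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  }
  if (!"batch" %in% names(cell_meta)) cell_meta$batch <- "batch1"

  totals <- Matrix::rowSums(counts)
  if (any(totals < 1)) {
    stop("every cell must have total count >= 1; offending cells: ",
         paste(utils::head(cell_ids[totals < 1], 5), collapse = ", "),
         call. = FALSE)
  }
  mito <- gene_meta$is_mitochondrial
  mito_counts <- if (any(mito)) Matrix::rowSums(counts[, mito, drop = FALSE]) else 0
  cell_meta$total_counts <- unname(totals)
  cell_meta$n_genes <- unname(Matrix::rowSums(counts > 0))
  cell_meta$mito_fraction <- unname(mito_counts / totals)

  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' @export
dimnames.expression_matrix <- function(x) dimnames(x$counts)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes (%.2f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  cat(sprintf("  batches: %s\n",
              paste(unique(x$cell_meta$batch), collapse = ", ")))
  cat(sprintf("  mitochondrial genes: %d; marker genes: %d\n",
              sum(x$gene_meta$is_mitochondrial),
              sum(!is.na(x$gene_meta$marker_of))))
  invisible(x)
}

#' Subset an expression matrix by cells and/or genes
#'
#' @param x an [expression_matrix()].
#' @param cells,genes character ids (or logical/integer indices) to keep.
#' @return A new `expression_matrix` restricted to the selection; per-cell QC
#'   columns are recomputed on the subset.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(cells)) cells <- rownames(x$counts)
  if (is.null(genes)) genes <- colnames(x$counts)
  keep_meta <- x$cell_meta[match(resolve_ids(cells, rownames(x$counts)),
                                 x$cell_meta$cell_id), , drop = FALSE]
  keep_meta$total_counts <- NULL; keep_meta$n_genes <- NULL
  keep_meta$mito_fraction <- NULL
  expression_matrix(x$counts[cells, genes, drop = FALSE],
                    cell_meta = keep_meta,
                    gene_meta = x$gene_meta[match(resolve_ids(genes, colnames(x$counts)),
                                                  x$gene_meta$gene_id), , drop = FALSE])
}

resolve_ids <- function(idx, ids) {
  if (is.character(idx)) idx else ids[idx]
}

#' Log-normalized expression container
#'
#' Created by [lognormalize()]; holds the log1p of depth-scaled expression
#' values together with the scale factor used, so the defining identity
#' `sum(exp(value) - 1) == scale_factor` per cell can always be re-checked.
#'
#' @param values sparse or dense numeric matrix, cells x genes.
#' @param scale_factor the scale factor the values were computed under.
#' @param cell_meta optional per-cell tibble carried over from the source
#'   counts.
#' @return An object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, scale_factor, cell_meta = NULL) {
  values <- methods::as(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  structure(list(values = values, scale_factor = scale_factor,
                 cell_meta = cell_meta),
            class = "normalized_matrix")
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' @export
dimnames.normalized_matrix <- function(x) dimnames(x$values)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d cells x %d genes, scale factor %g\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Column variances of a sparse matrix without densifying
#' @noRd
sparse_col_vars <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colMeans(m)
  sumsq <- Matrix::colSums(m^2)
  (sumsq - n * mu^2) / (n - 1)
}

as_label_tibble <- function(labels) {
  if (inherits(labels, "data.frame")) {
    stopifnot(all(c("cell_id", "cluster") %in% names(labels)))
    tibble::as_tibble(labels[c("cell_id", "cluster")])
  } else {
    if (is.null(names(labels))) {
      stop("labels must be a tibble with cell_id/cluster or a named vector",
           call. = FALSE)
    }
    tibble::tibble(cell_id = names(labels), cluster = as.character(unname(labels)))
  }
}
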