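#' Write an expression matrix in CellRanger-style MTX layout
#'
#' Writes `matrix.mtx` (Matrix Market coordinate, genes in rows as
#' CellRanger does, 1-based indices), `barcodes.tsv` (cell ids),
#' `features.tsv` (feature id, name, type) and `cell_meta.tsv` into `dir`.
#'
#' @param matrix an [expression_matrix()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(matrix, dir) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::t(matrix$counts), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(barcode = rownames(matrix$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(id = colnames(matrix$counts),
                                  name = colnames(matrix$counts),
                                  type = "Gene Expression"),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(matrix$cell_meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' Read a CellRanger-style MTX directory
#'
#' Expects the files written by [write_atlas()]; `cell_meta.tsv` is optional.
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return An [expression_matrix()].
#' @export
read_atlas <- function(dir) {
  counts <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = "barcode",
                              show_col_types = FALSE)$barcode
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              col_names = c("id", "name", "type"),
                              show_col_types = FALSE)
  meta_path <- file.path(dir, "cell_meta.tsv")
  cell_meta <- if (file.exists(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE)
  }
  expression_matrix(counts, cell_meta = cell_meta,
                    cell_ids = barcodes, gene_ids = features$id)
}

#' Write bulk TPM profiles as CSV
#'
#' First column `gene`, one column per type.
#'
#' @param bulk a [bulk_profile_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bulk_profiles <- function(bulk, path) {
  stopifnot(inherits(bulk, "bulk_profile_set"))
  tab <- tibble::as_tibble(t(bulk$tpm), rownames = "gene")
  readr::write_csv(tab, path)
  invisible(path)
}

#' Read bulk TPM profiles from CSV
#'
#' @param path CSV with a `gene` column and one numeric column per type.
#' @return A [bulk_profile_set()].
#' @export
read_bulk_profiles <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  genes <- tab[[1]]
  m <- t(as.matrix(tab[-1]))
  colnames(m) <- genes
  bulk_profile_set(m)
}

#' Read gating rules from a TSV file
#'
#' Columns `gene`, `comparator`, `threshold` and optionally `space`.
#'
#' @param path TSV path.
#' @return Tibble of gating rules for [gate_cells()].
#' @export
read_gating_rules <- function(path) {
  rules <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene", "comparator", "threshold") %in% names(rules)))
  if (!"space" %in% names(rules)) rules$space <- "normalized"
  rules
}
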