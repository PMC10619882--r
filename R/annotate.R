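#' Bulk TPM profile container
#'
#' @param tpm numeric matrix, cell types in rows and genes in columns; every
#'   row must sum to one million (within 1e-6 relative).
#' @return Object of class `bulk_profile_set` with elements `types` and
#'   `tpm`.
#' @export
bulk_profile_set <- function(tpm) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM values must be non-negative", call. = FALSE)
  sums <- rowSums(tpm)
  if (any(abs(sums - 1e6) > 1e-6 * 1e6)) {
    stop("each TPM row must sum to 1,000,000", call. = FALSE)
  }
  if (is.null(rownames(tpm))) rownames(tpm) <- paste0("type", seq_len(nrow(tpm)))
  structure(list(types = rownames(tpm), tpm = tpm), class = "bulk_profile_set")
}

#' @export
print.bulk_profile_set <- function(x, ...) {
  cat(sprintf("<bulk_profile_set> %d types x %d genes\n",
              nrow(x$tpm), ncol(x$tpm)))
  cat("  types:", paste(utils::head(x$types, 8), collapse = ", "), "\n")
  invisible(x)
}

#' Parameters for pseudo-single-cell simulation
#'
#' @param n_cells number of pseudo-cells, default 900.
#' @param depth_mean,depth_sd mean and standard deviation of the per-cell
#'   read-depth normal distribution, typically taken from
#'   [estimate_depth_params()] on the reference single-cell dataset.
#' @param seed integer seed.
#' @return List of class `pseudo_cell_params`.
#' @export
pseudo_cell_params <- function(n_cells = 900L, depth_mean = 2000,
                               depth_sd = 500, seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (depth_mean <= 0) stop("depth_mean must be positive", call. = FALSE)
  if (depth_sd < 0) stop("depth_sd must be non-negative", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), depth_mean = depth_mean,
                 depth_sd = depth_sd, seed = as.integer(seed)),
            class = "pseudo_cell_params")
}

#' Depth distribution of a reference dataset
#'
#' Mean and sample standard deviation of per-cell total raw counts, used to
#' match pseudo-cell depths to the reference single-cell experiment.
#'
#' @param matrix an [expression_matrix()] with at least 2 cells.
#' @return Named list with `depth_mean` and `depth_sd`.
#' @export
estimate_depth_params <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  totals <- Matrix::rowSums(matrix$counts)
  if (length(totals) < 2) stop("need >= 2 cells", call. = FALSE)
  list(depth_mean = mean(totals), depth_sd = stats::sd(totals))
}

#' Simulate pseudo-single cells from a bulk TPM vector
#'
#' Converts a deep bulk transcriptome into many shallow synthetic cells:
#' each pseudo-cell's depth is drawn from `Normal(depth_mean, depth_sd)`,
#' rounded to the nearest integer and truncated to >= 1, and its reads are
#' allocated multinomially with per-gene probability `TPM_g / sum(TPM)`.
#'
#' @param bulk_row named numeric TPM vector (names are gene ids).
#' @param params a [pseudo_cell_params()].
#' @return An [expression_matrix()] with `params$n_cells` cells.
#' @export
#' @examples
#' tpm <- c(a = 750000, b = 250000)
#' pc <- simulate_pseudo_cells(tpm, pseudo_cell_params(n_cells = 10,
#'                             depth_mean = 100, depth_sd = 0, seed = 2))
#' dim(pc)
simulate_pseudo_cells <- function(bulk_row, params = pseudo_cell_params()) {
  if (sum(bulk_row) <= 0) stop("TPM vector is all zero", call. = FALSE)
  if (any(bulk_row < 0)) stop("TPM values must be non-negative", call. = FALSE)
  p <- bulk_row / sum(bulk_row)
  counts <- withr::with_seed(params$seed, {
    depth <- pmax(1, round(stats::rnorm(params$n_cells, params$depth_mean,
                                        params$depth_sd)))
    t(vapply(depth, function(d) stats::rmultinom(1, d, p)[, 1],
             integer(length(p))))
  })
  dimnames(counts) <- list(sprintf("pseudo%04d", seq_len(params$n_cells)),
                           names(bulk_row))
  expression_matrix(counts)
}

#' Match bulk cell types to single-cell clusters by Pearson correlation
#'
#' For each bulk type: simulate pseudo-cells from its TPM vector, log-
#' normalize them with the same scale factor as the reference, average each
#' gene over pseudo-cells, and correlate that average with the per-cluster
#' average expression of the reference over shared genes. The best-matching
#' cluster per type is the one with the highest Pearson r (ties broken
#' toward the larger cluster, then lexically).
#'
#' @param bulk a [bulk_profile_set()].
#' @param params a [pseudo_cell_params()]; each type uses seed
#'   `params$seed + type index - 1`.
#' @param norm the reference [normalized_matrix()].
#' @param labels cluster labels for the reference cells (tibble `cell_id`,
#'   `cluster`, or named vector).
#' @return Object of class `correlation_assignment`: list with `matrix`
#'   (types x clusters Pearson r), `best_match` tibble (`type`, `cluster`,
#'   `r`, `runner_up`, `runner_up_r`) and `n_shared_genes`. Zero-variance
#'   average vectors give `NA` correlations (with a warning), never a silent
#'   zero.
#' @export
match_bulk_to_clusters <- function(bulk, params, norm, labels) {
  stopifnot(inherits(bulk, "bulk_profile_set"),
            inherits(norm, "normalized_matrix"))
  labels <- as_label_tibble(labels)
  shared <- intersect(colnames(bulk$tpm), colnames(norm$values))
  if (length(shared) < 2) stop("fewer than 2 shared genes", call. = FALSE)

  idx <- match(labels$cell_id, rownames(norm$values))
  if (anyNA(idx)) stop("labels reference unknown cells", call. = FALSE)
  clusters <- sort(unique(labels$cluster))
  cluster_sizes <- table(labels$cluster)
  cluster_avg <- vapply(clusters, function(cl) {
    rows <- idx[labels$cluster == cl]
    Matrix::colMeans(norm$values[rows, shared, drop = FALSE])
  }, numeric(length(shared)))

  r_mat <- matrix(NA_real_, nrow(bulk$tpm), length(clusters),
                  dimnames = list(bulk$types, clusters))
  for (i in seq_len(nrow(bulk$tpm))) {
    pc_params <- params
    pc_params$seed <- params$seed + i - 1L
    pc <- simulate_pseudo_cells(bulk$tpm[i, ], pc_params)
    pc_norm <- lognormalize(pc, scale_factor = norm$scale_factor)
    avg <- Matrix::colMeans(pc_norm$values[, shared, drop = FALSE])
    if (stats::sd(avg) == 0) {
      warning("zero-variance pseudo-cell average for type ", bulk$types[i],
              "; correlations reported as NA")
      next
    }
    for (j in seq_along(clusters)) {
      if (stats::sd(cluster_avg[, j]) == 0) {
        warning("zero-variance average for cluster ", clusters[j],
                "; correlation reported as NA")
        r_mat[i, j] <- NA_real_
      } else {
        r_mat[i, j] <- stats::cor(avg, cluster_avg[, j])
      }
    }
  }

  best <- purrr::map_dfr(seq_len(nrow(r_mat)), function(i) {
    r_row <- r_mat[i, ]
    ord <- order(-r_row, -as.numeric(cluster_sizes[clusters]), clusters,
                 na.last = TRUE)
    tibble::tibble(type = bulk$types[i],
                   cluster = clusters[ord[1]], r = r_row[ord[1]],
                   runner_up = if (length(ord) > 1) clusters[ord[2]] else NA,
                   runner_up_r = if (length(ord) > 1) r_row[ord[2]] else NA_real_)
  })
  structure(list(matrix = r_mat, best_match = best,
                 n_shared_genes = length(shared)),
            class = "correlation_assignment")
}

#' @export
print.correlation_assignment <- function(x, ...) {
  cat(sprintf("<correlation_assignment> %d types x %d clusters over %d shared genes\n",
              nrow(x$matrix), ncol(x$matrix), x$n_shared_genes))
  print(x$best_match)
  invisible(x)
}

#' Per-cluster expression summary for dot plots
#'
#' For each cluster and gene: the fraction of cells with non-zero normalized
#' expression and the arithmetic mean of the normalized values — the two
#' statistics a dot plot encodes as size and colour.
#'
#' @param norm a [normalized_matrix()].
#' @param labels cluster labels (tibble `cell_id`, `cluster`, or named
#'   vector); every cluster must be non-empty.
#' @param genes character vector of genes to summarize.
#' @return Tibble of class `dotplot_stats` with columns `cluster`, `gene`,
#'   `pct_expressing`, `mean_expression`.
#' @export
marker_summary <- function(norm, labels, genes) {
  stopifnot(inherits(norm, "normalized_matrix"))
  labels <- as_label_tibble(labels)
  missing <- setdiff(genes, colnames(norm$values))
  if (length(missing) > 0) {
    stop("unknown genes: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(labels$cell_id, rownames(norm$values))
  if (anyNA(idx)) stop("labels reference unknown cells", call. = FALSE)
  out <- purrr::map_dfr(sort(unique(labels$cluster)), function(cl) {
    rows <- idx[labels$cluster == cl]
    if (length(rows) == 0) stop("empty cluster: ", cl, call. = FALSE)
    sub <- norm$values[rows, genes, drop = FALSE]
    tibble::tibble(cluster = cl, gene = genes,
                   pct_expressing = unname(Matrix::colMeans(sub > 0)),
                   mean_expression = unname(Matrix::colMeans(sub)))
  })
  class(out) <- c("dotplot_stats", class(out))
  out
}

#' Hierarchical tree over cluster average expression
#'
#' Agglomerates cluster-average expression vectors with Euclidean distance
#' and (by default) complete linkage, the tree used to relate clusters such
#' as midline glia vs neurons vs repo-positive glia.
#'
#' @param norm a [normalized_matrix()].
#' @param labels cluster labels covering >= 2 clusters.
#' @param method linkage method passed to [stats::hclust()], default
#'   `"complete"`.
#' @return An [stats::hclust] object whose labels are the cluster ids.
#' @export
cluster_dendrogram <- function(norm, labels, method = "complete") {
  stopifnot(inherits(norm, "normalized_matrix"))
  labels <- as_label_tibble(labels)
  clusters <- sort(unique(labels$cluster))
  if (length(clusters) < 2) stop("need >= 2 clusters", call. = FALSE)
  idx <- match(labels$cell_id, rownames(norm$values))
  avg <- vapply(clusters, function(cl) {
    Matrix::colMeans(norm$values[idx[labels$cluster == cl], , drop = FALSE])
  }, numeric(ncol(norm$values)))
  avg <- matrix(avg, nrow = ncol(norm$values))  # genes x clusters, even 1-gene
  avg <- t(avg)
  rownames(avg) <- clusters
  stats::hclust(stats::dist(avg), method = method)
}

#' Write a dendrogram as Newick
#'
#' @param tree an [stats::hclust] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
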