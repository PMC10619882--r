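#' Cluster cells on a k-nearest-neighbour graph
#'
#' Scales the selected genes (per-gene z-score, capped at +/- 10), computes
#' principal components, builds an undirected k-nearest-neighbour graph in PC
#' space (Euclidean distance) and partitions it with multilevel modularity
#' community detection at the given resolution. Labels are `"0"`, `"1"`, ...
#' ordered by decreasing cluster size.
#'
#' @param norm a [normalized_matrix()] with >= 2 cells.
#' @param hvgs character vector of genes to use (e.g. from [select_hvgs()]).
#' @param n_pcs number of principal components; must be smaller than both
#'   the cell and gene counts.
#' @param resolution modularity resolution parameter, default 0.5.
#' @param k neighbours per cell, default 20 (reduced automatically for tiny
#'   inputs).
#' @param seed integer seed (community detection is stochastic).
#' @return Tibble with `cell_id` and `cluster`.
#' @export
cluster_cells <- function(norm, hvgs, n_pcs = 10L, resolution = 0.5,
                          k = 20L, seed = 1L) {
  stopifnot(inherits(norm, "normalized_matrix"))
  n_cells <- nrow(norm$values)
  if (n_cells < 2) stop("need >= 2 cells", call. = FALSE)
  missing <- setdiff(hvgs, colnames(norm$values))
  if (length(missing) > 0) {
    stop("unknown genes: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  if (n_pcs >= min(n_cells, length(hvgs))) {
    stop("n_pcs must be smaller than both the number of cells and of genes",
         call. = FALSE)
  }
  x <- as.matrix(norm$values[, hvgs, drop = FALSE])
  x <- scale(x)
  x[is.na(x)] <- 0            # constant genes scale to NaN
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x[x > 10] <- 10; x[x < -10] <- -10
  pcs <- stats::prcomp(x, center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x

  k <- min(k, n_cells - 1L)
  d <- as.matrix(stats::dist(pcs))
  edges <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    nn <- order(d[i, ])[2:(k + 1L)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  member <- igraph::membership(comm)
  # relabel by decreasing size, 0-based
  sizes <- sort(table(member), decreasing = TRUE)
  relabel <- stats::setNames(as.character(seq_along(sizes) - 1L), names(sizes))
  tibble::tibble(cell_id = rownames(norm$values),
                 cluster = unname(relabel[as.character(member)]))
}

#' Differential expression between two cell groups
#'
#' Wilcoxon rank-sum test on log-normalized values for every gene expressed
#' in at least `min_pct` of either group. The fold change is computed on
#' back-transformed means with a pseudo-count of 1:
#' `log2FC = log2((mean(exp(x_a) - 1) + 1) / (mean(exp(x_b) - 1) + 1))`.
#' P-values are Benjamini-Hochberg adjusted over the tested genes.
#'
#' @param norm a [normalized_matrix()].
#' @param group_a,group_b disjoint, non-empty character vectors of cell ids.
#' @param min_pct minimum expressing fraction in either group, default 0.1.
#' @return Tibble with `gene`, `log2_fold_change`, `p_value`, `adj_p`,
#'   `pct_a`, `pct_b`, ordered by `adj_p` then gene.
#' @export
differential_expression <- function(norm, group_a, group_b, min_pct = 0.1) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap", call. = FALSE)
  }
  ia <- match(group_a, rownames(norm$values))
  ib <- match(group_b, rownames(norm$values))
  if (anyNA(ia) || anyNA(ib)) stop("unknown cells in groups", call. = FALSE)
  va <- norm$values[ia, , drop = FALSE]
  vb <- norm$values[ib, , drop = FALSE]
  pct_a <- Matrix::colMeans(va > 0)
  pct_b <- Matrix::colMeans(vb > 0)
  test <- which(pct_a >= min_pct | pct_b >= min_pct)
  if (length(test) == 0) {
    return(tibble::tibble(gene = character(), log2_fold_change = numeric(),
                          p_value = numeric(), adj_p = numeric(),
                          pct_a = numeric(), pct_b = numeric()))
  }
  genes <- colnames(norm$values)[test]
  lfc <- log2((Matrix::colMeans(expm1(va[, test, drop = FALSE])) + 1) /
              (Matrix::colMeans(expm1(vb[, test, drop = FALSE])) + 1))
  p <- vapply(test, function(j) {
    xa <- as.numeric(va[, j]); xb <- as.numeric(vb[, j])
    if (all(c(xa, xb) == c(xa, xb)[1])) return(1)   # all tied: no evidence
    suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE,
                                        correct = FALSE)$p.value)
  }, numeric(1))
  out <- tibble::tibble(gene = genes, log2_fold_change = as.numeric(lfc),
                        p_value = p, adj_p = stats::p.adjust(p, "BH"),
                        pct_a = pct_a[test], pct_b = pct_b[test])
  dplyr::arrange(out, .data$adj_p, .data$gene)
}

#' Over-clustering split criterion
#'
#' A subdivision is trusted only when enough genes separate the candidate
#' subclusters strongly: at least `split_min_genes` genes at
#' `fold_threshold`-fold change or higher supports a split, while
#' `artifact_max_genes` or fewer marks the subdivision as an over-clustering
#' artifact. Counts between the two bounds are indeterminate and never
#' auto-split.
#'
#' @param fold_threshold minimum fold change, default 4 (|log2FC| >= 2).
#' @param split_min_genes minimum DEG count for a split, default 21
#'   ("greater than 20").
#' @param artifact_max_genes maximum DEG count for an artifact verdict,
#'   default 14 ("fewer than 15").
#' @param sig_max_adj_p BH-adjusted p gate applied when counting DEGs,
#'   default 0.05; set to `NULL` to count on fold change alone.
#' @return List of class `split_criterion`.
#' @export
split_criterion <- function(fold_threshold = 4, split_min_genes = 21L,
                            artifact_max_genes = 14L, sig_max_adj_p = 0.05) {
  if (artifact_max_genes >= split_min_genes) {
    stop("artifact_max_genes must be < split_min_genes", call. = FALSE)
  }
  if (fold_threshold <= 0) stop("fold_threshold must be positive", call. = FALSE)
  structure(list(fold_threshold = fold_threshold,
                 split_min_genes = as.integer(split_min_genes),
                 artifact_max_genes = as.integer(artifact_max_genes),
                 sig_max_adj_p = sig_max_adj_p),
            class = "split_criterion")
}

# maps a DEG count to a verdict; counts in the gap between the two bounds
# are indeterminate and never auto-split
verdict_from_count <- function(n_deg, criterion) {
  if (n_deg >= criterion$split_min_genes) "split"
  else if (n_deg <= criterion$artifact_max_genes) "artifact"
  else "indeterminate"
}

#' Test a cluster for genuine heterogeneity
#'
#' Re-clusters the cluster's cells in isolation at `sub_resolution`, then
#' counts genes differentially expressed between the two largest subclusters
#' at `criterion$fold_threshold`-fold or higher (and BH-adjusted p below
#' `criterion$sig_max_adj_p` when set). The verdict follows
#' [split_criterion()]. If only one subcluster is found the verdict is
#' `artifact` with zero DEGs.
#'
#' @param norm a [normalized_matrix()] covering at least the cluster's cells.
#' @param labels cluster labels.
#' @param cluster_id the cluster to examine (>= 4 cells).
#' @param sub_resolution resolution for the isolated re-clustering.
#' @param criterion a [split_criterion()].
#' @param n_pcs,k passed to [cluster_cells()].
#' @param n_hvgs genes used for the sub-clustering, default 2000 (capped at
#'   the gene count).
#' @param seed integer seed.
#' @return Object of class `split_decision`: list with `cluster_id`, `n_deg`,
#'   `verdict` (`"split"`, `"artifact"` or `"indeterminate"`),
#'   `subassignments` (tibble `cell_id`, `subcluster`) and `de` (the DE
#'   table between the two largest subclusters).
#' @export
overclustering_check <- function(norm, labels, cluster_id,
                                 sub_resolution = 0.5,
                                 criterion = split_criterion(),
                                 n_pcs = 10L, k = 20L, n_hvgs = 2000L,
                                 seed = 1L) {
  stopifnot(inherits(norm, "normalized_matrix"),
            inherits(criterion, "split_criterion"))
  labels <- as_label_tibble(labels)
  cells <- labels$cell_id[labels$cluster == cluster_id]
  if (length(cells) < 4) stop("cluster must have >= 4 cells", call. = FALSE)
  sub <- normalized_matrix(norm$values[cells, , drop = FALSE],
                           norm$scale_factor)
  hvgs <- select_hvgs(sub, min(n_hvgs, ncol(sub$values)))
  n_pcs <- min(n_pcs, length(cells) - 1L, length(hvgs) - 1L)
  sublabels <- cluster_cells(sub, hvgs, n_pcs = n_pcs,
                             resolution = sub_resolution, k = k, seed = seed)
  names(sublabels)[2] <- "subcluster"

  sizes <- sort(table(sublabels$subcluster), decreasing = TRUE)
  if (length(sizes) < 2) {
    return(structure(list(cluster_id = cluster_id, n_deg = 0L,
                          verdict = "artifact", subassignments = sublabels,
                          de = NULL, criterion = criterion),
                     class = "split_decision"))
  }
  top2 <- names(sizes)[1:2]
  de <- differential_expression(
    sub,
    sublabels$cell_id[sublabels$subcluster == top2[1]],
    sublabels$cell_id[sublabels$subcluster == top2[2]])
  hit <- abs(de$log2_fold_change) >= log2(criterion$fold_threshold)
  if (!is.null(criterion$sig_max_adj_p)) {
    hit <- hit & de$adj_p < criterion$sig_max_adj_p
  }
  n_deg <- sum(hit)
  verdict <- verdict_from_count(n_deg, criterion)
  structure(list(cluster_id = cluster_id, n_deg = as.integer(n_deg),
                 verdict = verdict, subassignments = sublabels, de = de,
                 criterion = criterion),
            class = "split_decision")
}

#' @export
print.split_decision <- function(x, ...) {
  cat(sprintf("<split_decision> cluster %s: %d genes >= %g-fold => %s\n",
              x$cluster_id, x$n_deg, x$criterion$fold_threshold, x$verdict))
  invisible(x)
}

#' Split a cluster according to subcluster assignments
#'
#' The largest subcluster keeps the original cluster id; every other
#' subcluster (in decreasing size order) receives a fresh id, counting up
#' from one past the largest numeric id already in use. Total cell count is
#' unchanged.
#'
#' @param labels cluster labels (tibble `cell_id`, `cluster`, or named
#'   vector).
#' @param cluster_id the cluster being split.
#' @param subassignments tibble with `cell_id` and `subcluster` covering
#'   exactly the cluster's cells (e.g. from [overclustering_check()]).
#' @return Tibble with `cell_id` and `cluster`, plus a `"split_map"`
#'   attribute recording subcluster -> new id, which makes the operation
#'   invertible.
#' @export
split_cluster <- function(labels, cluster_id, subassignments) {
  labels <- as_label_tibble(labels)
  sub <- tibble::as_tibble(subassignments)
  stopifnot(all(c("cell_id", "subcluster") %in% names(sub)))
  members <- labels$cell_id[labels$cluster == cluster_id]
  if (!setequal(sub$cell_id, members) || nrow(sub) != length(members)) {
    stop("subassignments must cover exactly the cells of cluster ",
         cluster_id, call. = FALSE)
  }
  sizes <- sort(table(sub$subcluster), decreasing = TRUE)
  numeric_ids <- suppressWarnings(as.numeric(unique(labels$cluster)))
  next_id <- if (all(!is.na(numeric_ids))) max(numeric_ids) + 1 else NA
  new_ids <- stats::setNames(character(length(sizes)), names(sizes))
  new_ids[1] <- as.character(cluster_id)
  for (i in seq_along(sizes)[-1]) {
    new_ids[i] <- if (!is.na(next_id)) {
      id <- as.character(next_id); next_id <- next_id + 1; id
    } else paste0(cluster_id, "_", i - 1)
  }
  out <- labels
  m <- match(out$cell_id, sub$cell_id)
  hit <- !is.na(m)
  out$cluster[hit] <- unname(new_ids[sub$subcluster[m[hit]]])
  attr(out, "split_map") <- tibble::tibble(subcluster = names(new_ids),
                                           new_cluster = unname(new_ids))
  out
}
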