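#' Quality-control thresholds
#'
#' Boundary semantics follow the wording the thresholds were defined with:
#' cells are retained when their mitochondrial fraction is strictly below
#' `mito_max`, and when their detected-gene count (genes with raw count > 0)
#' lies inside the inclusive band `[min_genes, max_genes]`.
#'
#' @param mito_max maximum mitochondrial read fraction (exclusive), default
#'   0.10.
#' @param min_genes,max_genes inclusive detected-gene band, defaults 50 and
#'   3000.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(mito_max = 0.10, min_genes = 50L, max_genes = 3000L) {
  if (mito_max < 0 || mito_max > 1) stop("mito_max must be in [0, 1]",
                                         call. = FALSE)
  if (min_genes < 0 || min_genes > max_genes) {
    stop("need 0 <= min_genes <= max_genes", call. = FALSE)
  }
  structure(list(mito_max = mito_max, min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes)), class = "qc_thresholds")
}

#' Filter cells on mitochondrial fraction and detected-gene count
#'
#' @param matrix an [expression_matrix()]; `gene_meta$is_mitochondrial` must
#'   flag at least one gene unless `mito_max = 1`.
#' @param thresholds a [qc_thresholds()].
#' @return List with `matrix` (the kept cells) and `report`, a tibble of
#'   removal counts per criterion (a cell failing both criteria is counted
#'   under each).
#' @export
#' @examples
#' sim <- simulate_atlas(sim_config(n_types = 2, cells_per_type = 40,
#'                                  n_genes = 120, seed = 3))
#' qc_filter(sim$matrix, qc_thresholds())$report
qc_filter <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (thresholds$mito_max < 1 && !any(matrix$gene_meta$is_mitochondrial)) {
    stop("no genes are flagged mitochondrial; cannot apply mito_max < 1",
         call. = FALSE)
  }
  meta <- matrix$cell_meta
  fail_mito <- meta$mito_fraction >= thresholds$mito_max
  fail_low <- meta$n_genes < thresholds$min_genes
  fail_high <- meta$n_genes > thresholds$max_genes
  keep <- !(fail_mito | fail_low | fail_high)
  report <- tibble::tibble(
    criterion = c("mito_fraction >= mito_max", "n_genes < min_genes",
                  "n_genes > max_genes", "total_removed"),
    n_removed = c(sum(fail_mito), sum(fail_low), sum(fail_high), sum(!keep)))
  list(matrix = subset_cells(matrix, cells = meta$cell_id[keep]),
       report = report)
}

#' Log-normalize raw counts
#'
#' Scales each cell's counts to its total, multiplies by the scale factor and
#' applies `log1p`: `value = ln(1 + count / total * scale_factor)`. Zero
#' counts stay exactly zero, so sparsity is preserved, and every kept cell
#' satisfies `sum(exp(value) - 1) == scale_factor`.
#'
#' @param matrix an [expression_matrix()] with all cell totals >= 1.
#' @param scale_factor positive scale factor, default 10,000.
#' @return A [normalized_matrix()].
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(1, 0, 3), nrow = 1,
#'                        dimnames = list("c1", c("a", "b", "c"))))
#' as.matrix(lognormalize(m)$values)  # ln(2501), 0, ln(7501)
lognormalize <- function(matrix, scale_factor = 1e4) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (scale_factor <= 0) stop("scale_factor must be positive", call. = FALSE)
  totals <- Matrix::rowSums(matrix$counts)
  if (any(totals == 0)) {
    stop("zero-total cells: ",
         paste(rownames(matrix$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  v <- Matrix::Diagonal(x = scale_factor / totals) %*% matrix$counts
  v <- methods::as(methods::as(v, "generalMatrix"), "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(matrix$counts)
  normalized_matrix(v, scale_factor, cell_meta = matrix$cell_meta)
}

#' Select highly variable genes
#'
#' Ranks genes by descending variance of their log-normalized values; ties
#' are broken by lexical gene id so the ordering is deterministic.
#'
#' @param norm a [normalized_matrix()].
#' @param n number of genes to return; if larger than the gene count, all
#'   genes are returned (still ordered).
#' @return Character vector of gene ids, most variable first.
#' @export
select_hvgs <- function(norm, n = 3000L) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  vars <- sparse_col_vars(norm$values)
  ids <- colnames(norm$values)
  ord <- order(-vars, ids)
  ids[ord][seq_len(min(n, length(ids)))]
}

#' A single marker-threshold gating rule
#'
#' @param gene gene id the rule tests.
#' @param comparator one of `"<="`, `"<"`, `">="`, `">"`, `"=="`.
#' @param threshold numeric threshold.
#' @param space `"normalized"` (default) or `"raw"`: which value space the
#'   rule is evaluated in.
#' @return One-row tibble usable directly or row-bound into a rule set for
#'   [gate_cells()].
#' @export
gating_rule <- function(gene, comparator, threshold, space = "normalized") {
  comparator <- match.arg(comparator, c("<=", "<", ">=", ">", "=="))
  space <- match.arg(space, c("normalized", "raw"))
  tibble::tibble(gene = gene, comparator = comparator,
                 threshold = threshold, space = space)
}

#' The neuronal + hemocyte clean-up rule set
#'
#' Convenience constructor for the contamination gate: the three pan-neuronal
#' markers at a normalized-expression threshold of 1 (inclusive) and the
#' hemocyte marker at 0, to be applied with `mode = "remove_if_any"` — cells
#' whose expression exceeds any threshold are removed.
#'
#' @param neuronal_genes character vector of neuronal marker gene ids.
#' @param hemocyte_gene hemocyte marker gene id (`NULL` to skip).
#' @param neuronal_threshold normalized-expression threshold, default 1.
#' @return Tibble of gating rules.
#' @export
cleanup_rules <- function(neuronal_genes, hemocyte_gene = "Hml-like",
                          neuronal_threshold = 1) {
  rules <- dplyr::bind_rows(lapply(neuronal_genes, gating_rule,
                                   comparator = "<=",
                                   threshold = neuronal_threshold))
  if (!is.null(hemocyte_gene)) {
    rules <- dplyr::bind_rows(rules, gating_rule(hemocyte_gene, "<=", 0))
  }
  rules
}

#' Gate cells on marker-expression rules
#'
#' In `remove_if_any` mode a cell is removed as soon as any rule's complement
#' holds (e.g. rule `Rdl <= 1` removes cells with `Rdl > 1`); in
#' `keep_if_all` mode a cell is kept only when every rule holds. The kept and
#' removed sets always form an exact partition of the input cells.
#'
#' @param norm a [normalized_matrix()]; rules with `space = "raw"` are
#'   evaluated on `raw$counts` instead.
#' @param rules tibble of rules from [gating_rule()]/[cleanup_rules()].
#' @param mode `"remove_if_any"` or `"keep_if_all"`.
#' @param raw optional [expression_matrix()] supplying raw-space values.
#' @return List with `kept` and `removed` (character cell ids) and `report`
#'   (tibble: per-rule number of cells failing that rule).
#' @export
gate_cells <- function(norm, rules, mode = c("remove_if_any", "keep_if_all"),
                       raw = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  mode <- match.arg(mode)
  rules <- tibble::as_tibble(rules)
  if (!"space" %in% names(rules)) rules$space <- "normalized"
  missing <- setdiff(rules$gene[rules$space == "normalized"],
                     colnames(norm$values))
  if (!is.null(raw)) {
    missing <- c(missing, setdiff(rules$gene[rules$space == "raw"],
                                  colnames(raw$counts)))
  } else if (any(rules$space == "raw")) {
    stop("rules in raw space require the 'raw' matrix", call. = FALSE)
  }
  if (length(missing) > 0) {
    stop("unknown genes in gating rules: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  cells <- rownames(norm$values)
  holds <- vapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    v <- if (r$space == "raw") as.numeric(raw$counts[, r$gene]) else
      as.numeric(norm$values[, r$gene])
    switch(r$comparator,
           "<=" = v <= r$threshold, "<" = v < r$threshold,
           ">=" = v >= r$threshold, ">" = v > r$threshold,
           "==" = v == r$threshold)
  }, logical(length(cells)))
  holds <- matrix(holds, nrow = length(cells))
  all_hold <- rowSums(holds) == nrow(rules)
  keep <- if (mode == "remove_if_any") all_hold else all_hold
  # both modes keep exactly the cells satisfying every rule; they differ in
  # how rule sets are phrased by the caller (removal vs positive selection)
  report <- tibble::tibble(
    gene = rules$gene, comparator = rules$comparator,
    threshold = rules$threshold,
    n_failing = colSums(!holds))
  list(kept = cells[keep], removed = cells[!keep], report = report)
}

#' Drop clusters dominated by a single batch
#'
#' Removes every cluster to which the designated minority batch contributes
#' strictly fewer than `min_frac` of the cluster's cells — such clusters are
#' likely batch artifacts rather than shared cell types.
#'
#' @param labels cluster labels: tibble with `cell_id` and `cluster`, or a
#'   named vector.
#' @param batch per-cell batch labels: tibble with `cell_id` and `batch`, or
#'   a named vector aligned with `labels`.
#' @param minority_batch name of the designated minority batch.
#' @param min_frac strict lower bound on the minority contribution, default
#'   0.01.
#' @return List with `dropped` (character cluster ids) and `report` (tibble:
#'   cluster, size, minority cells, fraction, dropped flag).
#' @export
#' @examples
#' labels <- tibble::tibble(cell_id = paste0("c", 1:400),
#'                          cluster = rep(c("0", "1"), each = 200))
#' batch <- tibble::tibble(cell_id = labels$cell_id,
#'                         batch = c("B", rep("A", 199),
#'                                   rep("B", 2), rep("A", 198)))
#' batch_contribution_filter(labels, batch, "B")$dropped  # "0" (0.5% < 1%)
batch_contribution_filter <- function(labels, batch, minority_batch,
                                      min_frac = 0.01) {
  labels <- as_label_tibble(labels)
  if (inherits(batch, "data.frame")) {
    batch <- tibble::as_tibble(batch)
    stopifnot(all(c("cell_id", "batch") %in% names(batch)))
  } else {
    batch <- tibble::tibble(cell_id = names(batch), batch = unname(batch))
  }
  joined <- dplyr::inner_join(labels, batch, by = "cell_id")
  if (nrow(joined) != nrow(labels)) {
    stop("labels and batch tables do not cover the same cells", call. = FALSE)
  }
  if (!minority_batch %in% joined$batch) {
    stop("unknown designated batch: ", minority_batch, call. = FALSE)
  }
  report <- joined |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(size = dplyr::n(),
                     n_minority = sum(.data$batch == minority_batch),
                     .groups = "drop") |>
    dplyr::mutate(minority_frac = .data$n_minority / .data$size,
                  dropped = .data$minority_frac < min_frac) |>
    dplyr::arrange(.data$cluster)
  list(dropped = report$cluster[report$dropped], report = report)
}
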