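#' Gene-set collection with universe
#'
#' @param sets named list of character vectors (term id -> annotated genes).
#' @param universe character vector of all testable genes; every annotated
#'   gene must be in it.
#' @param term_names optional named character vector of human-readable term
#'   names.
#' @return Object of class `term_collection`.
#' @export
term_collection <- function(sets, universe, term_names = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- unique(universe)
  sets <- lapply(sets, unique)
  stray <- setdiff(unique(unlist(sets)), universe)
  if (length(stray) > 0) {
    stop("annotated genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(sets), names(sets))
  }
  structure(list(sets = sets, universe = universe,
                 term_names = term_names[names(sets)]),
            class = "term_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one term per line, tab-separated as
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a GMT file.
#' @param universe optional universe; defaults to the union of all annotated
#'   genes.
#' @return A [term_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  descs <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "",
                  character(1))
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  if (is.null(universe)) universe <- unique(unlist(sets))
  term_collection(sets, universe, stats::setNames(descs, ids))
}

#' Hypergeometric over-representation test
#'
#' For each term, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap: `P(X >= k)` with `K` annotated genes among
#' `N` universe genes and `n` selected genes. P-values are BH-adjusted over
#' all tested terms; only terms passing `min_adj_p` are returned, sorted by
#' adjusted p.
#'
#' @param selected character vector of selected genes; must be a subset of
#'   the universe.
#' @param terms a [term_collection()].
#' @param min_adj_p adjusted-p cutoff on the returned rows, default 0.05;
#'   pass a value above 1 to keep every tested term.
#' @return Tibble with `term`, `name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `adj_p`.
#' @export
#' @examples
#' tc <- term_collection(list(t1 = c("a", "b", "c")), letters[1:10])
#' hypergeom_enrich(c("a", "b", "c"), tc)  # p = 1/choose(10, 3)
hypergeom_enrich <- function(selected, terms, min_adj_p = 0.05) {
  stopifnot(inherits(terms, "term_collection"))
  selected <- unique(selected)
  stray <- setdiff(selected, terms$universe)
  if (length(stray) > 0) {
    stop("selected genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(terms$universe)
  n <- length(selected)
  rows <- purrr::imap_dfr(terms$sets, function(genes, id) {
    K <- length(genes)
    k <- length(intersect(selected, genes))
    tibble::tibble(term = id, name = unname(terms$term_names[id]),
                   k = k, K = K, n = n, N = N,
                   p_value = stats::phyper(k - 1, K, N - K, n,
                                           lower.tail = FALSE))
  })
  rows$adj_p <- stats::p.adjust(rows$p_value, "BH")
  rows <- dplyr::filter(rows, .data$adj_p < min_adj_p)
  dplyr::arrange(rows, .data$adj_p, .data$term)
}

#' Jaccard similarity of two gene sets
#' @param a,b character vectors.
#' @return Overlap / union size; 0 when both sets are empty.
#' @export
jaccard_similarity <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Parameters for enrichment redundancy reduction and grouping
#'
#' @param similarity_cutoff pairwise similarity above which (strictly) the
#'   less significant of two terms is removed, default 0.7.
#' @param top_n number of terms kept for grouping, default 20.
#' @return List of class `simplify_params`.
#' @export
simplify_params <- function(similarity_cutoff = 0.7, top_n = 20L) {
  if (similarity_cutoff < 0 || similarity_cutoff > 1) {
    stop("similarity_cutoff must be in [0, 1]", call. = FALSE)
  }
  structure(list(similarity_cutoff = similarity_cutoff,
                 top_n = as.integer(top_n)), class = "simplify_params")
}

#' Remove redundant enriched terms
#'
#' Greedy pass over the rows in ascending adjusted-p order (ties broken by
#' term id): a term is kept only if its similarity to every previously kept
#' term is at or below the cutoff (strictly greater similarity removes it).
#' The output is always a subset of the input and the operation is
#' idempotent.
#'
#' @param rows enrichment tibble from [hypergeom_enrich()].
#' @param terms the [term_collection()] the rows refer to.
#' @param params a [simplify_params()].
#' @param similarity a function of two gene-set character vectors returning a
#'   similarity in `[0, 1]`; defaults to [jaccard_similarity()].
#' @return The retained rows, same columns, ascending `adj_p`.
#' @export
simplify_terms <- function(rows, terms, params = simplify_params(),
                           similarity = jaccard_similarity) {
  stopifnot(inherits(terms, "term_collection"))
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0) return(rows)
  unknown <- setdiff(rows$term, names(terms$sets))
  if (length(unknown) > 0) {
    stop("rows reference unknown terms: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- dplyr::arrange(rows, .data$adj_p, .data$term)
  kept <- integer(0)
  for (i in seq_len(nrow(rows))) {
    sims <- vapply(kept, function(j) {
      similarity(terms$sets[[rows$term[i]]], terms$sets[[rows$term[j]]])
    }, numeric(1))
    if (all(sims <= params$similarity_cutoff)) kept <- c(kept, i)
  }
  rows[kept, , drop = FALSE]
}

#' Group enriched terms by similarity
#'
#' Keeps the `top_n` most significant rows, computes pairwise distances
#' `1 - similarity` and agglomerates with Ward's method (`ward.D`). The
#' resulting tree orders the heat-table, whose value column is
#' `-log10(adj_p)` (the FDR scale enrichment heatmaps are drawn on).
#'
#' @inheritParams simplify_terms
#' @return Object of class `term_grouping`: list with `tree` (an
#'   [stats::hclust], `NULL` when fewer than 2 rows), and `table` (tibble
#'   `term`, `name`, `adj_p`, `neg_log10_fdr`, ordered by the tree).
#' @export
group_terms <- function(rows, terms, params = simplify_params(),
                        similarity = jaccard_similarity) {
  stopifnot(inherits(terms, "term_collection"))
  rows <- dplyr::arrange(tibble::as_tibble(rows), .data$adj_p, .data$term)
  rows <- utils::head(rows, params$top_n)
  if (nrow(rows) == 0) {
    return(structure(list(tree = NULL, table = rows), class = "term_grouping"))
  }
  if (nrow(rows) == 1) {
    tab <- dplyr::mutate(rows, neg_log10_fdr = -log10(.data$adj_p))
    return(structure(list(tree = NULL, table = tab), class = "term_grouping"))
  }
  m <- length(rows$term)
  d <- matrix(0, m, m, dimnames = list(rows$term, rows$term))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      s <- similarity(terms$sets[[rows$term[i]]], terms$sets[[rows$term[j]]])
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  tree <- stats::hclust(stats::as.dist(d), method = "ward.D")
  tab <- rows[tree$order, , drop = FALSE]
  tab$neg_log10_fdr <- -log10(tab$adj_p)
  structure(list(tree = tree, table = tab), class = "term_grouping")
}

#' @export
print.term_grouping <- function(x, ...) {
  cat(sprintf("<term_grouping> %d terms%s\n", nrow(x$table),
              if (is.null(x$tree)) "" else " with Ward tree"))
  print(x$table)
  invisible(x)
}
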