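#' Tidy a correlation assignment into long format
#'
#' @param x a `correlation_assignment` from [match_bulk_to_clusters()].
#' @param ... unused.
#' @return Tibble with one row per (type, cluster): `type`, `cluster`, `r`,
#'   `is_best_match`.
#' @export
tidy.correlation_assignment <- function(x, ...) {
  long <- tibble::as_tibble(x$matrix, rownames = "type") |>
    tidyr::pivot_longer(-"type", names_to = "cluster", values_to = "r")
  best <- dplyr::select(x$best_match, "type", best = "cluster")
  dplyr::left_join(long, best, by = "type") |>
    dplyr::mutate(is_best_match = .data$cluster == .data$best) |>
    dplyr::select(-"best")
}

#' @rdname tidy.correlation_assignment
#' @export
glance.correlation_assignment <- function(x, ...) {
  tibble::tibble(n_types = nrow(x$matrix), n_clusters = ncol(x$matrix),
                 n_shared_genes = x$n_shared_genes,
                 mean_best_r = mean(x$best_match$r, na.rm = TRUE))
}

#' Tidy a split decision
#'
#' @param x a `split_decision` from [overclustering_check()].
#' @param ... unused.
#' @return `tidy()`: the DE table between the two largest subclusters (empty
#'   tibble when only one subcluster was found); `glance()`: one row with
#'   `cluster_id`, `n_deg`, `verdict`, `n_subclusters`.
#' @export
tidy.split_decision <- function(x, ...) {
  x$de %||% tibble::tibble(gene = character(), log2_fold_change = numeric(),
                           p_value = numeric(), adj_p = numeric(),
                           pct_a = numeric(), pct_b = numeric())
}

#' @rdname tidy.split_decision
#' @export
glance.split_decision <- function(x, ...) {
  tibble::tibble(cluster_id = as.character(x$cluster_id), n_deg = x$n_deg,
                 verdict = x$verdict,
                 n_subclusters = length(unique(x$subassignments$subcluster)))
}

#' Tidy HCR positivity scores
#'
#' @param x an `hcr_positivity` from [score_hcr_positivity()].
#' @param ... unused.
#' @return `tidy()`: the per-nucleus score tibble; `glance()`: the
#'   per-region + overall summary.
#' @export
tidy.hcr_positivity <- function(x, ...) x$scores

#' @rdname tidy.hcr_positivity
#' @export
glance.hcr_positivity <- function(x, ...) x$summary

#' Tidy clone statistics
#'
#' @param x a `clone_stats` from [clone_proportion_stats()].
#' @param ... unused.
#' @return `tidy()`: the proportions tibble; `glance()`: the test result
#'   tibble (empty when no test was requested).
#' @export
tidy.clone_stats <- function(x, ...) {
  x$proportions %||% tibble::tibble(category = character(), count = numeric(),
                                    percent = numeric())
}

#' @rdname tidy.clone_stats
#' @export
glance.clone_stats <- function(x, ...) {
  x$test %||% tibble::tibble(method = character(), statistic = numeric(),
                             p_value = numeric())
}
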