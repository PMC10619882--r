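# Small in-code fixtures shared across test files.

# expression_matrix from a dense integer matrix with auto ids
em <- function(counts, ...) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  }
  expression_matrix(counts, ...)
}

# normalized_matrix directly from a matrix of values (for gating tests that
# construct normalized values by hand)
nm <- function(values, scale_factor = 1e4) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("c%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("g%03d", seq_len(ncol(values)))
  }
  normalized_matrix(values, scale_factor)
}

# a small simulated atlas reused by several files
small_atlas <- function(seed = 7, ...) {
  simulate_atlas(sim_config(n_types = 2, cells_per_type = 50, n_genes = 100,
                            seed = seed, ...))
}

truth_labels <- function(truth) {
  tibble::tibble(cell_id = truth$cell_id,
                 cluster = as.character(truth$true_type))
}

# do two partitions agree exactly (up to label names)?
partitions_identical <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# independent upper-tail hypergeometric oracle: enumerate all draws
hyper_upper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K universe elements are "in the term"
  mean(hits >= k)
}

# independent two-sided Fisher oracle for a 2x2 table: enumerate all tables
# with the observed margins, sum probabilities <= observed probability
fisher_two_sided_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# step-up BH oracle
bh_adjust_enum <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  cummin_val <- 1
  for (i in seq_along(ord)) {
    rank_i <- m - i + 1
    cummin_val <- min(cummin_val, p[ord[i]] * m / rank_i)
    adj[ord[i]] <- cummin_val
  }
  adj
}
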