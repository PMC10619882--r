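test_that("depth parameters are the mean and sample SD of totals", {
  flat <- em(matrix(rep(50L, 6), nrow = 3))  # totals 100 each
  expect_equal(estimate_depth_params(flat),
               list(depth_mean = 100, depth_sd = 0))
  two <- em(matrix(c(50L, 50L, 150L, 150L), nrow = 2, byrow = TRUE))
  dp <- estimate_depth_params(two)
  expect_equal(dp$depth_mean, 200)
  expect_equal(dp$depth_sd, sqrt(2) * 100, tolerance = 1e-12)
  one <- em(matrix(1L, 1, 2))
  expect_error(estimate_depth_params(one), ">= 2 cells")
})

test_that("pseudo-cells honour count, depth and one-hot allocation", {
  tpm <- c(a = 5e5, b = 5e5)
  pc <- simulate_pseudo_cells(tpm, pseudo_cell_params(depth_mean = 2000,
                                                      depth_sd = 500,
                                                      seed = 1))
  expect_equal(nrow(pc$counts), 900)  # default n_cells

  onehot <- simulate_pseudo_cells(c(only = 1e6, other = 0),
                                  pseudo_cell_params(n_cells = 50,
                                                     depth_mean = 100,
                                                     depth_sd = 10, seed = 2))
  expect_true(all(onehot$counts[, "other"] == 0))
  expect_true(all(onehot$counts[, "only"] ==
                    Matrix::rowSums(onehot$counts)))

  # fixed depth: every pseudo-cell total equals the drawn depth
  fixed <- simulate_pseudo_cells(tpm, pseudo_cell_params(n_cells = 30,
                                                         depth_mean = 500,
                                                         depth_sd = 0,
                                                         seed = 3))
  expect_equal(unname(Matrix::rowSums(fixed$counts)), rep(500, 30))

  expect_error(simulate_pseudo_cells(c(a = 0, b = 0)), "all zero")
})

test_that("pooled allocation stays within binomial sampling error", {
  params <- pseudo_cell_params(n_cells = 900, depth_mean = 2000,
                               depth_sd = 0, seed = 4)
  pc <- simulate_pseudo_cells(c(a = 5e5, b = 5e5), params)
  n_reads <- sum(pc$counts)
  frac <- sum(pc$counts[, "a"]) / n_reads
  se <- sqrt(0.25 / n_reads)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("pooled pseudo-cell proportions converge to TPM at high depth", {
  tpm <- stats::setNames(c(2, 5, 10, 23, 60) / 100 * 1e6, letters[1:5])
  pc <- simulate_pseudo_cells(tpm, pseudo_cell_params(n_cells = 900,
                                                      depth_mean = 1e5,
                                                      depth_sd = 0, seed = 5))
  props <- Matrix::colSums(pc$counts) / sum(pc$counts)
  expect_true(all(abs(props - tpm / 1e6) / (tpm / 1e6) < 0.01))
})

test_that("bulk profiles match their own clusters with near-perfect r", {
  sim <- small_atlas(seed = 11)
  norm <- lognormalize(sim$matrix)
  labels <- truth_labels(sim$truth)
  bulk <- simulate_bulk_profiles(sim$matrix, sim$truth)
  ca <- match_bulk_to_clusters(
    bulk, pseudo_cell_params(n_cells = 300, depth_mean = 2e4, depth_sd = 0,
                             seed = 12),
    norm, labels)
  expect_equal(ca$best_match$cluster, c("1", "2"))
  expect_true(all(ca$best_match$r > 0.99))
  expect_true(all(ca$matrix >= -1 & ca$matrix <= 1))
})

test_that("orthogonal one-hot signatures give the identity assignment", {
  # two clusters with disjoint signatures, bulk profiles matching them
  vals <- rbind(matrix(rep(c(5, 0), each = 3), 3), # cluster A expresses g1
                matrix(rep(c(0, 5), each = 3), 3)) # cluster B expresses g2
  vals <- cbind(vals, matrix(c(1, 2, 1, 2, 1, 2), 6, 2)) # shared noise genes
  colnames(vals) <- c("g1", "g2", "n1", "n2")
  rownames(vals) <- sprintf("c%02d", 1:6)
  norm <- nm(vals)
  labels <- tibble::tibble(cell_id = rownames(vals),
                           cluster = rep(c("A", "B"), each = 3))
  tpm <- rbind(typeA = c(9e5, 0, 5e4, 5e4), typeB = c(0, 9e5, 5e4, 5e4))
  colnames(tpm) <- colnames(vals)
  ca <- match_bulk_to_clusters(bulk_profile_set(tpm),
                               pseudo_cell_params(n_cells = 100,
                                                  depth_mean = 1000,
                                                  depth_sd = 0, seed = 6),
                               norm, labels)
  expect_equal(ca$best_match$cluster, c("A", "B"))
})

test_that("relabelling clusters permutes columns but not best-match identity", {
  sim <- small_atlas(seed = 13)
  norm <- lognormalize(sim$matrix)
  bulk <- simulate_bulk_profiles(sim$matrix, sim$truth)
  params <- pseudo_cell_params(n_cells = 200, depth_mean = 5000,
                               depth_sd = 0, seed = 14)
  labels <- truth_labels(sim$truth)
  relabelled <- dplyr::mutate(labels,
                              cluster = dplyr::recode(cluster,
                                                      "1" = "zz", "2" = "aa"))
  ca1 <- match_bulk_to_clusters(bulk, params, norm, labels)
  ca2 <- match_bulk_to_clusters(bulk, params, norm, relabelled)
  map <- c("1" = "zz", "2" = "aa")
  expect_equal(unname(map[ca1$best_match$cluster]), ca2$best_match$cluster)
  expect_equal(unname(ca1$matrix[, c("1", "2")]),
               unname(ca2$matrix[, c("zz", "aa")]))
})

test_that("correlations are invariant under joint gene permutation", {
  sim <- small_atlas(seed = 15)
  norm <- lognormalize(sim$matrix)
  bulk <- simulate_bulk_profiles(sim$matrix, sim$truth)
  params <- pseudo_cell_params(n_cells = 300, depth_mean = 2e4,
                               depth_sd = 0, seed = 16)
  labels <- truth_labels(sim$truth)
  perm <- withr::with_seed(1, sample(colnames(norm$values)))
  norm_p <- normalized_matrix(norm$values[, perm], norm$scale_factor)
  bulk_p <- bulk_profile_set(bulk$tpm[, perm])
  ca1 <- match_bulk_to_clusters(bulk, params, norm, labels)
  ca2 <- match_bulk_to_clusters(bulk_p, params, norm_p, labels)
  # the multinomial draw stream depends on gene order, so equality is
  # statistical (large fixed depth), not bitwise
  expect_equal(ca1$matrix, ca2$matrix, tolerance = 5e-3)
})

test_that("too few shared genes and zero-variance vectors are surfaced", {
  norm <- nm(cbind(g1 = c(1, 2)))
  tpm <- matrix(c(5e5, 5e5), 1, dimnames = list("t", c("g1", "gX")))
  expect_error(match_bulk_to_clusters(bulk_profile_set(tpm),
                                      pseudo_cell_params(seed = 1), norm,
                                      tibble::tibble(cell_id = rownames(norm$values),
                                                     cluster = "A")),
               "2 shared genes")

  # constant cluster average -> NA correlation with a warning, never 0
  vals <- cbind(g1 = c(1, 1, 0, 2), g2 = c(1, 1, 3, 0))
  norm2 <- nm(vals)
  labels <- tibble::tibble(cell_id = rownames(norm2$values),
                           cluster = rep(c("flat", "ok"), each = 2))
  tpm2 <- matrix(c(6e5, 4e5), 1, dimnames = list("t", c("g1", "g2")))
  expect_warning(
    ca <- match_bulk_to_clusters(bulk_profile_set(tpm2),
                                 pseudo_cell_params(n_cells = 20,
                                                    depth_mean = 100,
                                                    depth_sd = 0, seed = 2),
                                 norm2, labels),
    "zero-variance")
  expect_true(is.na(ca$matrix[, "flat"]))
})

test_that("marker_summary reports expressing fraction and mean expression", {
  vals <- cbind(g1 = c(1, 2, 0, 0), g2 = c(0, 0, 0, 0))
  norm <- nm(vals)
  labels <- tibble::tibble(cell_id = rownames(norm$values), cluster = "A")
  ms <- marker_summary(norm, labels, c("g1", "g2"))
  expect_equal(ms$pct_expressing, c(0.5, 0))
  expect_equal(ms$mean_expression, c(0.75, 0))

  single <- nm(cbind(g1 = 2.5))
  ms1 <- marker_summary(single,
                        tibble::tibble(cell_id = rownames(single$values),
                                       cluster = "X"), "g1")
  expect_equal(ms1$pct_expressing, 1)
  expect_equal(ms1$mean_expression, 2.5)

  expect_error(marker_summary(norm, labels, "missing"), "missing")
})

test_that("cluster dendrogram merges by Euclidean distance", {
  # three 1-D cluster averages at 0, 1, 10: (0,1) merge first at height 1
  vals <- matrix(c(0, 0, 1, 1, 10, 10), ncol = 1)
  rownames(vals) <- sprintf("c%02d", 1:6)
  colnames(vals) <- "g1"
  norm <- nm(vals)
  labels <- tibble::tibble(cell_id = rownames(vals),
                           cluster = rep(c("a", "b", "c"), each = 2))
  tree <- cluster_dendrogram(norm, labels)
  expect_equal(length(tree$height), 2)  # n_clusters - 1 merges
  expect_equal(tree$height[1], 1)
  first <- tree$labels[-tree$merge[1, ]]
  expect_setequal(first, c("a", "b"))

  # identical averages merge at height 0
  vals2 <- matrix(c(3, 3, 3, 3), ncol = 1,
                  dimnames = list(sprintf("d%d", 1:4), "g1"))
  labels2 <- tibble::tibble(cell_id = rownames(vals2),
                            cluster = rep(c("p", "q"), each = 2))
  tree2 <- cluster_dendrogram(nm(vals2), labels2)
  expect_equal(tree2$height[1], 0)

  expect_error(cluster_dendrogram(norm,
                                  dplyr::mutate(labels, cluster = "one")),
               ">= 2 clusters")
})
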