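test_that("cluster_cells recovers a planted two-type partition", {
  sim <- simulate_atlas(sim_config(n_types = 2, cells_per_type = 60,
                                   n_genes = 150, n_markers_per_type = 30,
                                   marker_fold = 8,
                                   contamination_fraction = 0,
                                   hemocyte_fraction = 0, seed = 21))
  norm <- lognormalize(sim$matrix)
  hv <- select_hvgs(norm, 100)
  cl <- cluster_cells(norm, hv, n_pcs = 10, resolution = 0.5, seed = 21)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_true(partitions_identical(cl$cluster, sim$truth$true_type))

  again <- cluster_cells(norm, hv, n_pcs = 10, resolution = 0.5, seed = 21)
  expect_identical(cl, again)
})

test_that("a homogeneous blob stays one cluster at resolution 0.5", {
  sim <- simulate_atlas(sim_config(n_types = 1, cells_per_type = 120,
                                   n_genes = 150,
                                   contamination_fraction = 0,
                                   hemocyte_fraction = 0, seed = 22))
  norm <- lognormalize(sim$matrix)
  cl <- cluster_cells(norm, select_hvgs(norm, 100), n_pcs = 10,
                      resolution = 0.5, seed = 22)
  expect_equal(length(unique(cl$cluster)), 1)
})

test_that("cluster_cells validates PC count", {
  norm <- nm(matrix(stats::rnorm(20), 4, 5))
  expect_error(cluster_cells(norm, colnames(norm$values), n_pcs = 4),
               "n_pcs")
})

test_that("log2 fold changes follow the pseudo-count convention", {
  # back-transformed means 15 vs 0 -> log2(16/1) = 4
  vals <- rbind(matrix(log1p(15), 4, 1), matrix(0, 4, 1))
  vals <- cbind(vals, c(1, 2, 1, 2, 1, 2, 1, 2))  # a null gene
  colnames(vals) <- c("marker", "null")
  rownames(vals) <- sprintf("c%02d", 1:8)
  norm <- nm(vals)
  de <- differential_expression(norm, rownames(vals)[1:4], rownames(vals)[5:8])
  expect_equal(de$log2_fold_change[de$gene == "marker"], 4, tolerance = 1e-12)
  expect_equal(de$log2_fold_change[de$gene == "null"], 0, tolerance = 1e-12)
  expect_true(all(de$adj_p >= de$p_value - 1e-15))
})

test_that("identical groups give zero fold change everywhere", {
  vals <- matrix(stats::rnorm(40, 2), 8, 5)
  vals[vals < 0] <- 0
  rownames(vals) <- sprintf("c%02d", 1:8)
  norm <- nm(vals)
  # same value pattern in both groups
  norm$values[5:8, ] <- norm$values[1:4, ]
  de <- differential_expression(norm, rownames(vals)[1:4], rownames(vals)[5:8],
                                min_pct = 0)
  expect_true(all(abs(de$log2_fold_change) < 1e-12))
})

test_that("genes below min_pct in both groups are not tested", {
  vals <- matrix(0, 40, 2)
  vals[1, 1] <- 1; vals[21, 1] <- 1   # gene 1 in 5% of each group
  vals[, 2] <- rep(c(1, 2), 20)       # gene 2 everywhere
  colnames(vals) <- c("rare", "common")
  rownames(vals) <- sprintf("c%02d", 1:40)
  norm <- nm(vals)
  de <- differential_expression(norm, rownames(vals)[1:20],
                                rownames(vals)[21:40], min_pct = 0.1)
  expect_false("rare" %in% de$gene)
  expect_true("common" %in% de$gene)
})

test_that("differential expression is antisymmetric under group swap", {
  sim <- small_atlas(seed = 23)
  norm <- lognormalize(sim$matrix)
  a <- sim$truth$cell_id[sim$truth$true_type == 1]
  b <- sim$truth$cell_id[sim$truth$true_type == 2]
  de_ab <- differential_expression(norm, a, b)
  de_ba <- differential_expression(norm, b, a)
  m <- match(de_ab$gene, de_ba$gene)
  expect_equal(de_ab$log2_fold_change, -de_ba$log2_fold_change[m],
               tolerance = 1e-12)
  expect_equal(de_ab$p_value, de_ba$p_value[m], tolerance = 1e-12)
  expect_error(differential_expression(norm, a, c(b, a[1])), "overlap")
  expect_error(differential_expression(norm, character(0), b), "non-empty")
})

test_that("p-values are uniform under a permutation null", {
  # pool the null p-values over 10 seeded permutations (200 genes x 200
  # cells each) and test uniformity once: a per-seed pass/fail at a fixed
  # alpha would itself reject by chance in a multi-seed loop
  all_p <- unlist(lapply(1:10, function(s) {
    withr::with_seed(s, {
      vals <- matrix(stats::rexp(200 * 200), 200, 200)
      rownames(vals) <- sprintf("c%03d", 1:200)
      colnames(vals) <- sprintf("g%03d", 1:200)
      grp <- sample(rep(c(TRUE, FALSE), 100))
      norm <- nm(vals)
      de <- differential_expression(norm, rownames(vals)[grp],
                                    rownames(vals)[!grp], min_pct = 0)
      de$p_value
    })
  }))
  ks <- suppressWarnings(stats::ks.test(all_p, "punif")$p.value)
  expect_gt(ks, 0.01)
  # nominal type-I error control
  expect_lt(abs(mean(all_p < 0.05) - 0.05), 0.02)
})

test_that("verdicts follow the DEG-count rule including the gap", {
  crit <- split_criterion()
  expect_equal(gliatlas:::verdict_from_count(25, crit), "split")
  expect_equal(gliatlas:::verdict_from_count(21, crit), "split")
  expect_equal(gliatlas:::verdict_from_count(17, crit), "indeterminate")
  expect_equal(gliatlas:::verdict_from_count(14, crit), "artifact")
  expect_equal(gliatlas:::verdict_from_count(0, crit), "artifact")
  expect_error(split_criterion(split_min_genes = 10, artifact_max_genes = 14),
               "artifact_max_genes")
})

test_that("planted mixtures split and homogeneous clusters do not", {
  mixed <- simulate_atlas(sim_config(n_types = 2, cells_per_type = 60,
                                     n_genes = 150, n_markers_per_type = 30,
                                     marker_fold = 8,
                                     contamination_fraction = 0,
                                     hemocyte_fraction = 0, seed = 24))
  norm <- lognormalize(mixed$matrix)
  labels <- tibble::tibble(cell_id = mixed$truth$cell_id, cluster = "0")
  dec <- overclustering_check(norm, labels, "0", seed = 24)
  expect_equal(dec$verdict, "split")
  expect_gte(dec$n_deg, 21)

  homog <- simulate_atlas(sim_config(n_types = 1, cells_per_type = 120,
                                     n_genes = 150,
                                     contamination_fraction = 0,
                                     hemocyte_fraction = 0, seed = 25))
  norm_h <- lognormalize(homog$matrix)
  labels_h <- tibble::tibble(cell_id = homog$truth$cell_id, cluster = "0")
  dec_h <- overclustering_check(norm_h, labels_h, "0", seed = 25)
  expect_equal(dec_h$verdict, "artifact")
  expect_lte(dec_h$n_deg, 14)

  expect_error(overclustering_check(norm, labels[1:3, ], "0"), ">= 4 cells")
})

test_that("split_cluster assigns fresh numeric ids and conserves cells", {
  # 15 clusters labelled 0..14; split cluster "9" into two
  cells <- sprintf("c%03d", 1:150)
  labels <- tibble::tibble(cell_id = cells,
                           cluster = as.character(rep(0:14, each = 10)))
  members <- labels$cell_id[labels$cluster == "9"]
  sub <- tibble::tibble(cell_id = members,
                        subcluster = rep(c("s0", "s1"), c(6, 4)))
  out <- split_cluster(labels, "9", sub)
  expect_equal(nrow(out), 150)
  expect_setequal(unique(out$cluster), as.character(0:15))
  # larger subcluster keeps 9, smaller becomes 15
  expect_equal(sum(out$cluster == "9"), 6)
  expect_equal(sum(out$cluster == "15"), 4)

  # splitting into one group is the identity
  ident <- split_cluster(labels, "9",
                         tibble::tibble(cell_id = members, subcluster = "s"))
  expect_equal(ident$cluster, labels$cluster)

  # invertible through the recorded map
  map <- attr(out, "split_map")
  restored <- out$cluster
  restored[restored %in% map$new_cluster] <- "9"
  expect_equal(restored, labels$cluster)

  expect_error(split_cluster(labels, "9",
                             tibble::tibble(cell_id = c(members[-1], "c001"),
                                            subcluster = "s")),
               "exactly the cells")
})
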