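#' Configuration for the synthetic atlas generator
#'
#' Collects and validates all knobs of [simulate_atlas()]. Defaults emulate a
#' small dissociated-CNS experiment: a handful of transcriptionally distinct
#' cell types with dedicated marker programs, lognormally skewed library
#' sizes, a mitochondrial gene set, a minority of cells carrying an added
#' neuronal ambient-contamination program, a sprinkle of hemocytes, and two
#' sequencing batches of unequal size.
#'
#' @param n_types number of cell types.
#' @param cells_per_type integer vector, one entry per type (recycled from a
#'   scalar).
#' @param n_genes total number of genes, including the reserved
#'   mitochondrial (`mt-*`), neuronal-program (`neu-*`) and hemocyte
#'   (`Hml-like`) genes.
#' @param n_markers_per_type number of dedicated marker genes per type (also
#'   the size of the neuronal program).
#' @param marker_fold expression ratio of a marker gene in its own type
#'   relative to any other type; must be >= 1.
#' @param baseline_mean relative expression weight of non-marker genes; only
#'   ratios of weights matter under multinomial read allocation.
#' @param depth_lognormal_mu,depth_lognormal_sigma log-scale mean and sd of
#'   the per-cell library-size distribution (libraries are rounded and
#'   truncated to >= 1).
#' @param mito_gene_fraction fraction of genes flagged mitochondrial; because
#'   all baseline genes share one weight, the typical per-cell mitochondrial
#'   read fraction is close to this value.
#' @param contamination_fraction fraction of cells receiving the added
#'   neuronal program.
#' @param contamination_strength target log-normalized expression level of
#'   each neuronal-program gene in contaminated cells (under scale factor
#'   10,000). Must exceed 1.2 so contaminated cells clear the gating
#'   threshold of 1 with at least a 20% margin; clean cells carry zero
#'   neuronal reads and miss it with certainty.
#' @param hemocyte_fraction fraction of cells flagged as hemocytes (given one
#'   `Hml-like` read; disjoint from the contaminated set).
#' @param rare_pair optional length-2 integer vector of type indices flagged
#'   as a merged rare pair in the ground truth.
#' @param batch_proportions two positive reals summing to 1; cells are
#'   assigned to batches `"batch1"`/`"batch2"` with these probabilities.
#' @param seed integer seed; all randomness flows from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_types = 4,
                       cells_per_type = 200,
                       n_genes = 200,
                       n_markers_per_type = 10,
                       marker_fold = 8,
                       baseline_mean = 1,
                       depth_lognormal_mu = log(2000),
                       depth_lognormal_sigma = 0.3,
                       mito_gene_fraction = 0.05,
                       contamination_fraction = 0.1,
                       contamination_strength = 2,
                       hemocyte_fraction = 0.01,
                       rare_pair = NULL,
                       batch_proportions = c(0.8, 0.2),
                       seed = 1L) {
  if (length(cells_per_type) == 1) {
    cells_per_type <- rep(cells_per_type, n_types)
  }
  cfg <- list(n_types = as.integer(n_types),
              cells_per_type = as.integer(cells_per_type),
              n_genes = as.integer(n_genes),
              n_markers_per_type = as.integer(n_markers_per_type),
              marker_fold = marker_fold, baseline_mean = baseline_mean,
              depth_lognormal_mu = depth_lognormal_mu,
              depth_lognormal_sigma = depth_lognormal_sigma,
              mito_gene_fraction = mito_gene_fraction,
              contamination_fraction = contamination_fraction,
              contamination_strength = contamination_strength,
              hemocyte_fraction = hemocyte_fraction,
              rare_pair = if (!is.null(rare_pair)) as.integer(rare_pair),
              batch_proportions = batch_proportions,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (cfg$n_types < 1) bad("n_types", "must be >= 1")
  if (length(cfg$cells_per_type) != cfg$n_types) {
    bad("cells_per_type", "length must equal n_types")
  }
  if (any(cfg$cells_per_type < 1)) bad("cells_per_type", "all entries must be >= 1")
  if (cfg$marker_fold < 1) bad("marker_fold", "must be >= 1")
  if (cfg$baseline_mean <= 0) bad("baseline_mean", "must be positive")
  for (f in c("mito_gene_fraction", "contamination_fraction",
              "hemocyte_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "must be in [0, 1]")
  }
  if (cfg$contamination_strength < 0) {
    bad("contamination_strength", "must be non-negative")
  }
  if (cfg$contamination_fraction > 0 && cfg$contamination_strength <= 1.2) {
    bad("contamination_strength",
        "must exceed 1.2 so contaminated cells clear the gate with margin")
  }
  if (length(cfg$batch_proportions) != 2 ||
      any(cfg$batch_proportions < 0) ||
      abs(sum(cfg$batch_proportions) - 1) > 1e-8) {
    bad("batch_proportions", "must be two non-negative reals summing to 1")
  }
  if (!is.null(cfg$rare_pair) &&
      (length(cfg$rare_pair) != 2 || any(cfg$rare_pair < 1) ||
       any(cfg$rare_pair > cfg$n_types) ||
       cfg$rare_pair[1] == cfg$rare_pair[2])) {
    bad("rare_pair", "must be two distinct type indices in 1..n_types")
  }
  n_reserved <- n_reserved_genes(cfg)
  if (cfg$n_genes < n_reserved + 1) {
    bad("n_genes", sprintf(
      "too small: %d reserved genes (mito + neuronal + hemocyte + markers) need n_genes >= %d",
      n_reserved, n_reserved + 1))
  }
  invisible(cfg)
}

n_mito_genes <- function(cfg) {
  if (cfg$mito_gene_fraction == 0) 0L else
    max(1L, as.integer(round(cfg$mito_gene_fraction * cfg$n_genes)))
}

n_reserved_genes <- function(cfg) {
  n_mito_genes(cfg) + cfg$n_markers_per_type +  # mito + neuronal program
    1L +                                        # Hml-like
    cfg$n_types * cfg$n_markers_per_type        # type markers
}

# Scale factor the gating thresholds are defined under.
GATING_SCALE_FACTOR <- 1e4

#' Simulate a cell-by-gene atlas with planted ground truth
#'
#' Draws each cell's library size from a lognormal, allocates reads over
#' genes by a per-type multinomial whose marker genes are up-weighted by
#' `marker_fold`, then plants contamination and hemocyte signals
#' deterministically in count space: contaminated cells receive exactly
#' enough added reads on every neuronal-program gene that their
#' log-normalized value (scale factor 10,000) equals at least
#' `contamination_strength`, while clean cells carry zero neuronal reads.
#' Hemocytes receive one `Hml-like` read. Ground truth is therefore exact:
#' the gating rules `neu-* <= 1` and `Hml-like <= 0` recover the planted
#' flags with 100% sensitivity and specificity.
#'
#' Because every type up-weights the same number of markers by the same
#' fold, the probability normalizer is identical across types and the
#' expected own-type/other-type ratio of marker counts equals `marker_fold`
#' exactly.
#'
#' @param config a [sim_config()].
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (tibble with `cell_id`, `true_type`, `contaminated`, `hemocyte`,
#'   `rare_pair_member`, `library_size` = the drawn pre-planting depth).
#' @export
#' @examples
#' sim <- simulate_atlas(sim_config(n_types = 2, cells_per_type = 50,
#'                                  n_genes = 100, seed = 7))
#' sim$matrix
#' table(sim$truth$true_type)
simulate_atlas <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_atlas_impl(config))
}

simulate_atlas_impl <- function(cfg) {
  n_mito <- n_mito_genes(cfg)
  n_neu <- cfg$n_markers_per_type
  n_marker <- cfg$n_types * cfg$n_markers_per_type
  n_base <- cfg$n_genes - n_mito - n_neu - 1L - n_marker

  gene_ids <- c(sprintf("g%04d", seq_len(n_base)),
                if (n_mito > 0) sprintf("mt-%d", seq_len(n_mito)),
                sprintf("neu-%d", seq_len(n_neu)),
                "Hml-like",
                sprintf("g%04d", n_base + seq_len(n_marker)))
  marker_of <- rep(NA_integer_, cfg$n_genes)
  marker_idx <- (cfg$n_genes - n_marker + 1L):cfg$n_genes
  marker_of[marker_idx] <- rep(seq_len(cfg$n_types),
                               each = cfg$n_markers_per_type)
  is_mito <- startsWith(gene_ids, "mt-")
  is_neu <- startsWith(gene_ids, "neu-")
  is_hml <- gene_ids == "Hml-like"

  n_cells <- sum(cfg$cells_per_type)
  true_type <- rep(seq_len(cfg$n_types), times = cfg$cells_per_type)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))

  depth <- pmax(1, round(stats::rlnorm(n_cells, cfg$depth_lognormal_mu,
                                       cfg$depth_lognormal_sigma)))

  # per-type gene probabilities; neuronal + hemocyte genes get zero weight
  base_w <- rep(cfg$baseline_mean, cfg$n_genes)
  base_w[is_neu | is_hml] <- 0
  probs <- lapply(seq_len(cfg$n_types), function(t) {
    w <- base_w
    w[!is.na(marker_of) & marker_of == t] <- cfg$baseline_mean * cfg$marker_fold
    w / sum(w)
  })

  counts <- matrix(0L, n_cells, cfg$n_genes)
  for (t in seq_len(cfg$n_types)) {
    rows <- which(true_type == t)
    counts[rows, ] <- t(vapply(
      rows, function(i) stats::rmultinom(1, depth[i], probs[[t]])[, 1],
      integer(cfg$n_genes)))
  }

  n_cont <- round(cfg$contamination_fraction * n_cells)
  contaminated <- rep(FALSE, n_cells)
  contaminated[sample.int(n_cells, n_cont)] <- TRUE
  n_hem <- round(cfg$hemocyte_fraction * n_cells)
  hemocyte <- rep(FALSE, n_cells)
  clean_pool <- which(!contaminated)
  hemocyte[sample(clean_pool, min(n_hem, length(clean_pool)))] <- TRUE

  if (any(contaminated)) {
    # added reads a per neuronal gene solve
    # log1p(a / (T0 + k a) * sf) >= strength  =>  a >= q T0 / (1 - k q)
    q <- (exp(cfg$contamination_strength) - 1) / GATING_SCALE_FACTOR
    k <- n_neu
    stopifnot(k * q < 1)
    a <- ceiling(q * depth[contaminated] / (1 - k * q))
    counts[contaminated, is_neu] <- matrix(rep(a, times = k), ncol = k)
  }
  counts[hemocyte, is_hml] <- 1L

  batch <- sample(c("batch1", "batch2"), n_cells, replace = TRUE,
                  prob = cfg$batch_proportions)

  rare_member <- rep(FALSE, n_cells)
  if (!is.null(cfg$rare_pair)) rare_member <- true_type %in% cfg$rare_pair

  dimnames(counts) <- list(cell_ids, gene_ids)
  mat <- expression_matrix(
    counts,
    cell_meta = tibble::tibble(cell_id = cell_ids, batch = batch,
                               true_type = true_type),
    gene_meta = tibble::tibble(gene_id = gene_ids, is_mitochondrial = is_mito,
                               marker_of = marker_of))
  truth <- tibble::tibble(cell_id = cell_ids, true_type = true_type,
                          contaminated = contaminated, hemocyte = hemocyte,
                          rare_pair_member = rare_member,
                          library_size = as.numeric(depth))
  list(matrix = mat, truth = truth)
}

#' Collapse a simulated atlas to per-type bulk TPM profiles
#'
#' Averages raw counts within each true type and rescales each type's vector
#' to sum to one million, mimicking the deep bulk cell-type transcriptomes
#' that seed pseudo-cell simulation.
#'
#' @param matrix an [expression_matrix()].
#' @param truth the paired ground-truth tibble from [simulate_atlas()] (only
#'   `cell_id` and `true_type` are used).
#' @return A [bulk_profile_set()] with one TPM row per type, named
#'   `type<i>`.
#' @export
simulate_bulk_profiles <- function(matrix, truth) {
  stopifnot(inherits(matrix, "expression_matrix"))
  truth <- tibble::as_tibble(truth)
  idx <- match(rownames(matrix$counts), truth$cell_id)
  if (anyNA(idx)) stop("matrix and truth are not paired", call. = FALSE)
  types <- sort(unique(truth$true_type[idx]))
  tpm <- t(vapply(types, function(t) {
    rows <- which(truth$true_type[idx] == t)
    if (length(rows) == 0) stop("type with zero cells: ", t, call. = FALSE)
    mu <- Matrix::colMeans(matrix$counts[rows, , drop = FALSE])
    1e6 * mu / sum(mu)
  }, numeric(ncol(matrix$counts))))
  rownames(tpm) <- paste0("type", types)
  colnames(tpm) <- colnames(matrix$counts)
  bulk_profile_set(tpm)
}

#' Simulate an ROI intensity table with planted positivity
#'
#' Generates one record per nucleus (region label + mean probe intensity)
#' with known positive flags. Positives are drawn so their intensity scaled
#' by the generated normalization value lands strictly above the 2.25
#' positivity threshold with margin; negatives land strictly below.
#'
#' @param n_nuclei number of nuclei.
#' @param region_props per-region proportions of nuclei; must sum to 1.
#'   Names are used as region labels (default `region1`, ...).
#' @param positive_frac_per_region per-region fraction of positive nuclei;
#'   same length as `region_props`.
#' @param intensity_params list with `normalization_value` (default 100) and
#'   scaled intensity ranges `pos_range` (default `c(3, 5)`) and `neg_range`
#'   (default `c(0, 1.5)`); ranges are in units of the normalization value.
#' @param seed integer seed.
#' @return List with `rois` (tibble `roi_id`, `region`, `mean_intensity`),
#'   `truth` (tibble `roi_id`, `positive`) and `normalization_value`.
#' @export
simulate_roi_table <- function(n_nuclei, region_props, positive_frac_per_region,
                               intensity_params = list(), seed = 1L) {
  if (length(region_props) != length(positive_frac_per_region)) {
    stop("region_props and positive_frac_per_region must have equal length",
         call. = FALSE)
  }
  if (abs(sum(region_props) - 1) > 1e-8) {
    stop("region_props must sum to 1", call. = FALSE)
  }
  if (any(positive_frac_per_region < 0 | positive_frac_per_region > 1)) {
    stop("positive fractions must be in [0, 1]", call. = FALSE)
  }
  ip <- utils::modifyList(list(normalization_value = 100,
                               pos_range = c(3, 5), neg_range = c(0, 1.5)),
                          intensity_params)
  if (min(ip$pos_range) <= 2.25 || max(ip$neg_range) >= 2.25) {
    stop("intensity ranges must not straddle the 2.25 threshold", call. = FALSE)
  }
  regions <- names(region_props)
  if (is.null(regions)) regions <- paste0("region", seq_along(region_props))
  withr::with_seed(seed, {
    region <- sample(regions, n_nuclei, replace = TRUE, prob = region_props)
    frac <- positive_frac_per_region[match(region, regions)]
    positive <- stats::runif(n_nuclei) < frac
    scaled <- ifelse(positive,
                     stats::runif(n_nuclei, ip$pos_range[1], ip$pos_range[2]),
                     stats::runif(n_nuclei, ip$neg_range[1], ip$neg_range[2]))
    rois <- tibble::tibble(roi_id = sprintf("roi%05d", seq_len(n_nuclei)),
                           region = region,
                           mean_intensity = scaled * ip$normalization_value)
    list(rois = rois,
         truth = tibble::tibble(roi_id = rois$roi_id, positive = positive),
         normalization_value = ip$normalization_value)
  })
}

#' Simulate a clone-category count table
#'
#' One multinomial draw of `n_clones` clones over categories, emulating
#' tallies of labelled clones by morphological category.
#'
#' @param category_probs per-category probabilities; must sum to 1. Names are
#'   used as category labels.
#' @param n_clones total number of clones (>= 1).
#' @param seed integer seed.
#' @return Tibble with `category` and `count`; counts sum to `n_clones`.
#' @export
simulate_clone_table <- function(category_probs, n_clones, seed = 1L) {
  if (any(category_probs < 0)) stop("category_probs must be non-negative",
                                    call. = FALSE)
  if (abs(sum(category_probs) - 1) > 1e-8) {
    stop("category_probs must sum to 1", call. = FALSE)
  }
  if (n_clones < 1) stop("n_clones must be >= 1", call. = FALSE)
  cats <- names(category_probs)
  if (is.null(cats)) cats <- paste0("category", seq_along(category_probs))
  counts <- withr::with_seed(seed,
    stats::rmultinom(1, n_clones, category_probs)[, 1])
  tibble::tibble(category = cats, count = as.integer(counts))
}
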