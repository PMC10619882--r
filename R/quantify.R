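#' Normalization value of an intensity image
#'
#' Mean fluorescence intensity of the average-intensity projection of the
#' probe channel. A 3-D stack is first averaged over its third axis; by
#' linearity the result equals the grand mean of all voxels.
#'
#' @param image 2-D matrix or 3-D array of non-negative intensities.
#' @return Positive scalar; an all-zero image is an error because the value
#'   is used as a divisor.
#' @export
compute_normalization_value <- function(image) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), mean)
  v <- mean(image)
  if (v <= 0) stop("normalization value must be > 0 (all-zero image?)",
                   call. = FALSE)
  v
}

#' HCR positivity parameters
#'
#' @param normalization_value per-sample mean projection intensity (see
#'   [compute_normalization_value()]); must be positive.
#' @param threshold scaled-intensity positivity threshold, default 2.25;
#'   nuclei are positive strictly above it.
#' @return List of class `positivity_params`.
#' @export
positivity_params <- function(normalization_value, threshold = 2.25) {
  if (normalization_value <= 0) {
    stop("normalization_value must be positive", call. = FALSE)
  }
  structure(list(normalization_value = normalization_value,
                 threshold = threshold), class = "positivity_params")
}

#' Score per-nucleus HCR positivity
#'
#' Scales each nucleus's mean probe intensity by the sample normalization
#' value; a nucleus is positive when the scaled value is strictly above the
#' threshold.
#'
#' @param rois data frame with columns `roi_id`, `region`, `mean_intensity`.
#' @param params a [positivity_params()].
#' @param regions optional declared region set; labels outside it are an
#'   error. Defaults to the labels present.
#' @return Object of class `hcr_positivity`: list with `scores` (per-nucleus
#'   tibble adding `scaled_intensity`, `positive`) and `summary` (tibble of
#'   per-region and overall positive fractions).
#' @export
#' @examples
#' rois <- tibble::tibble(roi_id = c("r1", "r2"), region = "medulla",
#'                        mean_intensity = c(5, 1))
#' score_hcr_positivity(rois, positivity_params(2))$scores
score_hcr_positivity <- function(rois, params, regions = NULL) {
  stopifnot(inherits(params, "positivity_params"))
  rois <- tibble::as_tibble(rois)
  stopifnot(all(c("roi_id", "region", "mean_intensity") %in% names(rois)))
  if (any(rois$mean_intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (!is.null(regions)) {
    unknown <- setdiff(unique(rois$region), regions)
    if (length(unknown) > 0) {
      stop("unknown region labels: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  scores <- dplyr::mutate(
    rois,
    scaled_intensity = .data$mean_intensity / params$normalization_value,
    positive = .data$scaled_intensity > params$threshold)
  by_region <- scores |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(), n_positive = sum(.data$positive),
                     positive_fraction = mean(.data$positive),
                     .groups = "drop")
  overall <- tibble::tibble(region = "(overall)", n = nrow(scores),
                            n_positive = sum(scores$positive),
                            positive_fraction = mean(scores$positive))
  structure(list(scores = scores,
                 summary = dplyr::bind_rows(by_region, overall),
                 params = params),
            class = "hcr_positivity")
}

#' @export
print.hcr_positivity <- function(x, ...) {
  cat(sprintf("<hcr_positivity> %d nuclei, threshold %g\n",
              nrow(x$scores), x$params$threshold))
  print(x$summary)
  invisible(x)
}

#' Chi-square test of regional positivity distribution
#'
#' Goodness-of-fit of the per-region positive-nucleus counts against the
#' distribution expected if positives followed the regional distribution of
#' all nuclei: expected = total positives x region share of all nuclei, with
#' `regions - 1` degrees of freedom and no continuity correction.
#'
#' @param positives named vector (or tibble `region`, `count`) of positive
#'   counts per region.
#' @param all_nuclei same shape, counts of all nuclei per region; every
#'   region needs a positive expected count.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
regional_distribution_test <- function(positives, all_nuclei) {
  positives <- as_region_counts(positives)
  all_nuclei <- as_region_counts(all_nuclei)
  regions <- names(all_nuclei)
  if (!setequal(regions, names(positives))) {
    stop("positives and all_nuclei must cover the same regions", call. = FALSE)
  }
  positives <- positives[regions]
  if (length(regions) < 2) stop("need >= 2 regions (df would be 0)",
                                call. = FALSE)
  shares <- all_nuclei / sum(all_nuclei)
  expected <- sum(positives) * shares
  if (any(expected == 0)) {
    stop("zero expected count in region(s) ",
         paste(regions[expected == 0], collapse = ", "),
         "; merge sparse regions before testing", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(positives, p = shares))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

as_region_counts <- function(x) {
  if (inherits(x, "data.frame")) {
    stopifnot(all(c("region", "count") %in% names(x)))
    stats::setNames(x$count, x$region)
  } else {
    if (is.null(names(x))) names(x) <- paste0("region", seq_along(x))
    x
  }
}

#' Detect nucleus-like blobs in a 3-D stack
#'
#' Laplacian-of-Gaussian style blob detection: the stack is smoothed with a
#' separable Gaussian whose sigma is derived from the expected spot scale
#' (`sigma = scale_px / 4`), then local maxima over the 26-neighbourhood
#' that exceed a relative threshold are reported. Sensitivity maps linearly
#' from 0-100 to a relative peak threshold of 1.0-0.0 of the maximum
#' response, so higher sensitivity finds dimmer spots.
#'
#' @param stack 3-D numeric array (or 2-D matrix, treated as a single
#'   plane).
#' @param scale_px expected spot diameter in pixels.
#' @param sensitivity detection sensitivity in `[0, 100]`.
#' @return Tibble of centroids with columns `x`, `y`, `z`, `response`; empty
#'   for a blank image.
#' @export
detect_nuclei <- function(stack, scale_px = 13, sensitivity = 70) {
  if (length(stack) == 0) stop("empty stack", call. = FALSE)
  if (sensitivity < 0 || sensitivity > 100) {
    stop("sensitivity must be in [0, 100]", call. = FALSE)
  }
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  if (max(stack) <= 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          response = numeric()))
  }
  sigma <- max(scale_px / 4, 0.8)
  sm <- gaussian_smooth_3d(stack, sigma)
  rel_threshold <- 1 - sensitivity / 100
  threshold <- rel_threshold * max(sm)
  peaks <- local_maxima_3d(sm)
  keep <- sm[peaks] > threshold & sm[peaks] > 0
  idx <- peaks[keep, , drop = FALSE]
  tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                 response = sm[idx]) |>
    dplyr::arrange(dplyr::desc(.data$response))
}

# separable Gaussian smoothing along each axis of a 3-D array
gaussian_smooth_3d <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  for (axis in 1:3) {
    if (dim(a)[axis] > 1) a <- convolve_axis(a, kern, axis)
  }
  a
}

convolve_axis <- function(a, kern, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  r <- (length(kern) - 1) / 2
  # replicate-pad ends so edges are not darkened
  padded <- rbind(m[rep(1, r), , drop = FALSE], m,
                  m[rep(nrow(m), r), , drop = FALSE])
  out <- apply(padded, 2, function(col) {
    stats::filter(col, kern, sides = 2)[(r + 1):(r + nrow(m))]
  })
  aperm(array(out, d[perm]), order(perm))
}

local_maxima_3d <- function(a) {
  d <- dim(a)
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  is_max <- array(TRUE, d)
  for (s in seq_len(nrow(shifts))) {
    shifted <- shift_array(a, shifts$dx[s], shifts$dy[s], shifts$dz[s])
    is_max <- is_max & (a >= shifted)
  }
  which(is_max, arr.ind = TRUE)
}

shift_array <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(-Inf, d)
  src_x <- seq_len(d[1]) - dx; src_y <- seq_len(d[2]) - dy
  src_z <- seq_len(d[3]) - dz
  ok_x <- src_x >= 1 & src_x <= d[1]
  ok_y <- src_y >= 1 & src_y <= d[2]
  ok_z <- src_z >= 1 & src_z <= d[3]
  out[ok_x, ok_y, ok_z] <- a[src_x[ok_x], src_y[ok_y], src_z[ok_z]]
  out
}

#' Layer-binned volume of a 3-D mask
#'
#' Counts mask voxels falling into consecutive neuropil-layer bins along the
#' layer axis and converts to volume. Layer boundaries define half-open
#' intervals `[lower, upper)`; `bin_layers` consecutive layers are pooled
#' per bin (default 2). Voxels outside all layers are reported in an
#' explicit `"outside"` bin so volume is conserved.
#'
#' @param mask 3-D logical/0-1 array.
#' @param boundaries strictly increasing numeric vector of layer boundary
#'   positions (micrometres) along the layer axis; `length(boundaries) - 1`
#'   layers.
#' @param voxel_size length-3 numeric, micrometres per voxel along each
#'   axis.
#' @param layer_axis which array axis runs across layers, default 3.
#' @param bin_layers layers pooled per bin, default 2.
#' @return Tibble with `bin`, `layers`, `volume` (cubic micrometres),
#'   including the `"outside"` bin.
#' @export
layer_binned_volume <- function(mask, boundaries, voxel_size = c(1, 1, 1),
                                layer_axis = 3, bin_layers = 2) {
  stopifnot(length(dim(mask)) == 3, length(voxel_size) == 3)
  if (any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  n_layers <- length(boundaries) - 1
  n_bins <- ceiling(n_layers / bin_layers)
  vox_vol <- prod(voxel_size)
  idx <- which(mask != 0, arr.ind = TRUE)
  # voxel-centre position along the layer axis
  pos <- (idx[, layer_axis] - 0.5) * voxel_size[layer_axis]
  layer <- findInterval(pos, boundaries, left.open = FALSE)
  layer[pos >= boundaries[length(boundaries)]] <- 0  # beyond last boundary
  bin <- ifelse(layer >= 1 & layer <= n_layers,
                ceiling(layer / bin_layers), NA)
  counts <- vapply(seq_len(n_bins), function(b) sum(bin == b, na.rm = TRUE),
                   numeric(1))
  outside <- sum(is.na(bin))
  layer_span <- vapply(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_layers + 1
    hi <- min(b * bin_layers, n_layers)
    if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }, character(1))
  tibble::tibble(bin = c(as.character(seq_len(n_bins)), "outside"),
                 layers = c(layer_span, NA),
                 volume = c(counts, outside) * vox_vol)
}

#' Clone-category proportions and significance tests
#'
#' Summarizes a clone-count table as percentages (one decimal) and runs the
#' requested tests: two-sided Fisher's exact on a 2x2 table, two-sided
#' Mann-Whitney U on two numeric samples (exact enumeration when both
#' samples have at most 20 observations and no ties, normal approximation
#' otherwise; identical samples give `U = n1*n2/2` and p = 1), or a
#' goodness-of-fit chi-square against expected proportions.
#'
#' @param table for proportions and `"fisher"`: a matrix or data frame of
#'   counts (2x2 for Fisher). For `"chisq"`: a vector of counts.
#' @param test one of `"none"`, `"fisher"`, `"chisq"`,
#'   `"mann_whitney"`.
#' @param x,y numeric samples for `test = "mann_whitney"` (then `table` may
#'   be `NULL`).
#' @param expected_props expected proportions for `test = "chisq"`.
#' @return Object of class `clone_stats`: list with `proportions` (tibble
#'   `category`, `count`, `percent`, percentages rounded to 1 decimal) and
#'   `test` (tibble with `method`, `statistic`, `p_value`; `NULL` for
#'   `"none"`).
#' @export
#' @examples
#' clone_proportion_stats(c(surface = 70, channel = 22, lining = 9))
clone_proportion_stats <- function(table = NULL,
                                   test = c("none", "fisher", "chisq",
                                            "mann_whitney"),
                                   x = NULL, y = NULL,
                                   expected_props = NULL) {
  test <- match.arg(test)
  proportions <- NULL
  if (!is.null(table)) {
    counts <- if (is.matrix(table)) table else
      if (inherits(table, "data.frame")) as.matrix(table) else
        as.matrix(table)
    if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
    totals <- if (is.null(dim(table)) || any(dim(counts) == 1)) {
      v <- as.numeric(counts)
      nm <- if (!is.null(names(table))) names(table) else
        paste0("category", seq_along(v))
      tibble::tibble(category = nm, count = v,
                     percent = round(100 * v / sum(v), 1))
    } else {
      v <- rowSums(counts)
      nm <- rownames(counts) %||% paste0("category", seq_along(v))
      tibble::tibble(category = nm, count = v,
                     percent = round(100 * v / sum(v), 1))
    }
    proportions <- totals
  }
  test_res <- switch(test,
    none = NULL,
    fisher = {
      m <- as.matrix(table)
      if (!all(dim(m) == c(2, 2))) stop("Fisher test needs a 2x2 table",
                                        call. = FALSE)
      res <- stats::fisher.test(m, alternative = "two.sided")
      tibble::tibble(method = "fisher_exact",
                     statistic = unname(res$estimate),
                     p_value = res$p.value)
    },
    chisq = {
      v <- as.numeric(table)
      if (is.null(expected_props)) expected_props <- rep(1 / length(v),
                                                         length(v))
      res <- suppressWarnings(stats::chisq.test(v, p = expected_props))
      tibble::tibble(method = "chisq_gof",
                     statistic = unname(res$statistic),
                     p_value = res$p.value)
    },
    mann_whitney = {
      if (is.null(x) || is.null(y)) stop("mann_whitney needs x and y",
                                         call. = FALSE)
      mw <- mann_whitney_u(x, y)
      tibble::tibble(method = "mann_whitney_u", statistic = mw$U,
                     p_value = mw$p_value)
    })
  structure(list(proportions = proportions, test = test_res),
            class = "clone_stats")
}

#' @export
print.clone_stats <- function(x, ...) {
  cat("<clone_stats>\n")
  if (!is.null(x$proportions)) print(x$proportions)
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Mid-rank U statistic with p-value from [stats::wilcox.test()]: exact
#' enumeration when both samples have <= 20 observations and there are no
#' ties, normal approximation otherwise. When all observations are tied the
#' rank variance is zero and the p-value is 1 by definition (`U = n1*n2/2`).
#'
#' @param x,y numeric samples.
#' @return List with `U` and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1) {
    return(list(U = U, p_value = 1))
  }
  exact <- n1 <= 20 && n2 <= 20 && !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
  list(U = U, p_value = p)
}
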