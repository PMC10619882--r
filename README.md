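# gliatlas

Tools for building and validating glial single-cell atlases, modelled on the
analysis pipeline of a *Drosophila* CNS glia study. Single-cell RNA-seq of
glia is unusually messy: glia are few (a minority of CNS cells), fragile
during dissociation, and their droplets are frequently contaminated with
ambient neuronal transcripts, so a usable glial atlas depends on a chain of
bespoke filtering, annotation and validation steps. `gliatlas` packages
those steps as tested, composable functions:

* **QC and normalization** — retain cells with mitochondrial read fraction
  strictly below 10% and detected-gene counts in [50, 3000]; log-normalize
  with `value = ln(1 + count/total × 10,000)`; rank highly variable genes by
  variance of the normalized values.
* **Marker-threshold gating** — remove neuronal-contaminated cells
  (pan-neuronal markers at normalized expression ≤ 1, e.g. *Rdl*, *Frq1*,
  *Nckx30C*) and hemocytes (*Hml* ≤ 0), or positively select populations
  (midline glia: *sim* > 0 and *wrapper* > 0 with *repo* = 0, *elav* = 0).
* **Batch-contribution filtering** — drop clusters to which a designated
  minority dataset contributes fewer than 1% of cells.
* **Bulk-to-cluster annotation** — convert a deep bulk cell-type
  transcriptome into 900 shallow pseudo-single cells (depths drawn from a
  normal matched to the reference dataset; reads allocated multinomially
  with `p_g = TPM_g / ΣTPM`) and assign each bulk type to the scRNA-seq
  cluster with the highest Pearson correlation of average log-normalized
  expression.
* **Over-clustering criterion** — a candidate subdivision is a real split
  only when more than 20 genes differ at ≥ 4-fold (|log2FC| ≥ 2) between
  its two largest subclusters; fewer than 15 such genes marks an
  over-clustering artifact; counts in between stay indeterminate.
* **Gene-set enrichment** — upper-tail hypergeometric tests with
  Benjamini–Hochberg adjustment, redundancy reduction at pairwise
  similarity > 0.7, and Ward grouping of the top 20 terms.
* **Imaging and clone statistics** — HCR positivity (scaled intensity
  strictly above 2.25), regional chi-square tests, Laplacian-of-Gaussian
  nucleus detection, layer-binned cell volumes, Fisher's exact and
  Mann–Whitney U tests for clone-category tables.
* **Synthetic data with planted ground truth** — `simulate_atlas()` and
  friends generate count matrices, bulk TPM profiles, ROI intensity tables
  and clone tallies whose contamination flags, cell types and positivity
  labels are known exactly, so every stage of the pipeline is testable
  offline.

Results come back as tibbles (or small S3 objects with `tidy()`/`glance()`
methods and `autoplot()` figures), so the pipeline composes with dplyr and
ggplot2.

## Worked example

Simulate a three-type atlas with 10% neuronal contamination, clean it up,
and annotate the clusters from their own bulk profiles:

```r
library(gliatlas)

sim  <- simulate_atlas(sim_config(n_types = 3, cells_per_type = 100,
                                  n_genes = 150,
                                  contamination_fraction = 0.1, seed = 1))
qc   <- qc_filter(sim$matrix, qc_thresholds())
norm <- lognormalize(qc$matrix)

rules <- cleanup_rules(grep("^neu-", colnames(norm$values), value = TRUE))
gated <- gate_cells(norm, rules, mode = "remove_if_any")
length(gated$removed)
#> [1] 33

clean  <- subset_cells(qc$matrix, cells = gated$kept)
norm2  <- lognormalize(clean)
bulk   <- simulate_bulk_profiles(sim$matrix, sim$truth)
keep   <- sim$truth$cell_id %in% gated$kept
labels <- tibble::tibble(cell_id = sim$truth$cell_id[keep],
                         cluster = as.character(sim$truth$true_type[keep]))
match_bulk_to_clusters(bulk, pseudo_cell_params(seed = 2), norm2, labels)
#> <correlation_assignment> 3 types x 3 clusters over 150 shared genes
#> # A tibble: 3 × 5
#>   type  cluster     r runner_up runner_up_r
#>   <chr> <chr>   <dbl> <chr>           <dbl>
#> 1 type1 1       0.999 2               0.767
#> 2 type2 2       0.998 3               0.761
#> 3 type3 3       1.000 2               0.773
```

The 33 removed cells are exactly the planted contaminated/hemocyte cells
(the generator constructs them to clear the gating thresholds with margin),
and every bulk type matches its true cluster with r ≈ 1 while off-target
correlations sit near 0.77.

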