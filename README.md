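# scabatlas

Single-cell 3D genome analysis across the lifespan.

Single-cell chromosome-conformation assays (Dip-C and its population-scale
variant Pop-C) measure, cell by cell, which genomic loci touch in the
nucleus. Applied across donors of many ages, they reveal that some neurons
— cerebellar granule cells most dramatically — keep remodeling their 3D
genome for an entire lifetime: ultra-long-range (10–100 Mb)
intra-chromosomal contacts accumulate, chromatin A/B compartments
strengthen into checkerboard contact patterns, and specific
inter-chromosomal contacts form multi-chromosome hubs. `scabatlas` is an R
toolkit for this style of analysis, aimed at computational biologists
working with single-cell contact (`.pairs`) data:

* **scA/B** — per-cell, per-1-Mb-bin single-cell chromatin A/B compartment
  scores. For bin *i*, scA/B(*i*) is the mean reference CpG density of the
  partner bins over all contacts with exactly one end in *i* (intra
  contacts ≥ 1 Mb plus all inter contacts): A-compartment bins contact
  CpG-rich partners and score high.
* **Structure typing and staging** — Ward hierarchical clustering of the
  z-scored cells × bins scA/B matrix into structure types; granule cells
  are staged into five lifespan stages S1–S5 ordered by mean donor age,
  with per-age stage-abundance curves and peak ages.
* **Contact statistics** — distance-decay histograms; the fraction of
  intra-chromosomal contacts ≥ 10 Mb; aggregated 250-kb contact maps with
  iterative coverage normalization and log2 relative-change maps.
* **Inter-chromosomal hubs** — observed/expected enrichment per chromosome
  pair (marginal- or length-based expectation) and detection of
  multi-chromosome hubs as maximal cliques of pairs whose enrichment grows
  monotonically across stages.
* **scA/B dynamics** — per-stage region means, the top-20% most dynamic
  regions by between-stage variance, two temporal modes (up/down), and
  marker-gene locus trajectories.
* **Pop-C demultiplexing** — sex assignment from the X:A contact-density
  ratio, donor assignment from known SNP genotypes with doublet scoring,
  and genotype-free binomial-mixture EM clustering.
* **Synthetic data** — a calibrated generator that plants all of the above
  (distance mixtures per structure type, compartment checkerboards,
  cell-type profiles, lifespan-dynamic regions, hubs, sex differences,
  pooled-donor allele observations) with known truth, so every stage of
  the pipeline is testable without sequencing data. The preset library is
  calibrated to published per-type ultra-long-range fractions (e.g. human
  granule S1 19% → S5 33%, mouse 19% → 34%, microglia 34%, mouse Purkinje
  10%, human forebrain 16%).

## Worked example

Simulate a five-stage granule-cell cohort, compute scA/B, stage the cells,
and inspect the lifespan statistics:

```r
library(scabatlas)

genome <- make_synthetic_genome(seed = 1)    # 6 chrom x 80 Mb, 5-Mb A/B blocks
lib    <- preset_library()
design <- lapply(paste0("human_granule_S", 1:5), function(nm)
  list(preset = lib[[nm]], n_cells = 20))
cells  <- simulate_cohort(genome, design, n_contacts = 50000, seed = 7)

# ultra-long-range (>=10 Mb) intra-contact fraction per stage, %
frac <- sapply(cells, fraction_long_range)
type <- sapply(cells, function(ce) ce$meta$structure_type)
round(100 * tapply(frac, type, mean), 1)
#> human_granule_S1 human_granule_S2 human_granule_S3 human_granule_S4
#>             19.0             22.5             26.0             29.4
#> human_granule_S5
#>             33.0

mat <- build_scab_matrix(cells, genome$cpg_track)
st  <- stage_granule_cells(mat, k = 5)
table(truth = mat$meta$structure_type, stage = st$stage)
#>                   stage
#> truth              S1 S2 S3 S4 S5
#>   human_granule_S1 20  0  0  0  0
#>   human_granule_S2  0 20  0  0  0
#>   human_granule_S3  0  0 20  0  0
#>   human_granule_S4  0  0  0 20  0
#>   human_granule_S5  0  0  0  0 20

stage_abundance(st$stage, mat$meta$age)$peaks   # peak age per stage (years)
#>   S1   S2   S3   S4   S5
#>  0.2  1.0 10.0 30.0 80.0

sm    <- stage_mean_scab(mat, st$stage)
dyn   <- select_dynamic_regions(sm)             # top 20% by between-stage variance
modes <- temporal_modes(sm, dyn$selected)
c(regions = length(dyn$selected), table(modes))
#> regions      up    down
#>      80      33      47
```

The stage-wise ≥ 10 Mb fractions rise from 19% to 33% across S1→S5,
staging recovers the generating presets exactly, the stage-abundance peaks
sit at the planted donor ages (0.2, 1, 10, 30, 80 years), and the
dynamic-region filter returns exactly 20% of the 400 autosomal 1-Mb
regions, split into rising and falling temporal modes.

The whole pipeline (including demultiplexing, when pooled input is used)
can also be driven by one call: `run_atlas(atlas_config())` writes the
statistics tables plus a JSON manifest of every seed and parameter, and
reruns are byte-identical.

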