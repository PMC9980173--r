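---
title: "Methods: single-cell 3D genome analysis across the lifespan"
author: "scabatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell 3D genome analysis across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scabatlas)
```

# Overview

`scabatlas` implements the computational core of a single-cell 3D genome
(Dip-C style) lifespan analysis: per-cell chromatin A/B compartment scores
(scA/B) on a 1-Mb grid, hierarchical structure typing and five-stage
granule-cell staging, ultra-long-range contact statistics, aggregated and
relative-change contact maps, inter-chromosomal enrichment with
multi-chromosome hub detection, stage-resolved scA/B trajectories, and
demultiplexing of pooled donors. A calibrated synthetic contact generator
plants every piece of structure the pipeline estimates, so the whole
analysis is testable end to end without sequencing data.

This vignette is the package's methods account: the models, the tunable
parameters and their defaults, what the generator emulates and what it does
not, and the numerical choices made where the design was open.

# The scA/B model

A single cell's Hi-C data is a set of contacts, each a pair of genomic
positions. Chromatin segregates spatially into an active, gene-dense,
CpG-rich A compartment and an inactive, CpG-poor B compartment; in
contact maps this appears as a checkerboard at multi-megabase scale. The
single-cell compartment value of a 1-Mb bin is defined here contact-wise:

> scA/B(i) = mean CpG density of the partner bins of all qualifying
> contacts with exactly one end in bin i,

where qualifying contacts are all inter-chromosomal contacts plus intra
contacts spanning at least `min_distance` (default 1 Mb — shorter-range
ligation products sample the linear neighbourhood rather than the spatial
compartment). A bin needs `min_contacts_per_bin` partners (default 5) to be
scored; cells need `min_contacts` total contacts (default 5,000) to enter
the matrix. A-compartment bins contact CpG-rich partners and score high; B
bins score low. This contact-partner formulation avoids 3D structure
reconstruction entirely; it is validated against an exhaustive
partner-averaging oracle and by recovery of the generator's planted
compartments (median per-cell correlation above 0.9 at 50,000 contacts per
cell, the suite's study size).

The cells-by-bins matrix is restricted to autosomes (sex chromosomes would
cluster cells by donor sex, not by chromatin state), z-scored per cell over
observed bins, and missing entries are imputed with the post-normalization
mean (0) for embedding only, with the imputation mask retained.

# Structure typing and staging

3D genome structure types are identified by agglomerative hierarchical
clustering (Ward linkage, Euclidean distance) of the z-scored scA/B rows,
on the 50% most variable bins — variance filtering stabilizes
high-dimensional distances. Clustering is deterministic and invariant to
cell order. Granule cells are staged into k = 5 lifespan stages S1–S5 the
same way; clusters are then ordered by ascending mean donor age (the
stages are lifespan-ordered by definition), with mean PC1 as the fallback
when ages are missing. Embeddings (PCA always; t-SNE with perplexity 30 or
UMAP on the top 20 PCs, fixed seed) are for visualization; no decision
depends on them. Stage-abundance curves are per-age stage fractions; the
peak age of a stage is the argmax over the age grid.

With cohorts of 20 or more cells per stage at 50,000 contacts per cell,
staging recovers the generating presets essentially perfectly; at very
small cohort sizes (under ~10 cells per stage) single outlier cells can
split a weak-compartment early-stage cluster, which is a known
instability of Ward clustering at small n, not of the scA/B signal.

# Contact distance statistics

All intra-chromosomal statistics exclude distances below 10 kb
(self-ligation artifacts). The ultra-long-range fraction of a cell is the
share of intra contacts at or beyond 10 Mb (inclusive boundary). Distance
histograms use log10-spaced bins. Aggregated contact maps sum binned
contacts over a cell group (250-kb bins by default in the pipeline);
coverage normalization is 10 rounds of iterative marginal scaling toward
unit row/column sums — full matrix balancing is deliberately avoided
because aggregated single-cell maps are sparse. Because the scaling also
fixes the overall scale, relative-change maps
`log2((late + p) / (early + p))` (pseudocount p = 1e-6 of the matrix mean)
of proportional maps are exactly zero.

# Inter-chromosomal enrichment and hubs

Enrichment is observed / expected over inter-chromosomal contacts only,
intra pixels masked, at chromosome level or on large bins (5–6 Mb). Two
expectation models are provided:

* **marginal** (default): product of observed inter-contact marginals,
  renormalized so the expected total over inter pixels equals the observed
  total. This corrects per-chromosome coverage differences and makes the
  uniform null read exactly 1. Its known limitation: a strong planted hub
  inflates its chromosomes' marginals, so the hub reads back compressed,
  and on a small genome where the hub spans half the chromosomes the
  compositional effect can even invert the signal.
* **length**: chromosome-length product weights — the uniform-density
  null. A planted pair multiplier is recovered exactly as the ratio of the
  hub-pair enrichment to the non-hub baseline (the absolute value is
  compressed by total-renormalization: a 3x weight on one of 15 pairs
  yields 3 x 15/17).

Hub detection takes stage-ordered enrichment matrices and reports maximal
cliques (via `igraph`) of chromosome pairs whose enrichment increases
monotonically with total gain at least `gain_threshold` (default 0.5);
monotonically decreasing pairs are reported separately as weakening. On
the 6-chromosome toy genome the length model should be used for detection,
for the compositional reason above.

# scA/B dynamics

Stage means are per-bin means over the cells of each stage, missing
entries ignored, stages equally weighted regardless of cell counts. The
between-stage variance of a region is the population variance of its stage
means (mirroring a "between-stage" rather than sampling-variance reading);
the top 20% of regions by this variance are the dynamic regions, ties
broken by region ordinal, count exactly `floor(0.20 R)`. Their
trajectories are clustered on correlation distance (average linkage) into
k = 2 temporal modes, named "up"/"down" by the sign of the mean
last-minus-first difference. Gene sets (BED input) map to 1-Mb bins by
gene-body midpoint; the aggregated trajectory is the mean over gene bins,
with the fraction of rising regions reported as a monotonicity statistic.

# Demultiplexing pooled donors

Sex is called from the X:A ratio — contact-endpoint density on X over
autosomes — with a 0.75 boundary, the midpoint between the expected 0.5
(XY) and 1.0 (XX). Donor assignment with known genotypes maximizes the
per-donor log-likelihood in which each observed allele is alt with
probability `(dosage/2)(1-e) + (1-dosage/2)e`, allele error e = 0.01. All
50/50 two-donor mixtures are scored as doublet models; a cell is called a
doublet when the best pair beats the best single donor by more than
`doublet_margin` = 2 log-units (the demuxlet-style convention), and
ambiguous when the top two donors are within 2 log-units. Genotype-free
clustering is a binomial-mixture EM over per-cluster SNP alt fractions
with Beta(1,1) smoothing, best of 5 seeded restarts; the observed-data
log-likelihood is non-decreasing by construction and asserted in the
tests. Ambient contamination and unequal doublet mixtures are not
modeled.

# The synthetic generator

The generator's role is to plant, with known ground truth, exactly the
statistical structure the pipeline estimates:

* **Genome**: 6 chromosomes x 80 Mb (the last an X), alternating 5-Mb A/B
  blocks; CpG density per 1-Mb bin drawn from N(0.012, 0.0015) for A and
  N(0.006, 0.0015) for B, clamped positive — so the scA/B reference
  correlates with the planted compartments by construction.
* **Distance mixture**: each intra contact is ultra-long-range with
  probability `w_long` — log-uniform on [10 Mb, min(100 Mb, 0.9 L)] — and
  otherwise short-range from a truncated power law `s^-1.5` on
  [10 kb, 10 Mb). Sampled distances are clamped into their component's
  support after rounding, so the >=10 Mb fraction is exactly
  Bernoulli(`w_long`) per contact; the published per-type fractions are
  therefore reproduced to binomial precision. The 1.5 exponent is a
  generic polymer-like decay choice.
* **Preset library**: `w_long` values are the published per-type means
  (human granule S1/S5 0.19/0.33, mouse granule 0.19/0.34, human forebrain
  0.15/0.16, mouse forebrain 0.11/0.13, mouse Purkinje 0.09/0.10,
  microglia 0.34, oligodendrocytes 0.29/0.27); granule S2–S4 are linear
  interpolations, since only the monotone trend and the endpoints are
  established.
* **Compartment structure**: long-range and inter-chromosomal contacts
  accept same-compartment endpoint pairs with odds `checker_strength`
  (resampling positions, never distances; retry cap 100). Checker odds
  grow monotonically S1 to S5 (2.0 to 4.4), emulating the weak,
  domain-dominant neuronal structure maturing into a strong,
  compartment-dominant one.
* **Cell types and lifespan dynamics**: compartments flip in whole 5-Mb
  blocks. Each cell type flips its own deterministic 5% of blocks relative
  to the baseline, giving types distinct scA/B profiles; 8% of autosomal
  blocks are dynamic regions with a per-block maturity threshold in
  (0.05, 0.95) — when a preset's maturity (0 at birth, 1 aged) passes the
  threshold the block flips, B-origin blocks up to A and A-origin blocks
  down. These fractions are deliberately modest: the CpG reference is a
  static DNA property, so every flipped block dilutes the partner-pool
  contrast that scA/B measures; keeping the flipped minority small mirrors
  real data, where genome-wide CpG–compartment correlation stays high
  because only a minority of the genome switches compartment across life.
* **Hubs, sex, pools**: granule presets carry a chr1/chr3/chr5
  inter-chromosomal hub whose weight multiplier grows across stages; males
  have X contact density halved (single X vs diploid autosomes); pooled
  cells draw Poisson-many SNP observations from Hardy–Weinberg donor
  genotypes with symmetric allele error, doublets mixing two donors 50/50.

What the generator does **not** emulate: TADs and loops, cell-cycle and
replication structure, biological within-stage overdispersion (per-type
spread beyond sampling noise), coverage bias along chromosomes, and
read-level artifacts. Passing tests therefore demonstrate the estimators'
correctness and calibration on planted structure, not robustness to every
property of real libraries.

# Numerical and reproducibility choices

Study sizes in the suite were chosen to exercise the published summary
statistics at realistic scale while staying lightweight: calibration
cohorts of 100 cells x 50,000 contacts, staging cohorts of 200–250 cells,
demultiplexing pools of 8 donors x 200 SNP observations per cell. All
randomness flows from explicit seeds; cohorts give each cell an
independent substream seed drawn from the master seed, so any cell is
reproducible in isolation. Pairs-file positions are 1-based on disk and
converted to 0-based half-open bins only at the I/O boundary; CG
dinucleotides straddling a bin boundary credit the bin of their first
base; duplicate contacts are kept as-is. `run_atlas()` writes a JSON
manifest of every parameter and seed, and reruns of one configuration are
byte-identical.

# Known limitations

Stage separability depends on the genome draw: the dynamic blocks'
maturity thresholds are uniform, so an unlucky genome seed can leave an
adjacent-stage interval without any flipping block, weakening that stage
boundary; the default genome is verified to separate all five stages.
The scA/B formulation is contact-based; a 3D-neighbourhood variant from
reconstructed structures could differ at bins dominated by very sparse
long-range coverage. Stage ordering relies on donor ages; in their absence
PC1 ordering assumes the dominant variance axis is the lifespan axis. The
marginal enrichment model under-reports hubs that span a large share of
the genome (use the length model, or interpret ratios). The demultiplexer
assumes biallelic SNPs, independent sites, and exact 50/50 doublets.
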