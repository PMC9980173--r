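# Shared fixtures and independent oracles used across the suite.

# small two-chromosome assembly for I/O and binning tests
tiny_assembly <- function() {
  assembly(c("chr1", "chrX"), c(1e6, 5e5))
}

# default synthetic genome, built once per test run
the_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_synthetic_genome()
    g
  }
})

# random contacts on an assembly, as a data.table
random_contacts <- function(asm, n, seed) {
  set.seed(seed)
  ch_a <- sample(asm$chrom_names, n, replace = TRUE)
  ch_b <- sample(asm$chrom_names, n, replace = TRUE)
  data.table::data.table(
    chrom_a = ch_a,
    pos_a = vapply(ch_a, function(ch) sample.int(asm$chrom_lengths[[ch]], 1),
                   numeric(1)),
    chrom_b = ch_b,
    pos_b = vapply(ch_b, function(ch) sample.int(asm$chrom_lengths[[ch]], 1),
                   numeric(1)))
}

# brute-force scA/B oracle: loop over contacts, accumulate partner values
scab_oracle <- function(cell, reference, min_distance = 1e6,
                        min_contacts_per_bin = 5) {
  bi <- reference$bin_index
  sums <- numeric(n_bins(bi))
  counts <- integer(n_bins(bi))
  dt <- cell$contacts
  for (r in seq_len(nrow(dt))) {
    if (dt$is_intra[r] && dt$distance[r] < min_distance) next
    ba <- locate_bin(bi, dt$chrom_a[r], dt$pos_a[r])
    bb <- locate_bin(bi, dt$chrom_b[r], dt$pos_b[r])
    if (ba == bb) next
    sums[ba] <- sums[ba] + reference$values[bb]
    counts[ba] <- counts[ba] + 1L
    sums[bb] <- sums[bb] + reference$values[ba]
    counts[bb] <- counts[bb] + 1L
  }
  out <- ifelse(counts >= min_contacts_per_bin, sums / counts, NA_real_)
  out
}

# brute-force CG-dinucleotide counter on a character sequence (1-based,
# inclusive window; counts CG whose first base lies in the window)
cg_count_oracle <- function(seq_chars, from, to) {
  n <- 0L
  upto <- min(to, length(seq_chars) - 1L)
  for (i in from:upto) {
    if (toupper(seq_chars[i]) == "C" && toupper(seq_chars[i + 1]) == "G")
      n <- n + 1L
  }
  n
}

# per-read enumeration oracle for genotype log-likelihood
genotype_ll_oracle <- function(obs, dosages, eps) {
  ll <- 0
  for (r in seq_len(nrow(obs))) {
    g <- dosages[[obs$snp_id[r]]]
    p <- (g / 2) * (1 - eps) + (1 - g / 2) * eps
    for (k in seq_len(obs$alt_count[r])) ll <- ll + log(p)
    for (k in seq_len(obs$ref_count[r])) ll <- ll + log(1 - p)
  }
  ll
}

# mean >=10 Mb fraction over a simulated cohort of one preset
cohort_mean_fraction <- function(preset, n_cells, n_contacts, seed,
                                 genome = the_genome()) {
  p <- preset
  p$inter_frac <- 0
  class(p) <- class(preset)
  cells <- simulate_cohort(genome,
                           list(list(preset = p, n_cells = n_cells)),
                           n_contacts, seed = seed)
  mean(vapply(cells, fraction_long_range, numeric(1)))
}

# adjusted Rand index (independent implementation for cluster agreement)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
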