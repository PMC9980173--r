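test_that("distance histograms bin by decade and conserve totals", {
  asm <- assembly("c1", 2e8, sex_chroms = character())
  ce <- cell_contacts("c", data.frame(
    chrom_a = "c1", pos_a = c(1, 1, 1),
    chrom_b = "c1", pos_b = c(1 + 1e5, 1 + 1e6, 1 + 1e7)), asm)
  h <- distance_histogram(ce, n_log_bins = 3)
  expect_equal(h$counts, c(1, 1, 1))
  expect_equal(sum(h$counts), h$total)
  # floor: sub-10-kb contacts are excluded
  ce2 <- cell_contacts("c", data.frame(
    chrom_a = "c1", pos_a = c(1, 1), chrom_b = "c1",
    pos_b = c(500, 1 + 2e4)), asm)
  expect_equal(distance_histogram(ce2, n_log_bins = 2)$total, 1L)
  inter_only <- cell_contacts("c", data.frame(
    chrom_a = "chr1", pos_a = 1, chrom_b = "chrX", pos_b = 1),
    tiny_assembly())
  expect_error(distance_histogram(inter_only), "no intra")
})

test_that("mature-stage histograms shift mass into the 10-100 Mb window", {
  g <- the_genome()
  lib <- preset_library()
  mass_long <- function(preset, seed) {
    cells <- lapply(1:3, function(i)
      simulate_cell(g, preset, 20e3, seed = seed + i))
    h <- distance_histogram(cells, n_log_bins = 24)
    mids <- sqrt(h$edges[-1] * h$edges[-length(h$edges)])
    sum(h$counts[mids >= 1e7]) / h$total
  }
  expect_gt(mass_long(lib$human_granule_S5, 100),
            mass_long(lib$human_granule_S1, 200))
})

test_that("fraction_long_range follows its definition and flags edge cases", {
  asm <- assembly("c1", 2e8, sex_chroms = character())
  ce <- cell_contacts("c", data.frame(
    chrom_a = "c1", pos_a = c(1, 1), chrom_b = "c1",
    pos_b = c(1 + 5e6, 1 + 1.5e7)), asm)
  expect_equal(fraction_long_range(ce), 0.5)
  # inclusive boundary: exactly 10 Mb counts as long
  ce_b <- cell_contacts("c", data.frame(
    chrom_a = "c1", pos_a = 1, chrom_b = "c1", pos_b = 1 + 1e7), asm)
  expect_equal(fraction_long_range(ce_b), 1)
  inter_only <- cell_contacts("c", data.frame(
    chrom_a = "chr1", pos_a = 1, chrom_b = "chrX", pos_b = 1),
    tiny_assembly())
  expect_warning(expect_true(is.na(fraction_long_range(inter_only))),
                 "fraction undefined")
})

test_that("aggregate maps are symmetric, linear and conserve totals", {
  asm <- assembly(c("c1", "c2"), c(4e6, 4e6), sex_chroms = character())
  bi <- make_bins(asm, 1e6)
  ce1 <- cell_contacts("a", data.frame(chrom_a = "c1", pos_a = 5e5,
                                       chrom_b = "c1", pos_b = 2.5e6), asm)
  m1 <- aggregate_map(ce1, bi)
  expect_equal(m1$matrix[1, 3], 1)
  expect_equal(m1$matrix[3, 1], 1)
  expect_equal(sum(m1$matrix), 2)    # one off-diagonal contact counted twice
  expect_equal(m1$total, 1)
  # diagonal contact lands once
  ced <- cell_contacts("d", data.frame(chrom_a = "c1", pos_a = 1,
                                       chrom_b = "c1", pos_b = 2), asm)
  expect_equal(sum(aggregate_map(ced, bi)$matrix), 1)
  # linearity: cohort map = sum of per-cell maps
  ce2 <- cell_contacts("b", random_contacts(asm, 200, seed = 8), asm)
  mc <- aggregate_map(list(ce1, ce2), bi)
  expect_equal(mc$matrix, m1$matrix + aggregate_map(ce2, bi)$matrix)
  expect_true(isSymmetric(mc$matrix))
})

test_that("relative-change maps cancel identical and proportional maps", {
  asm <- assembly("c1", 6e6, sex_chroms = character())
  bi <- make_bins(asm, 1e6)
  ce <- cell_contacts("a", random_contacts(asm, 400, seed = 12), asm)
  m <- aggregate_map(ce, bi, normalize = TRUE)
  expect_equal(relative_change_map(m, m), matrix(0, 6, 6))
  # doubled contacts normalize away
  dt2 <- rbind(ce$contacts[, 1:4], ce$contacts[, 1:4])
  ce2 <- cell_contacts("b", dt2, asm)
  m2 <- aggregate_map(ce2, bi, normalize = TRUE)
  expect_lt(max(abs(relative_change_map(m2, m))), 1e-6)
  bi2 <- make_bins(asm, 2e6)
  expect_error(relative_change_map(m, aggregate_map(ce, bi2)),
               "grid mismatch")
})

test_that("mature vs immature synthetic maps strengthen same-compartment pixels", {
  g <- the_genome()
  lib <- preset_library()
  bi <- g$bin_index
  stage_map <- function(preset, seed) {
    cells <- lapply(1:4, function(i)
      simulate_cell(g, preset, 25e3, seed = seed + i))
    aggregate_map(cells, bi, normalize = TRUE)
  }
  m1 <- stage_map(lib$human_granule_S1, 300)
  m5 <- stage_map(lib$human_granule_S5, 400)
  rc <- relative_change_map(m5, m1)
  # restrict to >=10 Mb intra pixels of chr1; compare same- vs
  # cross-compartment pixels under the S5 effective profile
  es <- compartment_profile(g, lib$human_granule_S5)
  idx <- which(bi$bins$chrom == "chr1")
  pix <- expand.grid(i = idx, j = idx)
  pix <- pix[abs(pix$i - pix$j) >= 10, ]
  same <- es[pix$i] == es[pix$j]
  expect_gt(median(rc[cbind(pix$i, pix$j)][same]),
            median(rc[cbind(pix$i, pix$j)][!same]))
})

test_that("inter-chromosomal enrichment is calibrated and conserves counts", {
  g <- the_genome()
  null_p <- stage_preset("null", 0.2, checker_strength = 1, inter_frac = 0.5)
  cells <- lapply(1:6, function(i) simulate_cell(g, null_p, 20e3, seed = i))
  en <- interchrom_enrichment(cells)
  # conservation: observed upper-triangle total = inter contacts
  expect_equal(sum(en$observed[upper.tri(en$observed)], na.rm = TRUE),
               en$total)
  # uniform null: every pair within 3 binomial s.e. of 1
  n_pair <- en$observed[upper.tri(en$observed)]
  e_pair <- en$expected[upper.tri(en$expected)]
  ok <- !is.na(n_pair)
  z <- (n_pair[ok] - e_pair[ok]) / sqrt(e_pair[ok])
  expect_true(all(abs(z) < 3.5))
  expect_true(all(abs(en$enrichment - 1) < 0.1, na.rm = TRUE))
  intra_only <- simulate_cell(g, stage_preset("i", 0.2, inter_frac = 0), 100,
                              seed = 3)
  expect_error(interchrom_enrichment(intra_only), "no inter")
})

test_that("a planted hub pair reads back at its multiplier over baseline", {
  g <- the_genome()
  hub_p <- stage_preset("hub", 0.2, checker_strength = 1, inter_frac = 0.5,
                        hub = list(chroms = c("chr1", "chr3"),
                                   multiplier = 3))
  cells <- lapply(1:6, function(i) simulate_cell(g, hub_p, 20e3, seed = 50 + i))
  eh <- interchrom_enrichment(cells, expected_model = "length")
  base <- eh$enrichment["chr2", "chr4"]
  ratio <- eh$enrichment["chr1", "chr3"] / base
  n_hub <- eh$observed["chr1", "chr3"]
  se <- ratio / sqrt(n_hub)
  expect_lt(abs(ratio - 3), 3 * se + 0.1)
})

test_that("hub detection finds planted growing cliques and weakening pairs", {
  g <- the_genome()
  lib <- preset_library()
  enr <- lapply(paste0("human_granule_S", c(1, 3, 5)), function(n) {
    p <- lib[[n]]
    p$inter_frac <- 0.3
    class(p) <- "stage_preset"
    cells <- lapply(1:6, function(i)
      simulate_cell(g, p, 20e3, seed = i * 7 + nchar(n)))
    interchrom_enrichment(cells, expected_model = "length")
  })
  res <- detect_hub(enr, gain_threshold = 0.3)
  expect_true(any(vapply(res$hubs, identical, logical(1),
                         c("chr1", "chr3", "chr5"))))
  # pairs losing enrichment appear in the weakening list, not the hub
  weak_pairs <- paste(res$weakening$chrom_a, res$weakening$chrom_b)
  expect_false(any(grepl("chr1 chr3", weak_pairs)))
  expect_gt(nrow(res$weakening), 0)
  # no planted hub: no strengthening clique at the same threshold
  en0 <- lapply(1:2, function(k) {
    p0 <- stage_preset("p", 0.2, checker_strength = 1, inter_frac = 0.4)
    cells <- lapply(1:4, function(i)
      simulate_cell(g, p0, 15e3, seed = 900 + 10 * k + i))
    interchrom_enrichment(cells, expected_model = "length")
  })
  expect_length(detect_hub(en0, gain_threshold = 0.3)$hubs, 0)
  expect_error(detect_hub(en0[1]), "at least 2 stages")
})
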