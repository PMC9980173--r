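test_that("synthetic genome plants alternating blocks with CpG-correlated signs", {
  g <- make_synthetic_genome(n_chroms = 2, chrom_length = 100e6,
                             block_size = 5e6, seed = 3)
  expect_equal(n_bins(g$bin_index), 200L)
  signs <- g$compartment_sign[1:100]
  blocks <- matrix(signs, nrow = 5)      # 20 blocks of 5 bins on chr1
  expect_true(all(apply(blocks, 2, function(b) length(unique(b)) == 1)))
  expect_equal(blocks[1, ], rep(c(1, -1), 10))   # signs alternate
  expect_true(cor(g$cpg_track$values, g$compartment_sign) > 0)
})

test_that("single-block chromosomes and determinism behave as declared", {
  g1 <- make_synthetic_genome(n_chroms = 2, chrom_length = 20e6,
                              block_size = 20e6, seed = 5)
  per_chrom <- split(g1$compartment_sign, g1$bin_index$bins$chrom)
  expect_true(all(vapply(per_chrom, function(s) length(unique(s)) == 1,
                         logical(1))))
  g2 <- make_synthetic_genome(seed = 11)
  g3 <- make_synthetic_genome(seed = 11)
  expect_identical(g2$compartment_sign, g3$compartment_sign)
  expect_identical(g2$cpg_track$values, g3$cpg_track$values)
  expect_identical(g2$dynamic_bins, g3$dynamic_bins)
  expect_error(make_synthetic_genome(block_size = 200e6),
               "block_size exceeds")
})

test_that("degenerate mixtures produce the declared distance supports", {
  g <- the_genome()
  p_long <- stage_preset("all_long", w_long = 1, inter_frac = 0)
  ce <- simulate_cell(g, p_long, 2000, seed = 1)
  expect_true(all(ce$contacts$is_intra))
  expect_true(all(ce$contacts$distance >= 1e7))
  expect_true(all(ce$contacts$distance <= 1e8))

  p_short <- stage_preset("all_short", w_long = 0, inter_frac = 0)
  cs <- simulate_cell(g, p_short, 2000, seed = 2)
  expect_true(all(cs$contacts$distance >= 1e4))
  expect_true(all(cs$contacts$distance < 1e7))

  tiny <- make_synthetic_genome(n_chroms = 2, chrom_length = 8e6,
                                block_size = 1e6)
  expect_error(simulate_cell(tiny, p_long, 10, seed = 1),
               "no long-range support")
})

test_that("long-range fraction is binomial-calibrated at w_long", {
  g <- the_genome()
  p <- stage_preset("cal", w_long = 0.33, inter_frac = 0)
  ce <- simulate_cell(g, p, 50e3, seed = 9)
  frac <- fraction_long_range(ce)
  se <- sqrt(0.33 * 0.67 / 50e3)
  expect_lt(abs(frac - 0.33), 3 * se)
})

test_that("male cells have half the female X contact density", {
  g <- the_genome()
  pf <- stage_preset("f", w_long = 0.2, sex = "female")
  pm <- stage_preset("m", w_long = 0.2, sex = "male")
  rf <- mean(vapply(1:5, function(i)
    xa_ratio(simulate_cell(g, pf, 20e3, seed = i)), numeric(1)))
  rm_ <- mean(vapply(1:5, function(i)
    xa_ratio(simulate_cell(g, pm, 20e3, seed = 100 + i)), numeric(1)))
  expect_lt(abs(rf - 1), 0.1)
  expect_lt(abs(rm_ / rf - 0.5), 0.1)
})

test_that("checkerboard bias yields the planted same-compartment odds", {
  # two-block genome: for an ultra-long contact of distance d on an L-bp
  # chromosome, the uniform-start probability that both ends share a
  # compartment is p(d) = 2 max(0, L/2 - d) / (L - d) in closed form, so
  # the acceptance rule predicts a same-compartment rate of
  # cs p / (cs p + 1 - p) per contact
  g2 <- make_synthetic_genome(n_chroms = 3, chrom_length = 80e6,
                              block_size = 40e6, dynamic_frac = 0,
                              type_flip_frac = 0)
  cs <- 3
  p_b <- stage_preset("biased", w_long = 1, inter_frac = 0,
                      checker_strength = cs)
  ce <- simulate_cell(g2, p_b, 40e3, seed = 21)
  es <- compartment_profile(g2, p_b)
  ba <- locate_bin(g2$bin_index, ce$contacts$chrom_a, ce$contacts$pos_a)
  bb <- locate_bin(g2$bin_index, ce$contacts$chrom_b, ce$contacts$pos_b)
  same <- es[ba] == es[bb]
  d <- ce$contacts$distance
  p <- 2 * pmax(0, 40e6 - d) / (80e6 - d)
  s_exp <- cs * p / (cs * p + 1 - p)
  se <- sqrt(sum(s_exp * (1 - s_exp))) / length(d)
  expect_lt(abs(mean(same) - mean(s_exp)), 3 * se + 1e-3)
})

test_that("preset library carries the reported long-range fractions", {
  lib <- preset_library()
  expect_equal(lib$human_granule_S1$w_long, 0.19)
  expect_equal(lib$human_granule_S5$w_long, 0.33)
  expect_equal(lib$mouse_granule_S1$w_long, 0.19)
  expect_equal(lib$mouse_granule_S5$w_long, 0.34)
  expect_equal(lib$human_forebrain_birth$w_long, 0.15)
  expect_equal(lib$human_forebrain_mature$w_long, 0.16)
  expect_equal(lib$mouse_forebrain_birth$w_long, 0.11)
  expect_equal(lib$mouse_forebrain_mature$w_long, 0.13)
  expect_equal(lib$mouse_purkinje_birth$w_long, 0.09)
  expect_equal(lib$mouse_purkinje_mature$w_long, 0.10)
  expect_equal(lib$microglia$w_long, 0.34)
  expect_equal(lib$oligodendrocyte_human$w_long, 0.29)
  expect_equal(lib$oligodendrocyte_mouse$w_long, 0.27)
  # interpolated intermediates are monotone, as are checker strengths
  hs <- vapply(paste0("human_granule_S", 1:5),
               function(n) lib[[n]]$w_long, numeric(1))
  expect_true(all(diff(hs) > 0))
  cs <- vapply(paste0("human_granule_S", 1:5),
               function(n) lib[[n]]$checker_strength, numeric(1))
  expect_true(all(diff(cs) > 0))
  # every preset satisfies its invariants via the constructor
  expect_true(all(vapply(lib, inherits, logical(1), "stage_preset")))
})

test_that("cohorts are reproducible and carry balanced truth labels", {
  g <- the_genome()
  lib <- preset_library()
  design <- lapply(paste0("human_granule_S", 1:5), function(n)
    list(preset = lib[[n]], n_cells = 4))
  co1 <- simulate_cohort(g, design, 2000, seed = 31)
  co2 <- simulate_cohort(g, design, 2000, seed = 31)
  expect_equal(length(co1), 20L)
  types <- vapply(co1, function(ce) ce$meta$structure_type, character(1))
  expect_true(all(table(types) == 4))
  expect_identical(lapply(co1, function(ce) ce$contacts),
                   lapply(co2, function(ce) ce$contacts))
  expect_error(simulate_cohort(g, list(), 100, seed = 1), "empty design")
})

test_that("cohort long-range fractions are ordered by preset w_long", {
  g <- the_genome()
  lib <- preset_library()
  means <- vapply(paste0("human_granule_S", 1:5), function(n)
    cohort_mean_fraction(lib[[n]], n_cells = 5, n_contacts = 20e3,
                         seed = 17, genome = g), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("pool simulation respects genotypes, errors and doublets", {
  gt <- make_genotypes(2, 50, seed = 1)
  # zero error: observed alt fraction matches dosage exactly at hom sites
  pd0 <- pool_design(gt, cells_per_donor = 3, doublet_rate = 0,
                     allele_error_rate = 0, snp_obs_per_cell = 400)
  pool0 <- simulate_pool(pd0, seed = 2)
  obs <- pool0$obs
  for (cid in pool0$truth$cell_id) {
    d <- pool0$truth$donor[pool0$truth$cell_id == cid]
    o <- obs[obs$cell_id == cid]
    dos <- gt$dosage[d, o$snp_id]
    expect_true(all(o$alt_count[dos == 0] == 0))
    expect_true(all(o$ref_count[dos == 2] == 0))
  }
  # doublet_rate 1: everything is a doublet
  pd1 <- pool_design(gt, cells_per_donor = 3, doublet_rate = 1)
  pool1 <- simulate_pool(pd1, seed = 3)
  expect_true(all(pool1$truth$is_doublet))
  # error rate calibration at homozygous sites (binomial oracle)
  pde <- pool_design(gt, cells_per_donor = 40, doublet_rate = 0,
                     allele_error_rate = 0.01, snp_obs_per_cell = 200)
  poole <- simulate_pool(pde, seed = 4)
  oe <- poole$obs
  oe$donor <- poole$truth$donor[match(oe$cell_id, poole$truth$cell_id)]
  dos <- gt$dosage[cbind(oe$donor, oe$snp_id)]
  hom <- dos %in% c(0, 2)
  mism <- ifelse(dos[hom] == 0, oe$alt_count[hom], oe$ref_count[hom])
  tot <- oe$ref_count[hom] + oe$alt_count[hom]
  rate <- sum(mism) / sum(tot)
  se <- sqrt(0.01 * 0.99 / sum(tot))
  expect_lt(abs(rate - 0.01), 3 * se)
  # identical genotypes are flagged unidentifiable
  gt_dup <- gt
  gt_dup$dosage[2, ] <- gt_dup$dosage[1, ]
  expect_warning(simulate_pool(pool_design(gt_dup, cells_per_donor = 1),
                               seed = 5),
                 "unidentifiable")
})
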