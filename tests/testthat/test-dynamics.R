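# builds a small staged cohort once; reused across the dynamics tests
dynamics_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- the_genome()
    lib <- preset_library()
    design <- lapply(paste0("human_granule_S", 1:5), function(n)
      list(preset = lib[[n]], n_cells = 8))
    cells <- simulate_cohort(g, design, 30e3, seed = 57)
    m <- build_scab_matrix(cells, g$cpg_track)
    stage <- factor(sub("human_granule_", "", m$meta$structure_type))
    cache <<- list(genome = g, matrix = m, stage = stage,
                   means = stage_mean_scab(m, stage))
    cache
  }
})

test_that("stage means average cells within stages and flag empty stages", {
  fx <- dynamics_fixture()
  m <- fx$matrix
  sm <- fx$means
  expect_equal(dim(sm$values), c(ncol(m$values), 5L))
  # direct check on one stage/bin
  idx <- which(fx$stage == "S2")
  v <- m$values[idx, 1]
  v[!m$observed[idx, 1]] <- NA
  expect_equal(unname(sm$values[1, "S2"]), mean(v, na.rm = TRUE))
  # permuting cells within stages changes nothing
  perm <- sample(nrow(m$values))
  mp <- m
  mp$values <- m$values[perm, ]
  mp$observed <- m$observed[perm, ]
  expect_equal(stage_mean_scab(mp, fx$stage[perm])$values, sm$values)
  # an empty stage yields a missing column and a warning
  st2 <- factor(as.character(fx$stage), levels = c(levels(fx$stage), "S9"))
  expect_warning(sm2 <- stage_mean_scab(m, st2), "no cells")
  expect_true(all(is.na(sm2$values[, "S9"])))
  # planted A bins exceed planted B bins at every stage (S3 profile proxy)
  es <- compartment_profile(fx$genome,
                            preset_library()$human_granule_S3)[m$autosomal_bins]
  static <- setdiff(seq_along(es),
                    match(fx$genome$dynamic_bins, m$autosomal_bins))
  for (s in colnames(sm$values))
    expect_gt(mean(sm$values[static[es[static] > 0], s]),
              mean(sm$values[static[es[static] < 0], s]))
})

test_that("dynamic-region selection returns the exact top fraction", {
  fx <- dynamics_fixture()
  sel <- select_dynamic_regions(fx$means)
  expect_length(sel$selected, floor(0.2 * nrow(fx$means$values)))
  # 1,000 synthetic regions -> exactly 200
  fake <- fx$means
  fake$values <- matrix(rnorm(5000), 1000, 5)
  expect_length(select_dynamic_regions(fake)$selected, 200L)
  # hand-computed toy agrees with the brute-force variance oracle
  toy <- fx$means
  toy$values <- rbind(c(1, 1, 1, 1, 1),
                      c(0, 1, 2, 3, 4),
                      c(0, 0, 0, 0, 10))
  v <- select_dynamic_regions(toy, top_frac = 2 / 3)
  oracle <- apply(toy$values, 1, function(x) mean((x - mean(x))^2))
  expect_equal(unname(v$variance), unname(oracle))
  expect_equal(v$selected, sort(order(-oracle)[1:2]))
  # constant region is never selected while others vary
  expect_false(1L %in% v$selected)
  # selection is invariant to stage column order
  toy_perm <- toy
  toy_perm$values <- toy$values[, c(3, 1, 5, 2, 4)]
  expect_equal(select_dynamic_regions(toy_perm, top_frac = 2 / 3)$selected,
               v$selected)
  one_stage <- fx$means
  one_stage$values <- fx$means$values[, 1, drop = FALSE]
  expect_error(select_dynamic_regions(one_stage), "at least 2 stages")
})

test_that("planted dynamic regions are recovered and correctly signed", {
  fx <- dynamics_fixture()
  g <- fx$genome
  sel <- select_dynamic_regions(fx$means)
  planted <- match(g$dynamic_bins, fx$matrix$autosomal_bins)
  expect_gte(mean(planted %in% sel$selected), 0.95)
  modes <- temporal_modes(fx$means, sel$selected)
  sel_planted <- sel$selected[sel$selected %in% planted]
  dirs <- g$dynamic_direction[match(fx$matrix$autosomal_bins[sel_planted],
                                    g$dynamic_bins)]
  md <- modes[as.character(sel_planted)]
  agree <- (md == "up" & dirs == 1) | (md == "down" & dirs == -1)
  expect_gte(mean(agree), 0.95)
  expect_equal(adjusted_rand(md, dirs), 1.0)
})

test_that("temporal modes name monotone trajectories by direction", {
  fx <- dynamics_fixture()
  toy <- fx$means
  toy$values <- rbind(matrix(rep(c(0, 1, 2, 3, 4), 3), 3, byrow = TRUE),
                      matrix(rep(c(4, 3, 2, 1, 0), 3), 3, byrow = TRUE))
  toy$values <- toy$values + matrix(rnorm(30, sd = 0.01), 6)
  md <- temporal_modes(toy, 1:6)
  expect_equal(unname(md), rep(c("up", "down"), each = 3))
  expect_error(temporal_modes(toy, 1:6, k = 7), "fewer regions")
})

test_that("gene-set trajectories aggregate marker loci and rise with maturation", {
  fx <- dynamics_fixture()
  g <- fx$genome
  m <- fx$matrix
  # marker set: planted up-regions (B -> A flips), written through BED
  up_bins <- g$dynamic_bins[g$dynamic_direction == 1]
  bins <- g$bin_index$bins[up_bins]
  bed <- withr::local_tempfile(fileext = ".bed")
  data.table::fwrite(
    data.table::data.table(chrom = bins$chrom, start = bins$start,
                           end = bins$end,
                           name = sprintf("gene%02d", seq_len(nrow(bins)))),
    bed, sep = "\t", col.names = FALSE)
  genes <- read_bed(bed)
  tr <- gene_set_trajectory(fx$means, genes)
  expect_true(all(diff(tr$trajectory) > 0))
  expect_gt(tr$frac_increasing, 0.95)
  # a single-gene set returns that bin's own trajectory
  tr1 <- gene_set_trajectory(fx$means, genes[1, ])
  b <- match(locate_bin(g$bin_index, genes$chrom[1],
                        floor((genes$start[1] + genes$end[1]) / 2) + 1),
             m$autosomal_bins)
  expect_equal(unname(tr1$trajectory), unname(fx$means$values[b, ]))
  # non-overlapping gene set errors
  off <- data.frame(chrom = "chrX", start = 0, end = 1e6, name = "gx")
  expect_error(gene_set_trajectory(fx$means, off), "no overlap")
})
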