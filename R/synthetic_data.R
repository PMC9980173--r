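# Synthetic single-cell contact generator. Plants the statistical structure
# the downstream modules estimate: a compartment checkerboard with a
# CpG-correlated reference track, cell-type-specific compartment profiles,
# maturation-dependent dynamic regions that flip compartment across the
# lifespan, stage-specific distance-decay mixtures (short-range power law
# vs ultra-long-range >=10 Mb component), inter-chromosomal hubs, halved X
# density in males, and pooled-donor SNP allele observations.

#' Build a stage preset for the contact generator
#'
#' A preset bundles the generative parameters of one 3D genome structure
#' type: the probability \code{w_long} that an intra-chromosomal contact is
#' ultra-long-range (>= 10 Mb), the short-range power-law exponent, the
#' same-compartment odds multiplier \code{checker_strength} applied to
#' long-range and inter-chromosomal contacts, the inter-chromosomal contact
#' fraction, an optional chromosome-pair hub, and sex.
#'
#' @param name preset label.
#' @param w_long probability in \code{[0,1]} that an intra contact is drawn
#'   from the ultra-long-range component; this is exactly the expected
#'   >=10 Mb fraction of intra contacts.
#' @param decay_exponent power-law slope of the short-range component on
#'   \code{[10 kb, 10 Mb)}.
#' @param checker_strength odds multiplier (>= 1) favouring same-compartment
#'   endpoint pairs for long-range and inter contacts.
#' @param inter_frac fraction of contacts that are inter-chromosomal.
#' @param hub \code{NULL}, or \code{list(chroms = <character>, multiplier =
#'   <number >= 1>)}: all chromosome pairs within \code{chroms} get their
#'   inter-contact weight multiplied.
#' @param sex \code{"male"} or \code{"female"}; males have X contact density
#'   halved relative to autosomes.
#' @param age nominal donor age attached to cells (years or postnatal days).
#' @param cell_type label selecting the type-specific compartment profile
#'   (a deterministic set of bins whose compartment is flipped relative to
#'   the genome baseline); presets of the same cell type share a profile.
#'   Defaults to \code{name}.
#' @param maturity lifespan position in \code{[0, 1]} (0 = birth-like,
#'   1 = aged); dynamic regions whose flip threshold is at or below
#'   \code{maturity} have switched compartment.
#' @return An object of class \code{"stage_preset"} (a named list).
#' @export
stage_preset <- function(name, w_long, decay_exponent = 1.5,
                         checker_strength = 1.5, inter_frac = 0.05,
                         hub = NULL, sex = "female", age = NA_real_,
                         cell_type = name, maturity = 0.5) {
  stopifnot(w_long >= 0, w_long <= 1, checker_strength >= 1,
            inter_frac >= 0, inter_frac < 1, decay_exponent > 0,
            sex %in% c("male", "female"),
            maturity >= 0, maturity <= 1)
  if (!is.null(hub))
    stopifnot(is.list(hub), length(hub$chroms) >= 2, hub$multiplier >= 1)
  structure(list(name = name, w_long = w_long,
                 decay_exponent = decay_exponent,
                 checker_strength = checker_strength,
                 inter_frac = inter_frac, hub = hub, sex = sex, age = age,
                 cell_type = cell_type, maturity = maturity),
            class = "stage_preset")
}

#' Synthetic genome with planted A/B compartments and dynamic regions
#'
#' Chromosomes carry alternating A/B blocks of \code{block_size}; the 1-Mb
#' baseline compartment sign track is +1 (A) / -1 (B). A CpG-density track
#' is drawn from two Gaussians (A-bins CpG-richer than B-bins), so the
#' reference used by scA/B correlates positively with the planted signs.
#' The last chromosome is an X (\code{chrX}); the rest are autosomes.
#'
#' Two planted deviations from the baseline give cell types and lifespan
#' stages their distinct scA/B profiles (see
#' \code{\link{compartment_profile}}): a fraction \code{dynamic_frac} of
#' autosomal bins are \emph{dynamic regions} that flip compartment when a
#' preset's maturity passes their per-bin threshold (baseline B bins flip
#' up to A, baseline A bins flip down); and each cell type flips its own
#' deterministic \code{type_flip_frac} of the remaining bins.
#'
#' @param n_chroms total chromosomes including the X.
#' @param chrom_length chromosome length in bp (all equal; must exceed
#'   10 Mb so the ultra-long-range component has support).
#' @param block_size compartment block width, a multiple of 1 Mb.
#' @param seed RNG seed for the CpG draw, dynamic-region placement and
#'   type-profile hashing.
#' @param cpg_mean_a,cpg_mean_b,cpg_sd CpG-per-bp density Gaussians for A
#'   and B bins.
#' @param dynamic_frac fraction of autosomal bins that are dynamic regions.
#' @param type_flip_frac fraction of bins flipped per cell type.
#' @return Class \code{"synthetic_genome"}: list with \code{assembly},
#'   \code{bin_index} (1 Mb), \code{compartment_sign} (baseline +/-1 per
#'   bin), \code{cpg_track}, \code{dynamic_bins}, \code{dynamic_threshold},
#'   \code{dynamic_direction} (+1 up / -1 down), \code{type_flip_frac},
#'   \code{seed}.
#' @export
make_synthetic_genome <- function(n_chroms = 6, chrom_length = 80e6,
                                  block_size = 5e6, seed = 1,
                                  cpg_mean_a = 0.012, cpg_mean_b = 0.006,
                                  cpg_sd = 0.0015, dynamic_frac = 0.08,
                                  type_flip_frac = 0.05) {
  stopifnot(n_chroms >= 2, chrom_length > 0, block_size > 0,
            dynamic_frac >= 0, dynamic_frac < 1,
            type_flip_frac >= 0, type_flip_frac < 1)
  if (block_size > chrom_length) stop("block_size exceeds chromosome length")
  if (block_size %% 1e6 != 0) stop("block_size must be a multiple of 1 Mb")
  nm <- c(paste0("chr", seq_len(n_chroms - 1)), "chrX")
  asm <- assembly(nm, rep(chrom_length, n_chroms))
  bi <- make_bins(asm, 1e6)
  bins_per_chrom <- as.integer(ceiling(chrom_length / 1e6))
  block_bins <- as.integer(block_size / 1e6)
  sign_one <- ifelse((floor((seq_len(bins_per_chrom) - 1) / block_bins)) %% 2 == 0,
                     1, -1)
  signs <- rep(sign_one, n_chroms)
  set.seed(seed)
  cpg <- ifelse(signs > 0,
                stats::rnorm(length(signs), cpg_mean_a, cpg_sd),
                stats::rnorm(length(signs), cpg_mean_b, cpg_sd))
  cpg <- pmax(cpg, 1e-4)
  # compartments flip in whole blocks (A/B domains are multi-Mb), so a
  # switched region's short-range contact neighbourhood stays coherent
  blocks_per_chrom <- as.integer(ceiling(bins_per_chrom / block_bins))
  block_id <- rep(seq_len(blocks_per_chrom), each = block_bins,
                  length.out = bins_per_chrom)
  block_id <- as.integer(block_id + rep((seq_len(n_chroms) - 1) *
                                          blocks_per_chrom,
                                        each = bins_per_chrom))
  auto_blocks <- unique(block_id[bi$bins$chrom %in% asm$autosomes])
  n_dyn_blocks <- round(dynamic_frac * length(auto_blocks))
  dyn_blocks <- sort(sample(auto_blocks, n_dyn_blocks))
  dynamic_bins <- which(block_id %in% dyn_blocks)
  # thresholds strictly inside (0,1): every dynamic block changes over a
  # full 0 -> 1 maturity sweep
  block_thr <- setNames(stats::runif(n_dyn_blocks, 0.05, 0.95),
                        dyn_blocks)
  dynamic_threshold <- unname(block_thr[as.character(block_id[dynamic_bins])])
  structure(list(assembly = asm, bin_index = bi,
                 compartment_sign = signs,
                 cpg_track = bin_track(bi, cpg, kind = "cpg_density"),
                 block_id = block_id,
                 dynamic_bins = dynamic_bins,
                 dynamic_threshold = dynamic_threshold,
                 dynamic_direction = -signs[dynamic_bins],
                 type_flip_frac = type_flip_frac,
                 seed = seed),
            class = "synthetic_genome")
}

# deterministic per-type seed from the cell-type string
.type_seed <- function(genome, cell_type) {
  h <- sum(utf8ToInt(cell_type) * seq_along(utf8ToInt(cell_type)))
  (genome$seed * 131071 + h * 2654435761) %% 2147483647
}

#' Effective compartment profile of a preset on a synthetic genome
#'
#' Starts from the genome's baseline checkerboard, applies the cell type's
#' deterministic flip set, then flips every dynamic region whose threshold
#' is at or below the preset's maturity. This is the ground truth that
#' scA/B estimates for cells simulated from \code{preset}.
#'
#' @param genome a \code{\link{make_synthetic_genome}} result.
#' @param preset a \code{\link{stage_preset}} (or a list with
#'   \code{cell_type} and \code{maturity}).
#' @return Integer vector of +/-1 per 1-Mb bin.
#' @export
compartment_profile <- function(genome, preset) {
  s <- genome$compartment_sign
  all_blocks <- unique(genome$block_id)
  dyn_blocks <- unique(genome$block_id[genome$dynamic_bins])
  candidates <- setdiff(all_blocks, dyn_blocks)
  n_flip <- round(genome$type_flip_frac * length(all_blocks))
  if (n_flip > 0 && length(candidates) > 0) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    set.seed(.type_seed(genome, preset$cell_type))
    flip_blocks <- sample(candidates, min(n_flip, length(candidates)))
    assign(".Random.seed", old, envir = globalenv())
    flip <- which(genome$block_id %in% flip_blocks)
    s[flip] <- -s[flip]
  }
  hit <- genome$dynamic_threshold <= preset$maturity
  s[genome$dynamic_bins[hit]] <- -s[genome$dynamic_bins[hit]]
  s
}

# sign of the 1-Mb bin containing 1-based positions (vectorized, by chrom
# idx) under a precomputed effective sign vector
.sign_at <- function(genome, chrom_idx, pos, esign = genome$compartment_sign) {
  off <- unname(genome$bin_index$offset)[chrom_idx]
  esign[off + floor((pos - 1) / 1e6) + 1]
}

# resample-left-start acceptance for the compartment bias: endpoints in the
# same compartment accepted with probability 1, cross-compartment with 1/cs.
# chrom & distance stay fixed so the distance mixture is untouched.
.accept_checker <- function(genome, chrom_idx, pos_a, pos_b, cs,
                            resample, esign, max_iter = 100) {
  if (cs <= 1 || length(pos_a) == 0)
    return(list(pos_a = pos_a, pos_b = pos_b))
  pending <- seq_along(pos_a)
  for (iter in seq_len(max_iter)) {
    same <- .sign_at(genome, chrom_idx[pending], pos_a[pending], esign) ==
            .sign_at(genome, chrom_idx[pending], pos_b[pending], esign)
    acc <- same | (stats::runif(length(pending)) < 1 / cs)
    pending <- pending[!acc]
    if (length(pending) == 0) break
    new <- resample(pending)
    pos_a[pending] <- new$pos_a
    pos_b[pending] <- new$pos_b
  }
  list(pos_a = pos_a, pos_b = pos_b)
}

#' Simulate one cell's contacts from a stage preset
#'
#' Each contact is inter-chromosomal with probability \code{inter_frac}
#' (chromosome pair weighted by length products times any hub multiplier,
#' endpoints compartment-biased by \code{checker_strength}); otherwise intra:
#' with probability \code{w_long} the genomic distance is log-uniform on
#' \code{[10 Mb, min(100 Mb, 0.9 L)]} with compartment-biased endpoints, else
#' drawn from a truncated power law \code{s^-decay_exponent} on
#' \code{[10 kb, 10 Mb)}. Males have X contact density halved. The >=10 Mb
#' intra fraction is therefore exactly Bernoulli(\code{w_long}) per intra
#' contact.
#'
#' @param genome a \code{\link{make_synthetic_genome}} result.
#' @param preset a \code{\link{stage_preset}}.
#' @param n_contacts number of contacts to draw.
#' @param seed RNG seed.
#' @param cell_id identifier stored on the result.
#' @return A \code{\link{cell_contacts}} with truth labels
#'   (\code{structure_type}, \code{sex}, \code{w_long}, \code{age}) in
#'   \code{$meta}.
#' @export
simulate_cell <- function(genome, preset, n_contacts, seed,
                          cell_id = paste0("cell_", seed)) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(preset, "stage_preset"), n_contacts > 0)
  asm <- genome$assembly
  L <- unname(asm$chrom_lengths)
  if (preset$w_long > 0 && any(L <= 1e7))
    stop("no long-range support: chromosome shorter than 10 Mb")
  esign <- compartment_profile(genome, preset)
  set.seed(seed)
  nc <- length(L)
  w <- L
  if (preset$sex == "male")
    w[asm$chrom_names %in% asm$sex_chroms] <-
      w[asm$chrom_names %in% asm$sex_chroms] * 0.5

  is_inter <- stats::runif(n_contacts) < preset$inter_frac
  n_inter <- sum(is_inter)
  n_intra <- n_contacts - n_inter
  cs <- preset$checker_strength

  out <- vector("list", 2)

  if (n_intra > 0) {
    ci <- sample.int(nc, n_intra, replace = TRUE, prob = w)
    long <- stats::runif(n_intra) < preset$w_long
    d <- numeric(n_intra)
    if (any(!long)) {       # truncated power law on [10 kb, 10 Mb)
      a <- preset$decay_exponent
      u <- stats::runif(sum(!long))
      s0 <- 1e4; s1 <- 1e7
      s <- if (abs(a - 1) < 1e-9) exp(u * (log(s1) - log(s0)) + log(s0))
           else (u * (s1^(1 - a) - s0^(1 - a)) + s0^(1 - a))^(1 / (1 - a))
      d[!long] <- pmin(pmax(round(s), 1e4), 1e7 - 1)
    }
    if (any(long)) {        # log-uniform on [10 Mb, min(100 Mb, 0.9 L)]
      hi <- pmin(1e8, 0.9 * L[ci[long]])
      s <- exp(stats::runif(sum(long), log(1e7), log(hi)))
      d[long] <- pmin(pmax(round(s), 1e7), floor(hi))
    }
    draw_start <- function(idx) {
      pa <- floor(stats::runif(length(idx)) * (L[ci[idx]] - d[idx])) + 1
      list(pos_a = pa, pos_b = pa + d[idx])
    }
    st <- draw_start(seq_len(n_intra))
    pos_a <- st$pos_a; pos_b <- st$pos_b
    if (cs > 1 && any(long)) {
      res <- .accept_checker(genome, ci[long], pos_a[long], pos_b[long], cs,
                             resample = function(p) draw_start(which(long)[p]),
                             esign = esign)
      pos_a[long] <- res$pos_a; pos_b[long] <- res$pos_b
    }
    out[[1]] <- data.table::data.table(
      chrom_a = asm$chrom_names[ci], pos_a = pos_a,
      chrom_b = asm$chrom_names[ci], pos_b = pos_b)
  }

  if (n_inter > 0) {
    pr <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
    pw <- w[pr[, 1]] * w[pr[, 2]]
    if (!is.null(preset$hub)) {
      hi <- match(preset$hub$chroms, asm$chrom_names)
      in_hub <- pr[, 1] %in% hi & pr[, 2] %in% hi
      pw[in_hub] <- pw[in_hub] * preset$hub$multiplier
    }
    pk <- sample.int(nrow(pr), n_inter, replace = TRUE, prob = pw)
    ca <- pr[pk, 1]; cb <- pr[pk, 2]
    draw_pos <- function(idx) list(
      pos_a = floor(stats::runif(length(idx)) * L[ca[idx]]) + 1,
      pos_b = floor(stats::runif(length(idx)) * L[cb[idx]]) + 1)
    pp <- draw_pos(seq_len(n_inter))
    if (cs > 1) {
      # same acceptance rule, but endpoints live on different chromosomes
      pending <- seq_len(n_inter)
      for (iter in 1:100) {
        same <- .sign_at(genome, ca[pending], pp$pos_a[pending], esign) ==
                .sign_at(genome, cb[pending], pp$pos_b[pending], esign)
        acc <- same | (stats::runif(length(pending)) < 1 / cs)
        pending <- pending[!acc]
        if (length(pending) == 0) break
        new <- draw_pos(pending)
        pp$pos_a[pending] <- new$pos_a
        pp$pos_b[pending] <- new$pos_b
      }
    }
    out[[2]] <- data.table::data.table(
      chrom_a = asm$chrom_names[ca], pos_a = pp$pos_a,
      chrom_b = asm$chrom_names[cb], pos_b = pp$pos_b)
  }

  cell_contacts(cell_id, data.table::rbindlist(out), asm,
                meta = list(structure_type = preset$name, sex = preset$sex,
                            w_long = preset$w_long, age = preset$age,
                            cell_type = preset$cell_type,
                            maturity = preset$maturity))
}

#' Library of calibrated stage presets
#'
#' Ultra-long-range (>= 10 Mb) intra-contact fractions \code{w_long} are the
#' per-type means reported for the cerebellar/forebrain atlas: human granule
#' stages S1 and S5 at 0.19 and 0.33, mouse granule at 0.19 and 0.34,
#' human forebrain neurons 0.15 (birth) and 0.16 (mature), mouse forebrain
#' 0.11/0.13, mouse Purkinje 0.09/0.10, microglia 0.34, oligodendrocytes
#' 0.29 (human) / 0.27 (mouse). Granule stages S2-S4 are linear
#' interpolations between the S1/S5 endpoints. \code{checker_strength}
#' increases monotonically S1 to S5 (1.5 to 3.5); granule presets carry a
#' chr1/chr3/chr5 hub whose multiplier grows across stages. Granule preset
#' ages follow the human stage-abundance peaks (0.2, 1, 10, 30, 80 years)
#' and mouse peaks (P3, P14, P21, P56, P365).
#'
#' @return Named list of \code{\link{stage_preset}} objects.
#' @export
preset_library <- function() {
  gr_cs <- c(2.0, 2.6, 3.2, 3.8, 4.4)
  gr_hub_mult <- c(1.0, 1.5, 2.0, 2.5, 3.0)
  hub_chroms <- c("chr1", "chr3", "chr5")
  hs_ages <- c(0.2, 1, 10, 30, 80)
  mm_ages <- c(3, 14, 21, 56, 365)
  hs_w <- seq(0.19, 0.33, length.out = 5)
  mm_w <- seq(0.19, 0.34, length.out = 5)
  maturities <- seq(0, 1, length.out = 5)
  p <- list()
  for (i in 1:5) {
    hub <- if (gr_hub_mult[i] > 1)
      list(chroms = hub_chroms, multiplier = gr_hub_mult[i]) else NULL
    p[[paste0("human_granule_S", i)]] <- stage_preset(
      paste0("human_granule_S", i), hs_w[i], checker_strength = gr_cs[i],
      hub = hub, age = hs_ages[i],
      cell_type = "human_granule", maturity = maturities[i])
    p[[paste0("mouse_granule_S", i)]] <- stage_preset(
      paste0("mouse_granule_S", i), mm_w[i], checker_strength = gr_cs[i],
      hub = hub, age = mm_ages[i],
      cell_type = "mouse_granule", maturity = maturities[i])
  }
  p$human_forebrain_birth  <- stage_preset("human_forebrain_birth", 0.15, age = 0,
                                           cell_type = "human_forebrain", maturity = 0)
  p$human_forebrain_mature <- stage_preset("human_forebrain_mature", 0.16, age = 30,
                                           cell_type = "human_forebrain", maturity = 1)
  p$mouse_forebrain_birth  <- stage_preset("mouse_forebrain_birth", 0.11, age = 0,
                                           cell_type = "mouse_forebrain", maturity = 0)
  p$mouse_forebrain_mature <- stage_preset("mouse_forebrain_mature", 0.13, age = 56,
                                           cell_type = "mouse_forebrain", maturity = 1)
  p$mouse_purkinje_birth   <- stage_preset("mouse_purkinje_birth", 0.09, age = 0,
                                           cell_type = "mouse_purkinje", maturity = 0)
  p$mouse_purkinje_mature  <- stage_preset("mouse_purkinje_mature", 0.10, age = 56,
                                           cell_type = "mouse_purkinje", maturity = 1)
  p$microglia              <- stage_preset("microglia", 0.34,
                                           checker_strength = 4.4, age = 30,
                                           maturity = 1)
  p$oligodendrocyte_human  <- stage_preset("oligodendrocyte_human", 0.29,
                                           checker_strength = 3.8, age = 30,
                                           maturity = 1)
  p$oligodendrocyte_mouse  <- stage_preset("oligodendrocyte_mouse", 0.27,
                                           checker_strength = 3.8, age = 365,
                                           maturity = 1)
  p
}

#' Simulate a cohort of cells
#'
#' @param genome a \code{\link{make_synthetic_genome}} result.
#' @param design list of design rows, each
#'   \code{list(preset = <stage_preset>, n_cells = <int>, age = <num>)}
#'   (\code{age} optional; defaults to the preset's age).
#' @param n_contacts contacts per cell.
#' @param seed master seed; each cell gets an independent substream seed.
#' @return List of \code{\link{cell_contacts}}; each cell's \code{$meta}
#'   carries truth labels and age.
#' @export
simulate_cohort <- function(genome, design, n_contacts, seed) {
  if (length(design) == 0) stop("empty design")
  n_total <- sum(vapply(design, function(d) d$n_cells, numeric(1)))
  stopifnot(all(vapply(design, function(d) d$n_cells > 0, logical(1))))
  set.seed(seed)
  cell_seeds <- sample.int(2147483646L, n_total)
  cells <- vector("list", n_total)
  k <- 0L
  for (d in design) {
    age <- if (!is.null(d$age)) d$age else d$preset$age
    for (j in seq_len(d$n_cells)) {
      k <- k + 1L
      cells[[k]] <- simulate_cell(genome, d$preset, n_contacts,
                                  seed = cell_seeds[k],
                                  cell_id = sprintf("%s_c%03d", d$preset$name, j))
      cells[[k]]$meta$age <- age
    }
  }
  cells
}

#' Export a cohort as pairs files plus a metadata table
#'
#' @param cells list of \code{\link{cell_contacts}}.
#' @param dir output directory (created if needed).
#' @return path of the metadata TSV, invisibly.
#' @export
write_cohort <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.table::rbindlist(lapply(cells, function(ce) {
    write_pairs(ce, file.path(dir, paste0(ce$cell_id, ".pairs")))
    data.table::data.table(
      cell_id = ce$cell_id,
      structure_type = ce$meta$structure_type %||% NA_character_,
      sex = ce$meta$sex %||% NA_character_,
      age = ce$meta$age %||% NA_real_)
  }))
  path <- file.path(dir, "cells.tsv")
  data.table::fwrite(meta, path, sep = "\t")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Pooled donors -----------------------------------------------------------

#' Random donor genotypes at biallelic SNPs
#'
#' Draws Hardy-Weinberg genotypes (alt dosage 0/1/2) at independent SNPs
#' with allele frequencies uniform on \code{[maf_min, maf_max]}.
#'
#' @param n_donors,n_snps dimensions.
#' @param seed RNG seed.
#' @param maf_min,maf_max allele-frequency range.
#' @return Class \code{"genotype_set"}: list with \code{dosage} (donor x
#'   SNP matrix in \{0,1,2\}), \code{snp_ids}, \code{donor_ids}.
#' @export
make_genotypes <- function(n_donors, n_snps, seed = 1,
                           maf_min = 0.1, maf_max = 0.5) {
  set.seed(seed)
  af <- stats::runif(n_snps, maf_min, maf_max)
  dos <- vapply(af, function(p) stats::rbinom(n_donors, 2, p),
                integer(n_donors))
  dos <- matrix(dos, nrow = n_donors)
  rownames(dos) <- paste0("donor", seq_len(n_donors))
  colnames(dos) <- paste0("snp", seq_len(n_snps))
  structure(list(dosage = dos, snp_ids = colnames(dos),
                 donor_ids = rownames(dos)),
            class = "genotype_set")
}

#' Pool design for demultiplexing simulations
#'
#' @param genotypes a \code{\link{make_genotypes}} result.
#' @param cells_per_donor singlet cells simulated per donor.
#' @param doublet_rate fraction of extra cells that are 50/50 two-donor
#'   doublets.
#' @param allele_error_rate probability an observed allele is flipped.
#' @param snp_obs_per_cell mean number of allele observations per cell.
#' @return Class \code{"pool_design"} list.
#' @export
pool_design <- function(genotypes, cells_per_donor = 20, doublet_rate = 0.05,
                        allele_error_rate = 0.01, snp_obs_per_cell = 200) {
  stopifnot(inherits(genotypes, "genotype_set"),
            doublet_rate >= 0, doublet_rate <= 1,
            allele_error_rate >= 0, allele_error_rate <= 1)
  structure(list(genotypes = genotypes, cells_per_donor = cells_per_donor,
                 doublet_rate = doublet_rate,
                 allele_error_rate = allele_error_rate,
                 snp_obs_per_cell = snp_obs_per_cell),
            class = "pool_design")
}

#' Simulate per-cell SNP allele observations from a pooled run
#'
#' Singlet cells draw alleles from their donor's genotype (alt probability
#' dosage/2) with symmetric error \code{allele_error_rate}; doublets mix two
#' distinct donors 50/50. The number of observations per cell is Poisson
#' with mean \code{snp_obs_per_cell}, spread over SNPs uniformly.
#'
#' @param design a \code{\link{pool_design}}.
#' @param seed RNG seed.
#' @return List with \code{obs} (data.table: cell_id, snp_id, ref_count,
#'   alt_count) and \code{truth} (data.table: cell_id, donor, donor2,
#'   is_doublet).
#' @export
simulate_pool <- function(design, seed) {
  stopifnot(inherits(design, "pool_design"))
  G <- design$genotypes$dosage
  nd <- nrow(G)
  if (nd >= 2 && anyDuplicated(as.data.frame(G)) > 0)
    warning("unidentifiable: some donors have identical genotypes")
  set.seed(seed)
  n_singlet <- nd * design$cells_per_donor
  n_doublet <- if (design$doublet_rate >= 1) n_singlet
               else round(n_singlet * design$doublet_rate / (1 - design$doublet_rate))
  if (design$doublet_rate >= 1) n_singlet <- 0
  n_cells <- n_singlet + n_doublet
  donor1 <- c(rep(seq_len(nd), length.out = n_singlet),
              sample.int(nd, n_doublet, replace = TRUE))
  donor2 <- rep(NA_integer_, n_cells)
  if (n_doublet > 0 && nd >= 2)
    donor2[n_singlet + seq_len(n_doublet)] <-
      vapply(donor1[n_singlet + seq_len(n_doublet)],
             function(d) sample(setdiff(seq_len(nd), d), 1), integer(1))
  obs <- vector("list", n_cells)
  truth <- data.table::data.table(
    cell_id = sprintf("pc%04d", seq_len(n_cells)),
    donor = rownames(G)[donor1],
    donor2 = ifelse(is.na(donor2), NA_character_, rownames(G)[donor2]),
    is_doublet = !is.na(donor2))
  ns <- ncol(G)
  for (i in seq_len(n_cells)) {
    n_obs <- max(1L, stats::rpois(1, design$snp_obs_per_cell))
    snp <- sample.int(ns, n_obs, replace = TRUE)
    p_alt <- if (is.na(donor2[i])) G[donor1[i], snp] / 2
             else (G[donor1[i], snp] + G[donor2[i], snp]) / 4
    alt <- stats::runif(n_obs) < p_alt
    flip <- stats::runif(n_obs) < design$allele_error_rate
    alt <- xor(alt, flip)
    tab <- data.table::data.table(snp = snp, alt = alt)
    agg <- tab[, .(ref_count = sum(!alt), alt_count = sum(alt)), by = snp]
    obs[[i]] <- data.table::data.table(
      cell_id = truth$cell_id[i],
      snp_id = colnames(G)[agg$snp],
      ref_count = agg$ref_count, alt_count = agg$alt_count)
  }
  list(obs = data.table::rbindlist(obs), truth = truth)
}
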