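# Stage-resolved scA/B trajectory analysis: per-stage region means,
# top-variance dynamic-region selection, two temporal modes (up/down), and
# marker-gene locus aggregation.

#' Mean scA/B of each region at each stage
#'
#' Per-bin mean over the cells of each stage, ignoring unobserved
#' (imputed) entries. Stages with zero cells give an all-NA column and a
#' warning.
#'
#' @param mat a \code{\link{build_scab_matrix}} result.
#' @param stage per-cell stage labels (factor or character).
#' @return Class \code{"stage_means"}: list with \code{values} (regions x
#'   stages), \code{n_cells} (per stage), \code{bin_index},
#'   \code{autosomal_bins}.
#' @export
stage_mean_scab <- function(mat, stage) {
  stopifnot(inherits(mat, "scab_matrix"),
            length(stage) == nrow(mat$values))
  stage <- as.factor(stage)
  lv <- levels(stage)
  vals <- matrix(NA_real_, ncol(mat$values), length(lv),
                 dimnames = list(NULL, lv))
  n_cells <- setNames(integer(length(lv)), lv)
  for (s in lv) {
    idx <- which(stage == s)
    n_cells[s] <- length(idx)
    if (length(idx) == 0L) {
      warning("stage ", s, " has no cells; column left missing")
      next
    }
    v <- mat$values[idx, , drop = FALSE]
    obs <- mat$observed[idx, , drop = FALSE]
    v[!obs] <- NA
    vals[, s] <- colMeans(v, na.rm = TRUE)
  }
  vals[is.nan(vals)] <- NA
  structure(list(values = vals, n_cells = n_cells,
                 bin_index = mat$bin_index,
                 autosomal_bins = mat$autosomal_bins),
            class = "stage_means")
}

#' Select the top-variance dynamic regions
#'
#' Between-stage variance per region is the population variance of its
#' stage means (stages equally weighted); the top \code{floor(top_frac * R)}
#' regions are returned, ties broken by region ordinal. Regions with any
#' missing stage mean are ranked last.
#'
#' @param stage_means a \code{\link{stage_mean_scab}} result.
#' @param top_frac fraction of regions to keep (default 0.20).
#' @return List with \code{selected} (region ordinals, ranked), and
#'   \code{variance} (per-region between-stage variance).
#' @export
select_dynamic_regions <- function(stage_means, top_frac = 0.20) {
  V <- stage_means$values
  present <- colSums(!is.na(V)) > 0
  if (sum(present) < 2) stop("need at least 2 stages with cells")
  V <- V[, present, drop = FALSE]
  pop_var <- function(x) {
    if (any(is.na(x))) return(-Inf)
    mean((x - mean(x))^2)
  }
  v <- apply(V, 1, pop_var)
  k <- floor(top_frac * nrow(V))
  ord <- order(-v, seq_along(v))
  list(selected = sort(ord[seq_len(k)]), variance = replace(v, v == -Inf, NA))
}

#' Cluster dynamic-region trajectories into temporal modes
#'
#' Hierarchical clustering (average linkage) on the correlation distance of
#' stage trajectories, cut at \code{k = 2}; modes are named \code{"up"} /
#' \code{"down"} by the sign of the mean last-minus-first stage difference
#' within each cluster.
#'
#' @param stage_means a \code{\link{stage_mean_scab}} result.
#' @param regions region ordinals (e.g. from
#'   \code{\link{select_dynamic_regions}}).
#' @param k number of modes (default 2).
#' @return Character vector of mode labels (\code{"up"}/\code{"down"}; or
#'   \code{"mode<i>"} beyond 2), named by region ordinal.
#' @export
temporal_modes <- function(stage_means, regions, k = 2) {
  V <- stage_means$values[regions, , drop = FALSE]
  V <- V[, colSums(!is.na(V)) > 0, drop = FALSE]
  if (nrow(V) < k) stop("fewer regions than modes")
  if (any(is.na(V))) stop("regions with missing stage means")
  sds <- apply(V, 1, stats::sd)
  if (all(sds == 0)) stop("all trajectories identical (flat)")
  # correlation distance; flat trajectories get correlation 0 to anything
  C <- suppressWarnings(stats::cor(t(V)))
  C[is.na(C)] <- 0
  diag(C) <- 1
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  cl <- stats::cutree(hc, k = k)
  delta <- V[, ncol(V)] - V[, 1]
  lab <- character(length(cl))
  means <- tapply(delta, cl, mean)
  nm <- ifelse(means >= 0, "up", "down")
  # if both clusters go the same way, keep them distinct
  if (k == 2 && nm[1] == nm[2])
    nm[which.min(abs(means))] <- paste0(nm[which.min(abs(means))], "2")
  if (k > 2) nm <- paste0("mode", seq_len(k))
  nm <- setNames(as.character(nm), names(means))
  lab <- unname(nm[as.character(cl)])
  names(lab) <- regions
  lab
}

#' Map genes to 1-Mb bins and aggregate their scA/B trajectory
#'
#' Genes are assigned to the bin containing their body midpoint. The
#' aggregated trajectory is the mean stage trajectory over all gene bins
#' present in the matrix, with a monotonicity statistic (fraction of
#' regions whose last stage exceeds the first).
#'
#' @param stage_means a \code{\link{stage_mean_scab}} result.
#' @param genes data.frame/data.table with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open) and \code{name}, e.g.
#'   read from BED via \code{\link{read_bed}}.
#' @return List with \code{trajectory} (per-stage aggregated mean),
#'   \code{per_region} (matrix, gene bins x stages), \code{bins} (ordinals
#'   within the autosomal matrix), \code{frac_increasing}.
#' @export
gene_set_trajectory <- function(stage_means, genes) {
  genes <- data.table::as.data.table(genes)
  bi <- stage_means$bin_index
  mid <- floor((genes$start + genes$end) / 2) + 1  # 1-based midpoint
  gbin <- locate_bin(bi, genes$chrom, mid)
  pos <- match(gbin, stage_means$autosomal_bins)
  pos <- unique(pos[!is.na(pos)])
  pos <- pos[rowSums(!is.na(stage_means$values[pos, , drop = FALSE])) > 0]
  if (length(pos) == 0L)
    stop("no overlap between gene set and matrix bins")
  per_region <- stage_means$values[pos, , drop = FALSE]
  trajectory <- colMeans(per_region, na.rm = TRUE)
  last <- per_region[, ncol(per_region)]
  first <- per_region[, 1]
  list(trajectory = trajectory, per_region = per_region, bins = pos,
       frac_increasing = mean(last > first, na.rm = TRUE))
}

#' Read a BED file of gene regions
#'
#' Minimal BED reader: \code{chrom start end name}, 0-based half-open.
#' @param path BED path.
#' @return data.table with columns chrom, start, end, name.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3) stop("BED needs at least 3 columns")
  data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
  if (ncol(dt) >= 4) data.table::setnames(dt, 4, "name")
  else dt[, name := sprintf("region%d", .I)]
  dt[, .(chrom, start, end, name)]
}
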