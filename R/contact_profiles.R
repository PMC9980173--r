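# Contact distance-decay statistics, aggregated contact maps and
# inter-chromosomal enrichment / hub detection.
#
# All intra-chromosomal statistics apply a 10-kb QC floor (self-ligation
# artifacts); the ultra-long-range boundary is an inclusive >= 10 Mb.

.intra_distances <- function(cells, floor_bp = 1e4) {
  if (inherits(cells, "cell_contacts")) cells <- list(cells)
  d <- unlist(lapply(cells, function(ce)
    ce$contacts$distance[ce$contacts$is_intra]), use.names = FALSE)
  d[d >= floor_bp]
}

#' Distance histogram of intra-chromosomal contacts
#'
#' Log10-spaced histogram of genomic distances, intra contacts only,
#' distances below the 10-kb QC floor excluded. Counts sum to the retained
#' contact total.
#'
#' @param cells a \code{\link{cell_contacts}} or list of them (pooled).
#' @param n_log_bins number of log10-spaced bins.
#' @param floor_bp QC floor on distance (default 10 kb).
#' @return Class \code{"distance_histogram"}: list with \code{edges}
#'   (length \code{n_log_bins + 1}), \code{counts}, \code{total}.
#' @export
distance_histogram <- function(cells, n_log_bins = 30, floor_bp = 1e4) {
  d <- .intra_distances(cells, floor_bp)
  if (length(d) == 0L) stop("no intra-chromosomal contacts")
  edges <- 10^seq(log10(floor_bp), log10(max(d) + 1),
                  length.out = n_log_bins + 1)
  counts <- tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                     nbins = n_log_bins)
  structure(list(edges = edges, counts = counts, total = length(d)),
            class = "distance_histogram")
}

#' Fraction of intra-chromosomal contacts at or beyond a distance
#'
#' The ultra-long-range contact fraction: intra contacts with
#' \code{distance >= threshold} over all intra contacts passing the 10-kb
#' floor. Returns \code{NA} (flagged by a warning) when the cell has no
#' qualifying intra contacts.
#'
#' @param cell a \code{\link{cell_contacts}} (or list, pooled).
#' @param threshold distance boundary, inclusive; default 10 Mb.
#' @param floor_bp QC floor (default 10 kb).
#' @return Fraction in \code{[0, 1]}, or \code{NA}.
#' @export
fraction_long_range <- function(cell, threshold = 1e7, floor_bp = 1e4) {
  d <- .intra_distances(cell, floor_bp)
  if (length(d) == 0L) {
    warning("no intra-chromosomal contacts; fraction undefined")
    return(NA_real_)
  }
  mean(d >= threshold)
}

#' Aggregated contact map over a group of cells
#'
#' Sums binned contacts over cells into a symmetric matrix (both (i,j) and
#' (j,i) incremented; diagonal counted once). Optionally restricted to one
#' chromosome region, and optionally coverage-normalized by iterative
#' marginal scaling.
#'
#' @param cells list of \code{\link{cell_contacts}} (or one).
#' @param bin_index target grid (e.g. 250-kb bins); region maps use a grid
#'   built on a sub-assembly.
#' @param region optional \code{list(chrom=, start=, end=)} (0-based
#'   half-open) restricting to intra contacts within the window.
#' @param normalize if TRUE, iteratively scale rows/columns to unit mean
#'   marginal (10 iterations).
#' @return Class \code{"aggregate_map"}: list with \code{matrix} (dense,
#'   symmetric), \code{bin_index}, \code{total} (contacts mapped),
#'   \code{normalized}.
#' @export
aggregate_map <- function(cells, bin_index, region = NULL, normalize = FALSE) {
  if (inherits(cells, "cell_contacts")) cells <- list(cells)
  dt <- data.table::rbindlist(lapply(cells, function(ce) ce$contacts))
  if (!is.null(region)) {
    dt <- dt[chrom_a == region$chrom & chrom_b == region$chrom &
             pos_a > region$start & pos_a <= region$end &
             pos_b > region$start & pos_b <= region$end]
  }
  nb <- n_bins(bin_index)
  M <- matrix(0, nb, nb)
  if (nrow(dt)) {
    ba <- locate_bin(bin_index, dt$chrom_a, dt$pos_a)
    bb <- locate_bin(bin_index, dt$chrom_b, dt$pos_b)
    tab <- data.table::data.table(i = pmin(ba, bb), j = pmax(ba, bb))
    tab <- tab[, .N, by = .(i, j)]
    M[cbind(tab$i, tab$j)] <- tab$N
    M[cbind(tab$j, tab$i)] <- tab$N
  }
  total <- nrow(dt)
  if (normalize && total > 0) {
    # iterative marginal scaling toward unit row/column sums; fixes overall
    # scale too, so proportional maps normalize to the same matrix
    for (it in 1:10) {
      rs <- rowSums(M)
      s <- ifelse(rs > 0, sqrt(rs), 1)
      M <- M / outer(s, s)
    }
  }
  structure(list(matrix = M, bin_index = bin_index, total = total,
                 normalized = normalize),
            class = "aggregate_map")
}

#' Relative-change (log2 ratio) map between two stages
#'
#' \code{log2((late + p) / (early + p))} per pixel on coverage-normalized
#' maps; the pseudocount \code{p} defaults to 1e-6 of the mean of the two
#' matrices. Identical (or proportional, once normalized) maps give zeros.
#'
#' @param map_late,map_early \code{\link{aggregate_map}}s on the same grid.
#' @param pseudocount pseudocount; \code{NULL} for the default.
#' @return Matrix of log2 ratios.
#' @export
relative_change_map <- function(map_late, map_early, pseudocount = NULL) {
  if (!identical(dim(map_late$matrix), dim(map_early$matrix)) ||
      !identical(map_late$bin_index$bins, map_early$bin_index$bins))
    stop("grid mismatch between maps")
  A <- map_late$matrix; B <- map_early$matrix
  if (is.null(pseudocount))
    pseudocount <- 1e-6 * mean(c(A, B))
  if (pseudocount <= 0) pseudocount <- .Machine$double.eps
  log2((A + pseudocount) / (B + pseudocount))
}

#' Inter-chromosomal contact enrichment
#'
#' Observed counts per chromosome pair (or per large bin when
#' \code{bin_size} is given) over inter-chromosomal contacts only, divided
#' by an expectation with intra pixels masked (\code{NA}). Two expectation
#' models:
#' \describe{
#'   \item{\code{"marginal"}}{product of the observed inter-contact
#'     marginals, renormalized so the expected inter-pixel total equals the
#'     observed total. Corrects per-chromosome coverage differences, so
#'     uniform random inter contacts give enrichment ~= 1 everywhere; a
#'     strong planted hub partially absorbs into the marginals and reads
#'     back compressed.}
#'   \item{\code{"length"}}{chromosome-length product weights, i.e. the
#'     uniform-contact-density null. Reads a planted pair multiplier back
#'     at face value, but does not correct real coverage bias.}
#' }
#'
#' @param cells list of \code{\link{cell_contacts}} (pooled).
#' @param assembly the assembly (defaults to the first cell's).
#' @param bin_size \code{NULL} for chromosome-level, else a large bin size
#'   (e.g. 6 Mb or 5 Mb) for a bin-level matrix.
#' @param expected_model \code{"marginal"} (default) or \code{"length"}.
#' @return Class \code{"interchrom_matrix"}: list with \code{observed},
#'   \code{expected}, \code{enrichment} (all symmetric with NA intra
#'   blocks), \code{labels}, \code{total}.
#' @export
interchrom_enrichment <- function(cells, assembly = NULL, bin_size = NULL,
                                  expected_model = c("marginal", "length")) {
  expected_model <- match.arg(expected_model)
  if (inherits(cells, "cell_contacts")) cells <- list(cells)
  if (is.null(assembly)) assembly <- cells[[1]]$assembly
  dt <- data.table::rbindlist(lapply(cells, function(ce)
    ce$contacts[!ce$contacts$is_intra]))
  if (nrow(dt) == 0L) stop("no inter-chromosomal contacts")
  if (is.null(bin_size)) {
    labels <- assembly$chrom_names
    ia <- match(dt$chrom_a, labels); ib <- match(dt$chrom_b, labels)
    unit_chrom <- labels
  } else {
    bi <- make_bins(assembly, bin_size)
    labels <- sprintf("%s:%d", bi$bins$chrom, as.integer(bi$bins$start))
    ia <- locate_bin(bi, dt$chrom_a, dt$pos_a)
    ib <- locate_bin(bi, dt$chrom_b, dt$pos_b)
    unit_chrom <- bi$bins$chrom
  }
  n <- length(labels)
  obs <- matrix(0, n, n, dimnames = list(labels, labels))
  tab <- data.table::data.table(i = pmin(ia, ib), j = pmax(ia, ib))
  tab <- tab[, .N, by = .(i, j)]
  obs[cbind(tab$i, tab$j)] <- tab$N
  obs[cbind(tab$j, tab$i)] <- tab$N
  total <- nrow(dt)
  if (expected_model == "marginal") {
    marg <- rowSums(obs)
    expd <- outer(marg, marg)
  } else {
    if (is.null(bin_size)) {
      w <- unname(assembly$chrom_lengths[labels])
    } else {
      w <- bi$bins$end - bi$bins$start
    }
    expd <- outer(w, w)
    dimnames(expd) <- list(labels, labels)
  }
  intra_block <- outer(unit_chrom, unit_chrom, "==")
  obs[intra_block] <- NA; expd[intra_block] <- NA
  # renormalize so the expected total over inter pixels matches the
  # observed total (each contact appears twice in the symmetric matrices)
  expd <- expd * (2 * total / sum(expd, na.rm = TRUE))
  enr <- obs / expd
  structure(list(observed = obs, expected = expd, enrichment = enr,
                 labels = labels, total = total),
            class = "interchrom_matrix")
}

#' Detect multi-chromosome hubs from stage-resolved enrichment
#'
#' A chromosome pair belongs to the strengthening set when its enrichment
#' increases monotonically (non-strictly) across stages with total gain at
#' least \code{gain_threshold}; maximal cliques of such pairs are reported
#' as hubs. Pairs decreasing monotonically by at least the threshold are
#' returned separately as the weakening list.
#'
#' @param enrichment_per_stage list (ordered early to late) of
#'   \code{\link{interchrom_enrichment}} results on the same labels.
#' @param gain_threshold minimum total enrichment gain (late - early).
#' @return List with \code{hubs} (list of character vectors, largest
#'   first), \code{strengthening} and \code{weakening} (data.tables of
#'   pairs with first/last enrichment).
#' @export
detect_hub <- function(enrichment_per_stage, gain_threshold = 0.5) {
  if (length(enrichment_per_stage) < 2) stop("need at least 2 stages")
  labels <- enrichment_per_stage[[1]]$labels
  E <- lapply(enrichment_per_stage, function(e) {
    if (!identical(e$labels, labels)) stop("stage matrices differ in labels")
    e$enrichment
  })
  n <- length(labels)
  up <- list(); down <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    v <- vapply(E, function(m) m[i, j], numeric(1))
    if (any(is.na(v))) next
    dv <- diff(v)
    gain <- v[length(v)] - v[1]
    if (all(dv >= 0) && gain >= gain_threshold)
      up[[length(up) + 1]] <- data.table::data.table(
        chrom_a = labels[i], chrom_b = labels[j],
        first = v[1], last = v[length(v)], gain = gain)
    if (all(dv <= 0) && -gain >= gain_threshold)
      down[[length(down) + 1]] <- data.table::data.table(
        chrom_a = labels[i], chrom_b = labels[j],
        first = v[1], last = v[length(v)], gain = gain)
  }
  up <- data.table::rbindlist(up); down <- data.table::rbindlist(down)
  hubs <- list()
  if (nrow(up) >= 1) {
    g <- igraph::graph_from_data_frame(up[, .(chrom_a, chrom_b)],
                                       directed = FALSE)
    cl <- igraph::max_cliques(g, min = 2)
    hubs <- lapply(cl, function(x) sort(names(x)))
    hubs <- hubs[order(-lengths(hubs))]
  }
  list(hubs = hubs, strengthening = up, weakening = down)
}
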