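# Single-cell chromatin A/B compartment values (scA/B).
#
# scA/B is contact-based: for each 1-Mb bin, the mean reference value
# (CpG density) of the partner bins of all qualifying contacts touching the
# bin. A-compartment bins contact CpG-rich partners and score high; B bins
# score low. Qualifying contacts are inter-chromosomal contacts and intra
# contacts spanning at least min_distance (short-range ligation carries no
# compartment information).

#' Compute per-bin scA/B for one cell
#'
#' For each bin \code{i}, the scA/B value is the mean reference-track value
#' of partner bins over all contacts with exactly one end in \code{i}
#' (intra contacts with \code{distance >= min_distance} plus all inter
#' contacts). Bins with fewer than \code{min_contacts_per_bin} qualifying
#' partners are \code{NA}.
#'
#' @param cell a \code{\link{cell_contacts}}.
#' @param reference a \code{\link{bin_track}} (typically CpG density) on the
#'   1-Mb grid of the cell's assembly.
#' @param min_distance minimum intra-chromosomal distance (bp) for a contact
#'   to count; default 1 Mb.
#' @param min_contacts_per_bin minimum partner count per bin; default 5.
#' @return Numeric vector, one value per bin of the reference grid
#'   (\code{NA} where unobserved).
#' @export
compute_scab <- function(cell, reference, min_distance = 1e6,
                         min_contacts_per_bin = 5) {
  stopifnot(inherits(cell, "cell_contacts"), inherits(reference, "bin_track"))
  bi <- reference$bin_index
  dt <- cell$contacts
  keep <- dt[!is_intra | distance >= min_distance]
  out <- rep(NA_real_, n_bins(bi))
  if (nrow(keep) == 0L) {
    warning("no qualifying contacts in cell ", cell$cell_id)
    return(out)
  }
  ba <- locate_bin(bi, keep$chrom_a, keep$pos_a)
  bb <- locate_bin(bi, keep$chrom_b, keep$pos_b)
  one_end <- ba != bb   # "exactly one end in i": same-bin contacts drop out
  ba <- ba[one_end]; bb <- bb[one_end]
  if (length(ba) == 0L) {
    warning("no qualifying contacts in cell ", cell$cell_id)
    return(out)
  }
  bin <- c(ba, bb)
  partner_val <- reference$values[c(bb, ba)]
  s <- rowsum(partner_val, bin)
  n <- tabulate(bin, nbins = n_bins(bi))
  idx <- as.integer(rownames(s))
  mean_val <- rep(NA_real_, n_bins(bi))
  mean_val[idx] <- s[, 1] / n[idx]
  ok <- n >= min_contacts_per_bin
  out[ok] <- mean_val[ok]
  out
}

#' Assemble the cells x bins scA/B matrix
#'
#' Computes scA/B per cell, restricts to autosomal bins (sex chromosomes
#' would otherwise drive clustering by donor sex), applies per-cell z-score
#' normalization over observed bins, and imputes missing entries with 0
#' (the post-normalization mean) for embedding; the imputation mask is kept.
#' Cells with fewer than \code{min_contacts} total contacts, or with no
#' observed bins, are dropped with a message.
#'
#' @param cells list of \code{\link{cell_contacts}}.
#' @param reference 1-Mb \code{\link{bin_track}} (CpG density).
#' @param min_distance,min_contacts_per_bin passed to
#'   \code{\link{compute_scab}}.
#' @param min_contacts per-cell QC threshold on total contact count.
#' @param normalize per-cell normalization: \code{"zscore"} or \code{"none"}.
#' @return Class \code{"scab_matrix"}: list with \code{values} (cells x
#'   autosomal bins), \code{observed} (logical mask), \code{cell_ids},
#'   \code{bin_index} (full grid), \code{autosomal_bins} (ordinals into the
#'   grid), \code{meta} (data.table of per-cell metadata) and \code{params}.
#' @export
build_scab_matrix <- function(cells, reference, min_distance = 1e6,
                              min_contacts_per_bin = 5, min_contacts = 5000,
                              normalize = c("zscore", "none")) {
  normalize <- match.arg(normalize)
  bi <- reference$bin_index
  auto <- which(bi$bins$chrom %in% bi$assembly$autosomes)
  keep <- vapply(cells, function(ce) nrow(ce$contacts) >= min_contacts,
                 logical(1))
  if (!all(keep))
    message(sum(!keep), " cell(s) dropped by contact-count QC")
  cells <- cells[keep]
  if (length(cells) == 0L) stop("no cells pass QC")
  rows <- lapply(cells, function(ce)
    compute_scab(ce, reference, min_distance, min_contacts_per_bin)[auto])
  vals <- do.call(rbind, rows)
  observed <- !is.na(vals)
  nonempty <- rowSums(observed) > 0
  if (!all(nonempty)) {
    message(sum(!nonempty), " cell(s) dropped with zero observed bins")
    cells <- cells[nonempty]
    vals <- vals[nonempty, , drop = FALSE]
    observed <- observed[nonempty, , drop = FALSE]
  }
  if (normalize == "zscore") {
    for (i in seq_len(nrow(vals))) {
      v <- vals[i, observed[i, ]]
      s <- stats::sd(v)
      vals[i, observed[i, ]] <- if (is.na(s) || s == 0) 0
                                else (v - mean(v)) / s
    }
  }
  vals[!observed] <- 0
  meta <- data.table::rbindlist(lapply(cells, function(ce)
    data.table::data.table(
      cell_id = ce$cell_id,
      structure_type = ce$meta$structure_type %||% NA_character_,
      sex = ce$meta$sex %||% NA_character_,
      age = ce$meta$age %||% NA_real_)))
  structure(list(values = vals, observed = observed,
                 cell_ids = meta$cell_id, bin_index = bi,
                 autosomal_bins = auto, meta = meta,
                 params = list(min_distance = min_distance,
                               min_contacts_per_bin = min_contacts_per_bin,
                               min_contacts = min_contacts,
                               normalize = normalize)),
            class = "scab_matrix")
}

#' @export
print.scab_matrix <- function(x, ...) {
  cat(sprintf("<scab_matrix> %d cells x %d autosomal 1-Mb bins (%s)\n",
              nrow(x$values), ncol(x$values), x$params$normalize))
  invisible(x)
}

#' Export / import an scA/B matrix as TSV (+ JSON parameter sidecar)
#'
#' @param mat a \code{\link{build_scab_matrix}} result.
#' @param path TSV path; parameters go to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_scab_matrix <- function(mat, path) {
  bins <- mat$bin_index$bins[mat$autosomal_bins]
  dt <- data.table::data.table(cell_id = mat$cell_ids)
  cn <- sprintf("%s:%d", bins$chrom, as.integer(bins$start))
  for (j in seq_along(cn)) dt[[cn[j]]] <- mat$values[, j]
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(mat$params, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
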