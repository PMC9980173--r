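# Pooled-sample demultiplexing: sex from X:A contact density, donor
# assignment from known SNP genotypes, genotype-free EM clustering of
# allele observations, and doublet flagging.

#' X-to-autosome contact density ratio
#'
#' Contact-endpoint density on the X chromosome(s) divided by the autosomal
#' endpoint density, lengths taken from the assembly. ~0.5 in XY cells,
#' ~1.0 in XX cells. Both ends of every contact are counted.
#'
#' @param cell a \code{\link{cell_contacts}}.
#' @param assembly defaults to the cell's assembly.
#' @return Numeric ratio (0 when the cell has no X endpoints).
#' @export
xa_ratio <- function(cell, assembly = NULL) {
  if (is.null(assembly)) assembly <- cell$assembly
  ends <- c(cell$contacts$chrom_a, cell$contacts$chrom_b)
  on_x <- ends %in% assembly$sex_chroms
  n_auto <- sum(ends %in% assembly$autosomes)
  if (n_auto == 0L) stop("no autosomal contact endpoints")
  len_x <- sum(assembly$chrom_lengths[assembly$sex_chroms])
  len_a <- sum(assembly$chrom_lengths[assembly$autosomes])
  if (len_x == 0) stop("assembly has no sex chromosome")
  (sum(on_x) / len_x) / (n_auto / len_a)
}

#' Call sex from an X:A ratio
#'
#' @param ratio X:A contact-density ratio (see \code{\link{xa_ratio}}).
#' @param boundary decision boundary, default 0.75 (midpoint of the
#'   expected 0.5 male vs 1.0 female densities).
#' @return \code{"male"}, \code{"female"} or \code{"unknown"} for missing
#'   ratios. Vectorized.
#' @export
assign_sex <- function(ratio, boundary = 0.75) {
  out <- ifelse(is.na(ratio), "unknown",
                ifelse(ratio < boundary, "male", "female"))
  unname(out)
}

# per-donor alt probability at dosage g with allele error eps
.p_alt <- function(dosage, eps) (dosage / 2) * (1 - eps) + (1 - dosage / 2) * eps

# log-likelihood of (ref, alt) counts under alt probabilities p (vector over
# SNPs): sum alt*log(p) + ref*log(1-p)
.ll_counts <- function(ref, alt, p) sum(alt * log(p) + ref * log1p(-p))

#' Assign a cell to a donor from known genotypes
#'
#' Per-donor log-likelihood of the cell's allele observations: each read
#' allele is alt with probability \code{(dosage/2)(1-e) + (1-dosage/2)e}
#' where \code{e} is the allele error rate. All 50/50 two-donor doublet
#' models are also scored (mixture alt probability = mean of the two donor
#' probabilities). The call is \code{"doublet"} when the best pair beats
#' the best single donor by more than \code{doublet_margin} log-units, and
#' \code{"ambiguous"} when the top two single donors are within 2 log-units
#' (or no informative SNP was observed).
#'
#' @param obs data.table for one cell: \code{snp_id}, \code{ref_count},
#'   \code{alt_count}.
#' @param genotypes a \code{\link{make_genotypes}}-style
#'   \code{genotype_set}.
#' @param error_rate allele error rate (default 0.01).
#' @param doublet_margin log-likelihood margin for the doublet call
#'   (default 2).
#' @return List: \code{donor} (name, \code{"doublet"} or
#'   \code{"ambiguous"}), \code{status}, \code{log_lik} (per donor),
#'   \code{best_pair}, \code{pair_log_lik}.
#' @export
assign_by_genotype <- function(obs, genotypes, error_rate = 0.01,
                               doublet_margin = 2) {
  G <- genotypes$dosage
  m <- match(obs$snp_id, colnames(G))
  keep <- !is.na(m) & (obs$ref_count + obs$alt_count) > 0
  obs <- obs[keep]; m <- m[keep]
  donors <- rownames(G)
  if (nrow(obs) == 0L)
    return(list(donor = "ambiguous", status = "ambiguous",
                log_lik = setNames(rep(NA_real_, nrow(G)), donors),
                best_pair = NULL, pair_log_lik = NA_real_))
  P <- .p_alt(G[, m, drop = FALSE], error_rate)  # donors x observed SNPs
  ll <- vapply(seq_len(nrow(G)), function(d)
    .ll_counts(obs$ref_count, obs$alt_count, P[d, ]), numeric(1))
  names(ll) <- donors
  best <- which.max(ll)
  pair_ll <- -Inf; best_pair <- NULL
  if (nrow(G) >= 2) {
    for (a in seq_len(nrow(G) - 1)) for (b in seq(a + 1, nrow(G))) {
      pm <- (P[a, ] + P[b, ]) / 2
      v <- .ll_counts(obs$ref_count, obs$alt_count, pm)
      if (v > pair_ll) { pair_ll <- v; best_pair <- donors[c(a, b)] }
    }
  }
  sorted <- sort(ll, decreasing = TRUE)
  status <- if (pair_ll > max(ll) + doublet_margin) "doublet"
            else if (length(sorted) >= 2 && sorted[1] - sorted[2] < 2) "ambiguous"
            else "singlet"
  donor <- switch(status, doublet = "doublet", ambiguous = "ambiguous",
                  donors[best])
  list(donor = donor, status = status, log_lik = ll,
       best_pair = best_pair, pair_log_lik = pair_ll)
}

#' Demultiplex a whole pool against known genotypes
#'
#' @param obs data.table over all cells: \code{cell_id}, \code{snp_id},
#'   \code{ref_count}, \code{alt_count}.
#' @param genotypes a \code{genotype_set}.
#' @param error_rate,doublet_margin see \code{\link{assign_by_genotype}}.
#' @return data.table with one row per cell: \code{cell_id}, \code{donor},
#'   \code{status}, plus per-donor log-likelihood columns \code{ll_<donor>}.
#' @export
demux_pool <- function(obs, genotypes, error_rate = 0.01, doublet_margin = 2) {
  obs <- data.table::as.data.table(obs)
  cells <- unique(obs$cell_id)
  res <- lapply(cells, function(cid) {
    r <- assign_by_genotype(obs[cell_id == cid], genotypes,
                            error_rate, doublet_margin)
    row <- data.table::data.table(cell_id = cid, donor = r$donor,
                                  status = r$status)
    for (d in names(r$log_lik)) row[[paste0("ll_", d)]] <- r$log_lik[[d]]
    row
  })
  data.table::rbindlist(res)
}

#' Genotype-free clustering of allele observations (binomial EM)
#'
#' Fits a K-cluster mixture in which cluster \code{k} has an alt-allele
#' fraction per SNP; cells' (ref, alt) counts are binomial given their
#' cluster. EM with soft assignments; allele fractions get a light
#' Beta(1,1) smoothing for stability. The best of \code{n_restarts}
#' random initializations (by observed-data log-likelihood) is returned;
#' deterministic given \code{seed}.
#'
#' @param obs data.table: \code{cell_id}, \code{snp_id}, \code{ref_count},
#'   \code{alt_count}.
#' @param K number of clusters (>= 1).
#' @param n_restarts random restarts (default 5).
#' @param seed RNG seed.
#' @param max_iter,tol EM stopping rule.
#' @return List: \code{cluster} (named integer per cell), \code{freq}
#'   (K x SNP alt-fraction matrix), \code{log_lik}, \code{log_lik_trace}
#'   (for the winning restart; non-decreasing).
#' @export
cluster_by_alleles_em <- function(obs, K, n_restarts = 5, seed = 1,
                                  max_iter = 100, tol = 1e-6) {
  obs <- data.table::as.data.table(obs)
  cells <- sort(unique(obs$cell_id))
  snps <- sort(unique(obs$snp_id))
  if (K > length(cells)) stop("K exceeds number of cells")
  if (K < 1) stop("K must be >= 1")
  ALT <- matrix(0, length(cells), length(snps),
                dimnames = list(cells, snps))
  TOT <- ALT
  ci <- match(obs$cell_id, cells); si <- match(obs$snp_id, snps)
  ALT[cbind(ci, si)] <- ALT[cbind(ci, si)] + obs$alt_count
  TOT[cbind(ci, si)] <- TOT[cbind(ci, si)] + obs$ref_count + obs$alt_count
  REF <- TOT - ALT
  set.seed(seed)
  restart_seeds <- sample.int(2147483646L, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    # init: random soft responsibilities
    resp <- matrix(stats::runif(length(cells) * K), length(cells), K)
    resp <- resp / rowSums(resp)
    pi_k <- rep(1 / K, K)
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # M-step: smoothed alt fractions and mixing weights
      wa <- t(resp) %*% ALT          # K x SNP
      wt <- t(resp) %*% TOT
      f <- (wa + 1) / (wt + 2)
      pi_k <- colSums(resp) / length(cells)
      # E-step: binomial log-likelihood per cell x cluster
      llmat <- ALT %*% t(log(f)) + REF %*% t(log1p(-f))
      llmat <- sweep(llmat, 2, log(pi_k), "+")
      mx <- apply(llmat, 1, max)
      lse <- mx + log(rowSums(exp(llmat - mx)))
      resp <- exp(llmat - lse)
      ll <- sum(lse)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$log_lik)
      best <- list(cluster = setNames(max.col(resp), cells),
                   freq = f, log_lik = ll, log_lik_trace = trace)
  }
  best
}
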