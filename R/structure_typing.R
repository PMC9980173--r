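# Structure typing: embedding, hierarchical clustering into 3D genome
# structure types, lifespan staging of granule cells (S1-S5), and
# stage-abundance curves over age.

# top-fraction most variable bins (ties broken by ordinal); used before
# clustering to stabilize high-dimensional distances
.variable_bins <- function(values, top_frac = 0.5) {
  v <- apply(values, 2, stats::var)
  k <- max(1L, floor(top_frac * ncol(values)))
  order(-v, seq_along(v))[seq_len(k)]
}

#' Embed cells in 2D from the scA/B matrix
#'
#' PCA is always computed first; t-SNE or UMAP are run on the top principal
#' components with a fixed seed. PC1's sign is oriented so that the cells of
#' oldest age (or, failing ages, the last cells) score positive, making
#' layouts comparable across runs.
#'
#' @param mat a \code{\link{build_scab_matrix}} result (or plain matrix).
#' @param n_pcs number of principal components (reduced with a warning when
#'   fewer cells are available).
#' @param method \code{"pca"}, \code{"tsne"} or \code{"umap"}.
#' @param seed RNG seed for the stochastic embeddings.
#' @param perplexity t-SNE perplexity (reduced automatically for tiny
#'   cohorts).
#' @return List with \code{coords} (cells x 2), \code{pcs} (cells x
#'   \code{n_pcs} PCA scores) and \code{method}.
#' @export
embed_cells <- function(mat, n_pcs = 20, method = c("pca", "tsne", "umap"),
                        seed = 1, perplexity = 30) {
  method <- match.arg(method)
  values <- if (inherits(mat, "scab_matrix")) mat$values else as.matrix(mat)
  ages <- if (inherits(mat, "scab_matrix")) mat$meta$age else NULL
  if (nrow(values) < 3) stop("need at least 3 cells to embed")
  max_pcs <- min(nrow(values) - 1L, ncol(values))
  if (n_pcs > max_pcs) {
    warning("n_pcs reduced to ", max_pcs)
    n_pcs <- max_pcs
  }
  pc <- stats::prcomp(values, center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x
  # orient PC1: oldest cells positive
  ref <- if (!is.null(ages) && any(is.finite(ages))) {
    old <- which(ages >= stats::quantile(ages, 0.8, na.rm = TRUE))
    mean(scores[old, 1])
  } else mean(scores[seq(max(1, nrow(scores) - 4), nrow(scores)), 1])
  if (is.finite(ref) && ref < 0) scores[, 1] <- -scores[, 1]
  coords <- switch(method,
    pca = scores[, 1:2, drop = FALSE],
    tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE))
        stop("method 'tsne' requires the Rtsne package")
      px <- min(perplexity, floor((nrow(scores) - 1) / 3))
      set.seed(seed)
      Rtsne::Rtsne(scores, dims = 2, perplexity = px, pca = FALSE,
                   check_duplicates = FALSE)$Y
    },
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("method 'umap' requires the uwot package")
      uwot::umap(scores, n_neighbors = min(15, nrow(scores) - 1),
                 seed = seed)
    })
  rownames(coords) <- rownames(values)
  list(coords = coords, pcs = scores, method = method)
}

#' Cluster cells into 3D genome structure types
#'
#' Agglomerative (Ward) clustering of z-scored scA/B rows on the top 50\%
#' most variable bins; deterministic and invariant to cell order. When
#' \code{reference_labels} is supplied, cluster names are renamed to the
#' majority reference label within each cluster (ties broken alphabetically).
#'
#' @param mat a \code{\link{build_scab_matrix}} result (or matrix).
#' @param k number of types.
#' @param linkage \code{hclust} method; default \code{"ward.D2"}.
#' @param top_frac fraction of most-variable bins used.
#' @param reference_labels optional per-cell labels to name clusters by.
#' @return Character vector of type labels, one per cell.
#' @export
cluster_structure_types <- function(mat, k, linkage = "ward.D2",
                                    top_frac = 0.5, reference_labels = NULL) {
  values <- if (inherits(mat, "scab_matrix")) mat$values else as.matrix(mat)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(values)) stop("k exceeds number of cells")
  sel <- .variable_bins(values, top_frac)
  hc <- stats::hclust(stats::dist(values[, sel, drop = FALSE]),
                      method = linkage)
  cl <- stats::cutree(hc, k = k)
  labels <- paste0("type", cl)
  if (!is.null(reference_labels)) {
    for (g in unique(cl)) {
      tab <- sort(table(reference_labels[cl == g]), decreasing = TRUE)
      labels[cl == g] <- names(tab)[1]
    }
  }
  labels
}

#' Stage granule cells S1-S5 along the lifespan
#'
#' Hierarchical (Ward) clustering of granule-cell scA/B rows into \code{k}
#' clusters, which are then ordered S1..Sk by ascending mean donor age
#' (ties, or missing ages, fall back to mean PC1 with a warning).
#'
#' @param mat a \code{\link{build_scab_matrix}} of granule cells only.
#' @param k number of stages (default 5).
#' @param ages per-cell donor age; defaults to the matrix metadata ages.
#' @param top_frac fraction of most-variable bins used.
#' @return List with \code{stage} (factor \code{"S1"}..\code{"Sk"} per
#'   cell), \code{order} (cluster-to-stage map) and \code{hclust}.
#' @export
stage_granule_cells <- function(mat, k = 5, ages = NULL, top_frac = 0.5) {
  values <- if (inherits(mat, "scab_matrix")) mat$values else as.matrix(mat)
  if (is.null(ages) && inherits(mat, "scab_matrix")) ages <- mat$meta$age
  if (k > nrow(values)) stop("k exceeds number of cells")
  sel <- .variable_bins(values, top_frac)
  hc <- stats::hclust(stats::dist(values[, sel, drop = FALSE]),
                      method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  if (is.null(ages) || all(is.na(ages))) {
    warning("no ages supplied; ordering stages by mean PC1")
    pc1 <- stats::prcomp(values, center = TRUE, rank. = 1)$x[, 1]
    score <- tapply(pc1, cl, mean)
  } else {
    score <- tapply(ages, cl, mean, na.rm = TRUE)
  }
  ord <- order(score, as.integer(names(score)))
  stage_of <- integer(k)
  stage_of[as.integer(names(score))[ord]] <- seq_len(k)
  stage <- factor(paste0("S", stage_of[cl]),
                  levels = paste0("S", seq_len(k)))
  list(stage = stage, order = stage_of, hclust = hc)
}

#' Stage abundance across age
#'
#' At each age point, the fraction of cells in each stage; the per-stage
#' peak age is the argmax over the grid. Fractions at every age with at
#' least one cell sum to 1.
#'
#' @param stage per-cell stage labels (factor or character).
#' @param ages per-cell ages.
#' @param age_grid ages at which to evaluate; defaults to the sorted unique
#'   observed ages.
#' @return List with \code{curves} (data.table: age, stage, fraction,
#'   n_cells) and \code{peaks} (named vector of peak ages; \code{NA} for
#'   empty stages).
#' @export
stage_abundance <- function(stage, ages, age_grid = NULL) {
  stopifnot(length(stage) == length(ages))
  stage <- as.factor(stage)
  if (is.null(age_grid)) age_grid <- sort(unique(ages))
  curves <- data.table::rbindlist(lapply(age_grid, function(a) {
    idx <- which(ages == a)
    n <- length(idx)
    frac <- if (n) as.numeric(table(stage[idx]) / n)
            else rep(NA_real_, nlevels(stage))
    data.table::data.table(age = a, stage = levels(stage),
                           fraction = frac, n_cells = n)
  }))
  peaks <- vapply(levels(stage), function(s) {
    f <- curves[stage == s & n_cells > 0]
    if (nrow(f) == 0 || all(f$fraction == 0) || all(is.na(f$fraction)))
      return(NA_real_)
    f$age[which.max(f$fraction)]
  }, numeric(1))
  list(curves = curves, peaks = peaks)
}
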