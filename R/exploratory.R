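#' Principal component analysis of a spectra set
#'
#' Mean-centred PCA via singular value decomposition. Loadings rows are
#' orthonormal; explained-variance percentages are non-increasing and at
#' full rank `scores %*% loadings + mean` reconstructs the data.
#'
#' @param set a [spectra_set] with at least 2 spectra
#' @param n_pc number of components to keep (truncated to the data rank,
#'   with a warning, if too large)
#' @return a `spectra_pca` list: `scores` (n x n_pc), `loadings`
#'   (n_pc x n_points), `explained_variance_pct`, `mean_spectrum`, `meta`
#' @export
spectra_pca <- function(set, n_pc = 8L) {
  stopifnot(inherits(set, "spectra_set"), n_spectra(set) >= 2)
  X <- set$spectra
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  pos <- sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  r <- sum(pos)
  if (n_pc > r) {
    warning("n_pc = ", n_pc, " exceeds data rank ", r, "; truncating")
    n_pc <- r
  }
  keep <- seq_len(n_pc)
  var_all <- sv$d^2 / sum(sv$d^2)
  structure(list(
    scores = sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_pc),
    loadings = t(sv$v[, keep, drop = FALSE]),
    explained_variance_pct = 100 * var_all[keep],
    mean_spectrum = mu,
    wavenumbers = set$wavenumbers,
    meta = set$meta
  ), class = "spectra_pca")
}

#' Ward hierarchical clustering of spectra
#'
#' Agglomerative clustering on Euclidean distances with Ward's criterion
#' (the `ward.D2` convention: squared-distance Lance-Williams update on
#' unsquared input distances). Merge heights are non-decreasing.
#'
#' @param set a [spectra_set] with at least 2 spectra
#' @return an `hca_result`: `hclust` (the merge tree), `labels`
#'   (`<species>_<plant_id>` where available), `meta`
#' @export
hca_ward <- function(set) {
  stopifnot(inherits(set, "spectra_set"), n_spectra(set) >= 2)
  labels <- hca_labels(set$meta)
  d <- stats::dist(set$spectra, method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  hc$labels <- labels
  structure(list(hclust = hc, labels = labels, meta = set$meta),
            class = "hca_result")
}

hca_labels <- function(meta) {
  lab <- ifelse(!is.na(meta$species) & !is.na(meta$plant_id),
                paste(meta$species, meta$plant_id, sep = "_"),
                meta$spectrum_id)
  make.unique(lab, sep = "_")
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths derive from the Ward merge heights, so any standard
#' Newick reader reproduces the dendrogram topology.
#'
#' @param h an `hca_result`
#' @param path output file path
#' @return `path`, invisibly
#' @export
export_newick <- function(h, path) {
  stopifnot(inherits(h, "hca_result"))
  phy <- ape::as.phylo(h$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Majority-species purity of a dendrogram cut
#'
#' Cuts the tree into `k` clusters and reports, per cluster, the fraction
#' of its leaves carrying the majority species label, plus the mean
#' purity weighted by cluster size.
#'
#' @param h an `hca_result` whose leaves carry species labels
#' @param k number of clusters, `<=` leaf count
#' @return list with `per_cluster` (data frame: cluster, size, majority
#'   species, purity) and `mean_purity`
#' @export
cluster_purity <- function(h, k) {
  stopifnot(inherits(h, "hca_result"), k >= 1,
            k <= length(h$hclust$order))
  cl <- stats::cutree(h$hclust, k = k)
  species <- h$meta$species
  per <- do.call(rbind, lapply(sort(unique(cl)), function(g) {
    sp <- species[cl == g]
    tab <- sort(table(sp), decreasing = TRUE)
    data.frame(cluster = g, size = length(sp),
               majority = names(tab)[1],
               purity = as.numeric(tab[1]) / length(sp))
  }))
  list(per_cluster = per,
       mean_purity = sum(per$purity * per$size) / sum(per$size))
}
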