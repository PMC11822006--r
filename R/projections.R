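#' Normalize axon-projection profiles to unit length
#'
#' Each neuron's region-length row is scaled to unit total: by default each
#' row is divided by its sum so entries are length fractions summing to 1;
#' `method = "l2"` normalizes to unit Euclidean norm instead. All-zero rows
#' are excluded with a warning.
#'
#' @param matrix neurons x regions matrix of axon lengths (mm),
#'   non-negative.
#' @param method `"sum"` (default) or `"l2"`.
#' @return normalized matrix (possibly with fewer rows).
#' @export
normalize_profiles <- function(matrix, method = c("sum", "l2")) {
  method <- match.arg(method)
  m <- as.matrix(matrix)
  if (any(m < 0)) stopf("axon lengths must be non-negative")
  tot <- if (method == "sum") rowSums(m) else sqrt(rowSums(m^2))
  zero <- tot == 0
  if (any(zero)) {
    warnf("%d all-zero neuron row(s) excluded", sum(zero))
    m <- m[!zero, , drop = FALSE]
    tot <- tot[!zero]
  }
  if (nrow(m) == 0) stopf("no non-zero rows remain")
  m / tot
}

#' UMAP embedding and Ward clustering of projection profiles
#'
#' Computes a seeded 2-D UMAP embedding of the normalized profiles for
#' visualization, and cluster labels from agglomerative hierarchical
#' clustering (Ward linkage on Euclidean distances between the normalized
#' profiles themselves, not the embedding), with the tree cut at `k`
#' clusters.
#'
#' @param normalized neurons x regions normalized matrix
#'   ([normalize_profiles]).
#' @param n_neighbors UMAP nearest-neighbour count (default 20); must be
#'   smaller than the number of neurons.
#' @param k number of clusters to cut (default 2).
#' @param seed seed for the UMAP embedding.
#' @return list with `embedding` (neurons x 2), `labels` (integer cluster
#'   ids), and `hclust` (the dendrogram object).
#' @export
embed_and_cluster <- function(normalized, n_neighbors = 20, k = 2, seed = 1) {
  m <- as.matrix(normalized)
  if (nrow(m) < k + 1) stopf("need at least k + 1 = %d neurons", k + 1)
  if (n_neighbors >= nrow(m)) {
    stopf("n_neighbors (%d) must be smaller than the number of neurons (%d)",
          n_neighbors, nrow(m))
  }
  hc <- hclust(dist(m), method = "ward.D2")
  labels <- if (k == 1) rep(1L, nrow(m)) else cutree(hc, k = k)
  emb <- with_seed(seed, {
    uwot::umap(m, n_neighbors = n_neighbors, n_threads = 1,
               n_sgd_threads = 1, batch = TRUE)
  })
  list(embedding = emb, labels = as.integer(labels), hclust = hc)
}

#' Filter regions for display by mean projection length
#'
#' Keeps regions whose across-neuron mean axon length is at least
#' `min_mean_mm` (inclusive), to avoid plotting rare or minor projections.
#' Operates on raw (unnormalized) lengths.
#'
#' @param matrix neurons x regions raw length matrix (mm).
#' @param min_mean_mm minimum mean length (default 1 mm).
#' @return the retained columns of `matrix`.
#' @export
filter_display_regions <- function(matrix, min_mean_mm = 1) {
  m <- as.matrix(matrix)
  keep <- colMeans(m) >= min_mean_mm
  m[, keep, drop = FALSE]
}

#' Dendritic branch count and total length
#'
#' Counts dendritic branches (maximal unbranched paths between branch
#' points and terminals, over basal, apical and oblique segments) and sums
#' dendritic cable length.
#'
#' @param morph a [neuron_morphology].
#' @return list with `n_branches` and `total_length_um`.
#' @export
dendrite_summary <- function(morph) {
  stopifnot(inherits(morph, "neuron_morphology"))
  nodes <- morph$nodes
  dend_types <- c("basal", "apical", "oblique")
  is_dend <- nodes$type %in% dend_types
  if (!any(is_dend)) {
    warnf("no dendritic segments: zero branches")
    return(list(n_branches = 0L, total_length_um = 0))
  }
  # cable length: edge to parent, for every dendritic non-root node
  idx <- which(is_dend & nodes$parent != -1)
  par <- match(nodes$parent[idx], nodes$id)
  seg_len <- sqrt((nodes$x[idx] - nodes$x[par])^2 +
                  (nodes$y[idx] - nodes$y[par])^2 +
                  (nodes$z[idx] - nodes$z[par])^2)
  total <- sum(seg_len)
  # a branch starts at a dendritic node whose parent is a branch point
  # (>= 2 children), is non-dendritic (stem origin), or is the root
  children <- table(factor(nodes$parent, levels = nodes$id))
  n_children <- as.integer(children)
  names(n_children) <- nodes$id
  starts <- vapply(which(is_dend), function(i) {
    p <- nodes$parent[i]
    if (p == -1) return(TRUE)
    pi <- match(p, nodes$id)
    !(nodes$type[pi] %in% dend_types) || n_children[as.character(p)] >= 2
  }, logical(1))
  list(n_branches = sum(starts), total_length_um = total)
}
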