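#' Batch-balanced k-nearest-neighbour graph
#'
#' For every cell, its `k_per_batch` nearest neighbours are found *within each
#' batch separately* (its own batch included, itself excluded), so that each
#' neighbourhood is balanced across batches by construction. Distances are
#' attached and connectivities derived via [connectivities_from_distances()].
#'
#' @param embedding Numeric cells x d matrix.
#' @param batch_labels Per-cell batch label.
#' @param k_per_batch Neighbours requested per batch (fewer if a batch has
#'   fewer cells available).
#' @param connectivity_mode Kernel passed to [connectivities_from_distances()].
#' @return A directed [NeighborGraph] with symmetric connectivity values on
#'   each edge; every cell has exactly `k_per_batch` out-edges per batch
#'   (capped by batch size).
#' @export
bbknn_graph <- function(embedding, batch_labels, k_per_batch = 3L,
                        connectivity_mode = "umap_fuzzy_union") {
  embedding <- as.matrix(embedding)
  batch_labels <- as_ordered_factor(batch_labels)
  n <- nrow(embedding)
  stopifnot(length(batch_labels) == n, k_per_batch >= 1L)
  idx_by_batch <- lapply(levels(batch_labels), function(b) which(batch_labels == b))
  src <- dst <- integer(0); dd <- numeric(0)
  for (ix in idx_by_batch) {
    d2 <- cross_dist2(embedding, embedding[ix, , drop = FALSE])
    for (i in seq_len(n)) {
      di <- d2[i, ]
      self <- which(ix == i)
      if (length(self)) di[self] <- Inf
      kk <- min(k_per_batch, length(ix) - length(self))
      if (kk < 1L) next
      nb <- order(di, ix)[seq_len(kk)]   # distance ties -> lower cell index
      src <- c(src, rep(i, kk))
      dst <- c(dst, ix[nb])
      dd <- c(dd, sqrt(di[nb]))
    }
  }
  g <- NeighborGraph(data.frame(src = src, dst = dst, distance = dd),
                     n_cells = n, k = k_per_batch * nlevels(batch_labels),
                     directed = TRUE)
  connectivities_from_distances(g, mode = connectivity_mode)
}

#' Wrap BBKNN as an integration method on a dataset
#'
#' @param ds A [CellDataset] with at least one embedding.
#' @param use Embedding name (default: first embedding).
#' @param k_per_batch Neighbours per batch.
#' @return An [IntegrationOutput] of kind `"graph"`.
#' @export
bbknn_integrate <- function(ds, use = NULL, k_per_batch = 3L) {
  if (!length(ds$embeddings)) stop("bbknn needs an embedding; add one (e.g. PCA) first")
  use <- use %||% names(ds$embeddings)[1]
  g <- bbknn_graph(ds$embeddings[[use]], ds$batch, k_per_batch = k_per_batch)
  IntegrationOutput("bbknn", "graph", g,
                    params = list(use = use, k_per_batch = k_per_batch))
}
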