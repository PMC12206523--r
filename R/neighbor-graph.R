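#' Sparse k-nearest-neighbour graph
#'
#' Stores a kNN structure as an edge table with per-edge Euclidean distances
#' and, once computed, connectivities in (0, 1]. Directed graphs keep each
#' cell's out-edges to its selected neighbours; undirected graphs store each
#' unordered pair once.
#'
#' @param edges `data.frame` with integer columns `src`, `dst` (1-based cell
#'   indices), numeric `distance` and optionally `connectivity`.
#' @param n_cells Number of cells covered by the graph.
#' @param k Target number of neighbours per cell (informational).
#' @param directed Logical; `FALSE` means each row represents a symmetric edge.
#' @return A `NeighborGraph` object.
#' @export
NeighborGraph <- function(edges, n_cells, k = NA_integer_, directed = TRUE) {
  stopifnot(is.data.frame(edges),
            all(c("src", "dst", "distance") %in% names(edges)))
  if (!"connectivity" %in% names(edges)) edges$connectivity <- NA_real_
  edges <- edges[, c("src", "dst", "distance", "connectivity")]
  edges$src <- as.integer(edges$src)
  edges$dst <- as.integer(edges$dst)
  g <- structure(list(edges = edges, n_cells = as.integer(n_cells),
                      k = as.integer(k), directed = isTRUE(directed)),
                 class = "NeighborGraph")
  validate_neighbor_graph(g)
  g
}

validate_neighbor_graph <- function(g) {
  e <- g$edges
  if (nrow(e)) {
    if (any(e$src == e$dst)) stop("NeighborGraph contains self-edges")
    if (any(e$src < 1L | e$src > g$n_cells | e$dst < 1L | e$dst > g$n_cells)) {
      stop("edge endpoints outside 1..n_cells")
    }
    if (any(e$distance < 0)) stop("negative edge distance")
    conn <- e$connectivity
    if (any(!is.na(conn)) && any(is.na(conn))) {
      stop("connectivities must be present for every edge or for none")
    }
    if (any(!is.na(conn)) && (any(conn <= 0) || any(conn > 1))) {
      stop("connectivities must lie in (0, 1]")
    }
  }
  invisible(g)
}

#' @export
print.NeighborGraph <- function(x, ...) {
  cat(sprintf("NeighborGraph: %d cells, %d %s edges (k = %s)%s\n",
              x$n_cells, nrow(x$edges),
              if (x$directed) "directed" else "undirected",
              x$k,
              if (has_connectivities(x)) ", with connectivities" else ""))
  invisible(x)
}

#' @rdname NeighborGraph
#' @param g A `NeighborGraph`.
#' @export
has_connectivities <- function(g) nrow(g$edges) > 0 && !anyNA(g$edges$connectivity)

# apply an index map to all endpoints (used by permute_cells)
relabel_graph <- function(g, map) {
  e <- g$edges
  e$src <- map[e$src]
  e$dst <- map[e$dst]
  NeighborGraph(e, g$n_cells, g$k, g$directed)
}

# squared Euclidean cross-distances, guarded against negative round-off
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Exact k-nearest-neighbour graph from an embedding
#'
#' Brute-force exact search (block-wise full distance computation). Ties at
#' equal distance are broken in favour of the lower cell index, which makes the
#' edge set fully deterministic.
#'
#' @param embedding Numeric cells x d matrix.
#' @param k Number of neighbours per cell; must be `< nrow(embedding)`.
#' @param metric Distance metric; only `"euclidean"` is supported.
#' @param block Number of query rows processed per block.
#' @return A directed [NeighborGraph] in which every cell has exactly `k`
#'   out-edges, ordered by increasing distance.
#' @export
knn_graph <- function(embedding, k, metric = "euclidean", block = 512L) {
  metric <- match.arg(metric, "euclidean")
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) stop(sprintf("k (%d) must be smaller than the number of cells (%d)", k, n))
  if (k < 1L) stop("k must be >= 1")
  src <- dst <- integer(n * k)
  dist_out <- numeric(n * k)
  pos <- 0L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- cross_dist2(embedding[idx, , drop = FALSE], embedding)
    for (r in seq_along(idx)) {
      i <- idx[r]
      di <- d2[r, ]
      di[i] <- Inf
      # order() with a secondary index key breaks distance ties by lower index
      nb <- order(di, seq_len(n))[seq_len(k)]
      sl <- pos + seq_len(k)
      src[sl] <- i
      dst[sl] <- nb
      dist_out[sl] <- sqrt(di[nb])
      pos <- pos + k
    }
  }
  NeighborGraph(data.frame(src = src, dst = dst, distance = dist_out),
                n_cells = n, k = k, directed = TRUE)
}

# list of per-source-cell edge row indices (sorted by distance, tie by dst)
out_edge_rows <- function(g) {
  e <- g$edges
  ord <- order(e$src, e$distance, e$dst)
  split(ord, factor(e$src[ord], levels = seq_len(g$n_cells)))
}

#' Convert edge distances into connectivities
#'
#' Two kernels are provided; the choice of distance-to-connectivity kernel is a
#' documented interpretation (see the methods vignette) and both yield weights
#' in (0, 1] that decrease with distance.
#'
#' * `gaussian_adaptive`: per source cell `i`, a Gaussian kernel
#'   `w_ij = exp(-d_ij^2 / sigma_i^2)` with adaptive bandwidth `sigma_i` equal
#'   to the distance to the `ceiling(k/2)`-th nearest neighbour; weights are
#'   then symmetrised by the maximum over the two directions.
#' * `umap_fuzzy_union`: per-cell local scaling in the UMAP style — the nearest
#'   neighbour is pinned to weight 1 and a per-cell scale is found by binary
#'   search so that the weights sum to `log2(degree)`; directed memberships `a`
#'   and `b = t(a)` are combined by the fuzzy union `a + b - a*b`.
#'
#' @param g A [NeighborGraph] with distances.
#' @param mode `"gaussian_adaptive"` or `"umap_fuzzy_union"`.
#' @param sigma_rank Neighbour rank used as the adaptive bandwidth for
#'   `gaussian_adaptive`; defaults to `ceiling(k/2)`.
#' @return A [NeighborGraph] with the same directed edge set and a symmetric
#'   `connectivity` value attached to every edge (`w_ij == w_ji`).
#' @export
connectivities_from_distances <- function(g,
                                          mode = c("gaussian_adaptive", "umap_fuzzy_union"),
                                          sigma_rank = NULL) {
  mode <- match.arg(mode)
  if (nrow(g$edges) == 0L) stop("graph has no edges")
  e <- g$edges
  rows_by_src <- out_edge_rows(g)
  w <- numeric(nrow(e))
  if (mode == "gaussian_adaptive") {
    if (is.null(sigma_rank)) sigma_rank <- ceiling(max(1L, g$k, na.rm = TRUE) / 2)
    for (rows in rows_by_src) {
      if (!length(rows)) next
      d <- e$distance[rows]
      sigma <- d[min(length(d), sigma_rank)]
      if (sigma <= 0) sigma <- 1e-12
      w[rows] <- exp(-(d / sigma)^2)
    }
  } else {
    for (rows in rows_by_src) {
      if (!length(rows)) next
      d <- e$distance[rows]
      rho <- d[1]
      target <- log2(max(2, length(d)))
      w[rows] <- smooth_knn_weights(d, rho, target)
    }
  }
  # symmetrise: w_ij <- max (gaussian) or fuzzy union (umap) of the two directions
  key <- paste(e$src, e$dst)
  rev_idx <- match(paste(e$dst, e$src), key)
  w_rev <- ifelse(is.na(rev_idx), 0, w[rev_idx])
  w_sym <- if (mode == "gaussian_adaptive") pmax(w, w_rev) else w + w_rev - w * w_rev
  w_sym <- pmin(w_sym, 1)
  w_sym[w_sym <= 0] <- 1e-300
  e$connectivity <- w_sym
  NeighborGraph(e, g$n_cells, g$k, g$directed)
}

# binary search for the per-cell scale of the UMAP membership kernel
smooth_knn_weights <- function(d, rho, target, n_iter = 64L, tol = 1e-5) {
  dd <- pmax(d - rho, 0)
  if (all(dd == 0)) return(rep(1, length(d)))
  lo <- 0; hi <- Inf; sigma <- 1
  for (it in seq_len(n_iter)) {
    s <- sum(exp(-dd / sigma))
    if (abs(s - target) < tol) break
    if (s > target) {
      hi <- sigma
      sigma <- (lo + sigma) / 2
    } else {
      lo <- sigma
      sigma <- if (is.finite(hi)) (sigma + hi) / 2 else sigma * 2
    }
  }
  exp(-dd / sigma)
}

#' Collapse a directed graph to its undirected union
#'
#' @param g A [NeighborGraph].
#' @return An undirected [NeighborGraph]; each unordered pair is kept once with
#'   the minimum distance and (if present) maximum connectivity over the
#'   directions in which it occurred.
#' @export
symmetrize_graph <- function(g) {
  if (!g$directed) return(g)
  e <- g$edges
  a <- pmin(e$src, e$dst); b <- pmax(e$src, e$dst)
  key <- paste(a, b)
  first <- !duplicated(key)
  dist_min <- tapply(e$distance, key, min)
  ek <- key[first]
  out <- data.frame(src = a[first], dst = b[first],
                    distance = as.numeric(dist_min[ek]))
  if (has_connectivities(g)) {
    conn_max <- tapply(e$connectivity, key, max)
    out$connectivity <- as.numeric(conn_max[ek])
  }
  NeighborGraph(out, g$n_cells, g$k, directed = FALSE)
}

as_igraph <- function(g, use_connectivities = FALSE) {
  e <- g$edges
  ig <- igraph::graph_from_edgelist(cbind(e$src, e$dst), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$n_cells - igraph::vcount(ig)))
  if (use_connectivities) igraph::E(ig)$weight <- rep(e$connectivity, length.out = igraph::ecount(ig))
  igraph::simplify(ig, edge.attr.comb = "max")
}

#' Connected components of a (masked) neighbour graph
#'
#' Treats the graph as undirected; edges leaving the mask are ignored.
#'
#' @param g A [NeighborGraph].
#' @param cell_mask Logical vector of length `n_cells`, or integer indices of
#'   the cells to keep. Default: all cells.
#' @return Integer component label (1-based, ordered by first occurrence) per
#'   masked cell, in mask order.
#' @export
connected_components <- function(g, cell_mask = NULL) {
  if (is.null(cell_mask)) cell_mask <- seq_len(g$n_cells)
  if (is.logical(cell_mask)) cell_mask <- which(cell_mask)
  if (!length(cell_mask)) stop("cell_mask selects no cells")
  pos <- integer(g$n_cells)
  pos[cell_mask] <- seq_along(cell_mask)
  e <- g$edges
  keep <- pos[e$src] > 0L & pos[e$dst] > 0L
  ig <- igraph::graph_from_edgelist(
    cbind(pos[e$src[keep]], pos[e$dst[keep]]), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, length(cell_mask) - igraph::vcount(ig)))
  comp <- igraph::components(ig)$membership
  as.integer(match(comp, unique(comp)))
}
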