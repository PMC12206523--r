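# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops and textbook formulas only.

# exact kNN by full sort per cell; ties at equal distance -> lower index
brute_knn_edges <- function(emb, k) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  out <- NULL
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nb <- order(di, seq_len(n))[seq_len(k)]
    out <- rbind(out, data.frame(src = i, dst = nb))
  }
  out
}

edge_key <- function(e) sort(paste(e$src, e$dst))

# breadth-first search components over an undirected edge list
bfs_components <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges$src[r]; b <- edges$dst[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(n); cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

# silhouette widths straight from the definition (O(n^2))
brute_silhouette <- function(x, labels) {
  labels <- as.character(labels)
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# mutual information / entropies by direct summation over the joint table
nmi_direct <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  mi <- 0
  for (ai in unique(a)) for (bi in unique(b)) {
    pj <- sum(a == ai & b == bi) / n
    if (pj > 0) mi <- mi + pj * log(pj / (mean(a == ai) * mean(b == bi)))
  }
  ent <- function(l) {
    p <- table(l) / length(l)
    -sum(p * log(p))
  }
  ha <- ent(a); hb <- ent(b)
  if (ha == 0 && hb == 0) return(1)
  if (ha + hb == 0) return(0)
  mi / ((ha + hb) / 2)
}

# ARI by brute-force enumeration of all cell pairs
ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  tot <- choose(n, 2)
  index <- n11
  expected <- (n11 + n10) * (n11 + n01) / tot
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected) return(as.numeric(index == maximum))
  (index - expected) / (maximum - expected)
}

# small labelled Gaussian-mixture fixture in 2-D
make_mix_embedding <- function(n_per = 20, centers = rbind(c(0, 0), c(4, 4)),
                               sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    k <- nrow(centers)
    x <- do.call(rbind, lapply(seq_len(k), function(j) {
      cbind(rnorm(n_per, centers[j, 1], sd), rnorm(n_per, centers[j, 2], sd))
    }))
    list(x = x, label = rep(sprintf("c%d", seq_len(k)), each = n_per))
  })
}

# a graph with specified neighbour sets at unit distances
graph_from_neighbours <- function(nbrs, n_cells = NULL, distances = NULL) {
  src <- rep(seq_along(nbrs), lengths(nbrs))
  dst <- unlist(nbrs)
  d <- if (is.null(distances)) rep(1, length(dst)) else unlist(distances)
  NeighborGraph(data.frame(src = src, dst = dst, distance = d),
                n_cells = n_cells %||% max(src, dst),
                k = max(lengths(nbrs)), directed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny full dataset used by IO and pipeline tests
make_tiny_dataset <- function(seed = 1, n_per_batch = 8, n_genes = 6) {
  withr::with_seed(seed, {
    n <- 2 * n_per_batch
    counts <- matrix(rpois(n * n_genes, 5), n, n_genes,
                     dimnames = list(sprintf("bc%02d", 1:n),
                                     sprintf("g%d", 1:n_genes)))
    emb <- matrix(rnorm(n * 3), n, 3)
    rownames(emb) <- rownames(counts)
    g <- knn_graph(emb, k = 3)
    CellDataset(
      layers = list(counts = counts, data = log1p(counts)),
      batch = rep(c("A", "B"), each = n_per_batch),
      celltype = rep(c("t1", "t2"), n_per_batch),
      embeddings = list(pca = emb),
      graphs = list(knn = g),
      var_features = rep(c(TRUE, FALSE), length.out = n_genes)
    )
  })
}
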