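# --- NMI / ARI ---------------------------------------------------------------

test_that("nmi spans its analytic extremes", {
  a <- c("a", "a", "b", "b")
  expect_equal(nmi(a, a)$raw, 1, tolerance = 1e-12)
  expect_equal(nmi(a, c("x", "y", "x", "y"))$raw, 0, tolerance = 1e-12)
  expect_equal(nmi(rep("one", 6), rep("z", 6))$raw, 1)  # both single-cluster
  expect_error(nmi(a, a[1:3]), "length")
})

test_that("nmi and ari match direct-formula oracles on random partitions", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      a <- sample(letters[1:4], 100, replace = TRUE)
      b <- sample(LETTERS[1:3], 100, replace = TRUE)
    })
    expect_equal(nmi(a, b)$raw, nmi_direct(a, b), tolerance = 1e-12)
    expect_equal(ari(a, b)$raw, ari_pairs(a, b), tolerance = 1e-10)
  }
})

test_that("ari covers the hand-enumerated and degenerate cases", {
  expect_equal(ari(c("a", "a", "b", "b"), c("x", "y", "x", "y"))$raw, -0.5)
  expect_equal(ari(1:6, 1:6)$raw, 1)
  expect_equal(ari(rep("one", 8), rep(c("p", "q"), 4))$raw, 0)
})

test_that("nmi and ari are symmetric and renaming-invariant", {
  skip_if_not_installed("mclust")
  for (seed in 21:25) {
    withr::with_seed(seed, {
      a <- sample(3, 60, replace = TRUE)
      b <- sample(4, 60, replace = TRUE)
    })
    expect_equal(nmi(a, b)$raw, nmi(b, a)$raw, tolerance = 1e-12)
    expect_equal(ari(a, b)$raw, ari(b, a)$raw, tolerance = 1e-12)
    expect_equal(ari(a, b)$raw, mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-10)
    renamed <- c("zz", "q", "f")[a]
    expect_equal(nmi(renamed, b)$raw, nmi(a, b)$raw, tolerance = 1e-12)
  }
})

# --- clustering pre-step -----------------------------------------------------

test_that("cluster_for_labels recovers well-separated cliques", {
  mix <- make_mix_embedding(15, centers = rbind(c(0, 0), c(20, 0), c(0, 20)),
                            sd = 0.5, seed = 31)
  g <- knn_graph(mix$x, 5)
  part <- cluster_for_labels(g, mix$label, resolutions = c(0.5, 1))
  expect_equal(nmi(part, mix$label)$raw, 1, tolerance = 1e-12)
  expect_true(attr(part, "resolution") %in% c(0.5, 1))
  # determinism under a fixed seed
  part2 <- cluster_for_labels(g, mix$label, resolutions = c(0.5, 1))
  expect_identical(as.integer(part), as.integer(part2))
  expect_error(cluster_for_labels(g, mix$label, resolutions = numeric(0)),
               "non-empty")
})

# --- cell-type ASW -----------------------------------------------------------

test_that("celltype_asw reproduces the 1-D two-cluster fixture", {
  emb <- matrix(c(0, 1, 10, 11), ncol = 1)
  ct <- c("A", "A", "B", "B")
  res <- celltype_asw(emb, ct)
  # s(0) = (10.5-1)/10.5, s(1) = (9.5-1)/9.5, symmetric for the other cluster
  expected_raw <- (9.5 / 10.5 + 8.5 / 9.5) / 2
  expect_equal(res$raw, expected_raw, tolerance = 1e-10)
  expect_equal(res$scaled, (expected_raw + 1) / 2, tolerance = 1e-10)
  # coincident clusters -> scaled ~ 0.5
  withr::with_seed(32, embc <- matrix(rnorm(80), 40, 2))
  resc <- celltype_asw(embc, rep(c("A", "B"), 20))
  expect_equal(resc$scaled, 0.5, tolerance = 0.1)
})

test_that("celltype_asw matches the brute-force silhouette oracle", {
  for (seed in 33:35) {
    withr::with_seed(seed, {
      emb <- matrix(rnorm(30 * 3), 30, 3)
      ct <- sample(c("x", "y", "z"), 30, replace = TRUE)
    })
    expect_equal(celltype_asw(emb, ct)$raw, mean(brute_silhouette(emb, ct)),
                 tolerance = 1e-10)
  }
})

# --- graph connectivity ------------------------------------------------------

test_that("graph_connectivity scores label-induced components", {
  # labels: cells 1-4 'A' (path, connected), 5-8 'B' (3+1 split)
  nbrs <- list(2, c(1, 3), c(2, 4), 3, c(6, 7), c(5, 7), c(5, 6), 1)
  g <- graph_from_neighbours(nbrs, n_cells = 8)
  ct <- rep(c("A", "B"), each = 4)
  res <- graph_connectivity(g, ct)
  expect_equal(unname(res$detail["A"]), 1)
  expect_equal(unname(res$detail["B"]), 0.75)
  expect_equal(res$raw, 0.875)
  # singleton labels are trivially connected
  res2 <- graph_connectivity(g, c(rep("A", 7), "solo"))
  expect_equal(unname(res2$detail["solo"]), 1)
  # with a single label, raw is the largest component's share of all cells,
  # and equals 1 iff the whole graph is connected
  comp_all <- connected_components(g)
  expect_equal(graph_connectivity(g, rep("all", 8))$raw,
               max(tabulate(comp_all)) / 8)
  expect_equal(graph_connectivity(g, rep("all", 8))$raw == 1,
               max(comp_all) == 1)
})

# --- scGraph -----------------------------------------------------------------

test_that("scgraph is exact on rigid motions and reversed ranks", {
  withr::with_seed(41, {
    emb <- matrix(rnorm(80 * 2), 80, 2)
    ct <- rep(c("t1", "t2", "t3", "t4"), 20)
    batch <- rep(c("b1", "b2"), each = 40)
  })
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rigid <- sweep(emb %*% rot * 3, 2, c(5, -2), "+")
  expect_equal(scgraph(emb, rigid, ct, batch)$scaled, 1, tolerance = 1e-12)
  expect_equal(scgraph(emb, emb, ct, batch)$scaled, 1, tolerance = 1e-12)
})

test_that("scgraph matches a rank-correlation oracle on set centroids", {
  # 4 types on a line in the reference; integrated space reverses the
  # pairwise-distance ranks
  ct <- rep(c("a", "b", "c", "d"), each = 3)
  batch <- rep("b1", 12)
  ref_centers <- c(0, 1, 3, 7)
  int_centers <- c(0, 40, 60, 70)   # constructed so distance ranks reverse
  ref <- matrix(rep(ref_centers, each = 3), ncol = 1)
  int <- matrix(rep(int_centers, each = 3), ncol = 1)
  d_ref <- as.vector(dist(ref_centers))
  d_int <- as.vector(dist(int_centers))
  expected <- cor(d_ref, d_int, method = "spearman")
  expect_equal(scgraph(ref, int, ct, batch)$raw, expected, tolerance = 1e-12)
  # exactly reversed distance ranks -> raw -1, scaled 0
  ct3 <- rep(c("a", "b", "c"), each = 2)
  ref3 <- matrix(rep(c(0, 1, 3), each = 2), ncol = 1)
  int3 <- matrix(rep(c(0, 3, 1), each = 2), ncol = 1)
  rev_res <- scgraph(ref3, int3, ct3, rep("b1", 6))
  expect_equal(rev_res$raw, -1, tolerance = 1e-12)
  expect_equal(rev_res$scaled, 0, tolerance = 1e-12)
  # fewer than 3 types anywhere -> missing
  expect_warning(r <- scgraph(ref, int, rep(c("a", "b"), 6), batch), "3 cell types")
  expect_true(is.na(r$raw))
})

test_that("scgraph ignores batches with fewer than three cell types", {
  withr::with_seed(42, emb <- matrix(rnorm(60 * 2), 60, 2))
  ct <- c(rep(c("a", "b", "c"), 10), rep(c("a", "b"), 15))
  batch <- rep(c("full", "sparse"), each = 30)
  res <- scgraph(emb, emb * 2 + 1, ct, batch)
  expect_true(is.na(res$detail["sparse"]))
  expect_equal(unname(res$detail["full"]), 1)
})

# --- gene-set scores and cell-cycle conservation -----------------------------

test_that("score_gene_set behaves like a module score", {
  withr::with_seed(51, {
    x <- matrix(rnorm(100 * 200, mean = 5), 100, 200,
                dimnames = list(NULL, sprintf("gene%03d", 1:200)))
  })
  ds <- CellDataset(list(data = x), batch = rep("b", 100))
  set <- sprintf("gene%03d", 1:5)
  s0 <- score_gene_set(ds, "data", set, n_bins = 10, seed = 1)
  expect_lt(abs(mean(s0)), 0.2)          # uniform data -> scores ~ 0
  # shift the set genes in half the cells
  x2 <- x; x2[1:50, set] <- x2[1:50, set] + 5
  ds2 <- CellDataset(list(data = x2), batch = rep("b", 100))
  s1 <- score_gene_set(ds2, "data", set, n_bins = 10, seed = 1)
  expect_gt(mean(s1[1:50]) - mean(s1[51:100]), 3)
  # seeded determinism
  expect_identical(s1, score_gene_set(ds2, "data", set, n_bins = 10, seed = 1))
  expect_error(score_gene_set(ds, "data", c("nope1", "nope2")), "no genes")
})

test_that("cell_cycle_conservation is 1 when integration preserves the program", {
  truth <- synthetic_truth(n_batches = 2, n_types = 3, cells_per_batch = 120,
                           n_genes = 150, cc_program = TRUE,
                           cc_amplitude = 3, m = 2, seed = 52)
  ds <- simulate_counts(truth)
  sets <- cc_gene_sets(truth)
  x_before <- scibench:::pca_embedding(ds$layers$data, 10)
  expect_equal(cell_cycle_conservation(ds, x_before, x_before,
                                       sets$s, sets$g2m, n_pcs = 10)$raw, 1)
  # an integration that wipes all structure scores 0
  withr::with_seed(53, noise <- matrix(rnorm(length(x_before)), nrow(x_before)))
  res0 <- cell_cycle_conservation(ds, x_before, noise * 1e-6,
                                  sets$s, sets$g2m, n_pcs = 10)
  expect_lt(res0$raw, 0.45)
  # oracle latent correction keeps the program's variance structure
  oracle <- oracle_integration(ds, truth)
  res <- cell_cycle_conservation(ds, ds$embeddings$latent_true,
                                 oracle$payload, sets$s, sets$g2m, n_pcs = 10)
  expect_gte(res$raw, 0.9)
})
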