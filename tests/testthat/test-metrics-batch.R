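# --- LISI --------------------------------------------------------------------

test_that("lisi reproduces analytic inverse Simpson values", {
  # one cell with 4 equidistant neighbours, labels {a,a,b,b} -> uniform
  # weights -> effective number of labels = 2
  g <- graph_from_neighbours(list(c(2, 3, 4, 5), 1, 1, 1, 1), n_cells = 5)
  labels <- c("x", "a", "a", "b", "b")
  r <- lisi(g, labels, perplexity = 4)
  expect_equal(r$detail[1], 2, tolerance = 1e-9)
  # all neighbours same label -> LISI 1
  labels2 <- c("x", "a", "a", "a", "a")
  r2 <- lisi(g, labels2, perplexity = 4)
  expect_equal(r2$detail[1], 1, tolerance = 1e-9)
  # weights (0.75, 0.25): 3 'a' + 1 'b' equidistant -> 1/(0.5625+0.0625) = 1.6
  labels3 <- c("x", "a", "a", "a", "b")
  r3 <- lisi(g, labels3, perplexity = 4)
  expect_equal(r3$detail[1], 1.6, tolerance = 1e-9)
})

test_that("lisi calibrates neighbour weights to the target perplexity", {
  withr::with_seed(1, d <- sort(abs(rnorm(30))))
  p <- scibench:::perplexity_weights(d, perplexity = 10)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(-sum(p * log2(p)), log2(10), tolerance = 1e-4)
  # degenerate equal distances -> uniform
  p0 <- scibench:::perplexity_weights(rep(2, 8), perplexity = 5)
  expect_equal(p0, rep(1 / 8, 8))
})

test_that("ilisi and clisi scale to [0,1] with the right polarity", {
  mix <- make_mix_embedding(40, centers = rbind(c(0, 0), c(0, 0)), seed = 2)
  well_mixed <- ilisi(mix$x, mix$label, perplexity = 15)
  expect_gt(well_mixed$scaled, 0.8)
  far <- make_mix_embedding(40, centers = rbind(c(0, 0), c(100, 100)), seed = 3)
  separated <- ilisi(far$x, far$label, perplexity = 15)
  expect_lt(separated$scaled, 0.05)
  # same embeddings read as cell types: purity is the mirror image
  expect_lt(clisi(mix$x, mix$label, perplexity = 15)$scaled, 0.2)
  expect_gt(clisi(far$x, far$label, perplexity = 15)$scaled, 0.95)
  expect_true(well_mixed$raw >= 1 &&
                well_mixed$raw <= nlevels(factor(mix$label)))
})

test_that("lisi is invariant under label renaming and warns on one level", {
  withr::with_seed(4, emb <- matrix(rnorm(60 * 2), 60, 2))
  lab <- rep(c("a", "b", "c"), 20)
  r1 <- lisi(emb, lab, perplexity = 10)
  r2 <- lisi(emb, setNames(c("zz", "q", "m"), c("a", "b", "c"))[lab],
             perplexity = 10)
  expect_equal(r1$raw, r2$raw, tolerance = 1e-12)
  expect_warning(r3 <- lisi(emb, rep("one", 60)), "single label")
  expect_equal(r3$raw, 1)
})

# --- kBET --------------------------------------------------------------------

test_that("kbet evaluates the textbook chi-squared case", {
  # neighbourhood (8,2) against global (0.5,0.5), k=10:
  # chi2 = (8-5)^2/5 + (2-5)^2/5 = 3.6, df=1, p ~ 0.0578 -> not rejected
  nbrs <- c(list(2:11), as.list(rep(1, 19)))
  g <- graph_from_neighbours(nbrs, n_cells = 20)
  batch <- rep(c("a", "b"), each = 10)   # global frequencies 0.5/0.5
  # cell 1's neighbourhood: cells 2..11 -> 9 'a' + 1 'b'; rebuild for (8,2)
  nbrs[[1]] <- c(2:9, 11:12)             # 8 'a' (2..9) + 2 'b' (11,12)
  g <- graph_from_neighbours(nbrs, n_cells = 20)
  r <- suppressWarnings(kbet(g, batch, alpha = 0.05))
  p1 <- r$detail[1]
  expect_equal(p1, pchisq(3.6, df = 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_gt(p1, 0.05)                    # not rejected at alpha = 0.05
})

test_that("kbet is 0 on exact global composition and ~1 on separation", {
  # every neighbourhood composed exactly at global frequencies
  batch <- rep(c("a", "b"), each = 10)
  nbrs <- lapply(1:20, function(i) setdiff(c(1:5, 11:15), i)[1:8])
  g <- graph_from_neighbours(nbrs, n_cells = 20)
  expect_equal(suppressWarnings(kbet(g, batch))$raw, 0)
  # fully separated batches
  far <- make_mix_embedding(100, centers = rbind(c(0, 0), c(50, 50)), seed = 5)
  gk <- knn_graph(far$x, 15)
  expect_gt(kbet(gk, far$label)$raw, 0.99)
})

test_that("kbet holds its level under an i.i.d.-label null", {
  withr::with_seed(6, {
    emb <- matrix(rnorm(1000 * 5), 1000, 5)
    batch <- sample(c("a", "b"), 1000, replace = TRUE)
  })
  g <- knn_graph(emb, 20)
  rej <- kbet(g, batch, alpha = 0.05)$raw
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(rej, 0.05 + 3 * se)
})

test_that("kbet warns when under-powered and rejects single batches", {
  withr::with_seed(7, emb <- matrix(rnorm(40), 20, 2))
  g <- knn_graph(emb, 3)
  batch <- c(rep("a", 19), "b")   # k * min(f) = 3 * 0.05 < 1
  expect_warning(kbet(g, batch), "under-powered")
  expect_error(kbet(g, rep("a", 20)), ">= 2 batches")
})

# --- PCR ---------------------------------------------------------------------

test_that("pcr_batch spans its analytic extremes", {
  batch <- rep(c("a", "b"), each = 10)
  x <- matrix(as.numeric(batch == "b"), ncol = 1)
  expect_equal(pcr_batch(x, batch, n_pcs = 1)$raw, 1, tolerance = 1e-12)
  withr::with_seed(8, {
    xr <- matrix(rnorm(400 * 4), 400, 4)
    br <- sample(c("a", "b"), 400, replace = TRUE)
  })
  expect_lt(pcr_batch(xr, br, n_pcs = 4)$raw, 0.02)
  expect_error(pcr_batch(matrix(1, 10, 2), rep(c("a", "b"), 5)), "constant")
})

test_that("pcr_batch equals the hand-computed variance-weighted R^2", {
  # two orthogonal PCs with known variances and batch R^2
  withr::with_seed(9, {
    batch <- rep(c("a", "b"), each = 50)
    pc1 <- as.numeric(batch == "b") * 4 + rnorm(100, sd = 0.5)
    pc2 <- rnorm(100, sd = 2)
    x <- cbind(pc1, pc2)
  })
  res <- pcr_batch(x, batch, n_pcs = 2)
  pc <- prcomp(x, center = TRUE)
  r2 <- apply(pc$x, 2, function(s) summary(lm(s ~ batch))$r.squared)
  vars <- pc$sdev^2
  expect_equal(res$raw, sum(vars * r2) / sum(vars), tolerance = 1e-10)
})

test_that("pcr_batch is invariant under orthogonal rotation", {
  withr::with_seed(10, {
    x <- matrix(rnorm(80 * 5), 80, 5)
    batch <- rep(c("a", "b"), 40)
    q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  })
  expect_equal(pcr_batch(x %*% q, batch, n_pcs = 5)$raw,
               pcr_batch(x, batch, n_pcs = 5)$raw, tolerance = 1e-8)
})

test_that("pcr_comparison measures removed batch variance", {
  withr::with_seed(11, {
    batch <- rep(c("a", "b"), each = 40)
    x <- matrix(rnorm(80 * 3), 80, 3)
    x[batch == "b", 1] <- x[batch == "b", 1] + 5
  })
  expect_equal(pcr_comparison(x, x, batch, 3)$scaled, 0)
  clean <- x; clean[batch == "b", 1] <- clean[batch == "b", 1] - 5
  expect_gt(pcr_comparison(x, clean, batch, 3)$scaled, 0.9)
})

test_that("combat integration achieves a high pcr_comparison score", {
  withr::with_seed(12, {
    n <- 150; G <- 20
    batch <- rep(c("a", "b"), each = n)
    x <- matrix(rnorm(2 * n * G), 2 * n, G)
    x[batch == "b", ] <- x[batch == "b", ] + 2
  })
  corrected <- combat_correct(x, batch)$corrected
  expect_gte(pcr_comparison(x, corrected, batch, n_pcs = 10)$scaled, 0.9)
})

# --- DPCA --------------------------------------------------------------------

test_that("dpca spans identical and disjoint batch distributions", {
  withr::with_seed(13, v <- rnorm(400))
  x <- matrix(c(v, v), ncol = 1)
  batch <- rep(c("a", "b"), each = 400)
  expect_gt(dpca(x, batch)$raw, 0.95)
  x2 <- matrix(c(v, v + 1000), ncol = 1)
  expect_lt(dpca(x2, batch)$raw, 0.01)
})

test_that("dpca matches the closed-form overlap of two unit normals", {
  withr::with_seed(14, {
    a <- rnorm(5000, 0, 1)
    b <- rnorm(5000, 3, 1)
  })
  x <- matrix(c(a, b), ncol = 1)
  batch <- rep(c("a", "b"), each = 5000)
  # closed form: 2 * pnorm(-1.5) ~ 0.1336 (absolute band: KDE smoothing
  # inflates the overlap slightly)
  expect_lt(abs(dpca(x, batch)$raw - 2 * pnorm(-1.5)), 0.02)
})

test_that("dpca is symmetric in batch order and warns on tiny batches", {
  withr::with_seed(15, {
    x <- matrix(rnorm(60 * 2), 60, 2)
    batch <- rep(c("a", "b"), 30)
  })
  r1 <- dpca(x, batch)$raw
  batch_flipped <- ifelse(batch == "a", "b", "a")
  expect_equal(dpca(x, batch_flipped)$raw, r1, tolerance = 1e-12)
  expect_warning(dpca(x, c(rep(c("a", "b"), 29), "a", "tiny")), "excluded")
})

# --- batch ASW ---------------------------------------------------------------

test_that("batch_asw matches the brute-force silhouette oracle", {
  withr::with_seed(16, {
    emb <- matrix(rnorm(40 * 2), 40, 2)
    batch <- sample(c("a", "b"), 40, replace = TRUE)
    ct <- rep(c("t1", "t2"), each = 20)
  })
  res <- batch_asw(emb, batch, ct)
  per_group <- sapply(c("t1", "t2"), function(g) {
    ix <- ct == g
    mean(1 - abs(brute_silhouette(emb[ix, ], batch[ix])))
  })
  expect_equal(res$raw, mean(per_group), tolerance = 1e-10)
})

test_that("batch_asw spans interleaved and separated batches", {
  mixed <- make_mix_embedding(100, centers = rbind(c(0, 0), c(0, 0)), seed = 17)
  ct <- rep("t1", 200)
  expect_gt(batch_asw(mixed$x, mixed$label, ct)$raw, 0.85)
  apart <- make_mix_embedding(100, centers = rbind(c(0, 0), c(100, 0)), seed = 18)
  expect_lt(batch_asw(apart$x, apart$label, ct)$raw, 0.05)
  # no eligible group -> missing
  expect_warning(r <- batch_asw(mixed$x, rep("a", 200), ct), "undefined")
  expect_true(is.na(r$raw))
})
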