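#' Metric result container
#'
#' Every metric returns a `MetricResult` carrying the raw statistic, an
#' oriented value scaled to \[0, 1\] (higher = better for the metric's
#' purpose), an optional per-cell/per-group detail vector, and the parameters
#' used, for reproducibility.
#'
#' @param name Metric name.
#' @param raw Raw statistic.
#' @param scaled Value in \[0, 1\] (may be `NA` when undefined).
#' @param detail Optional per-cell or per-group vector.
#' @param params Named list of parameters used.
#' @return A `MetricResult`.
#' @export
MetricResult <- function(name, raw, scaled = NA_real_, detail = NULL, params = list()) {
  if (!is.na(scaled) && (scaled < -1e-12 || scaled > 1 + 1e-12)) {
    stop(sprintf("scaled value %g of metric '%s' outside [0,1]", scaled, name))
  }
  structure(list(name = name, raw = raw,
                 scaled = if (is.na(scaled)) scaled else min(max(scaled, 0), 1),
                 detail = detail, params = params),
            class = "MetricResult")
}

#' @export
print.MetricResult <- function(x, ...) {
  cat(sprintf("MetricResult '%s': raw = %.6g, scaled = %.6g\n",
              x$name, x$raw, x$scaled))
  invisible(x)
}

# --- neighbourhood machinery shared by LISI ---------------------------------

# per-cell neighbour indices + distances, from a graph or an embedding
neighbourhoods <- function(x, k = NULL) {
  if (inherits(x, "NeighborGraph")) {
    rows <- out_edge_rows(x)
    e <- x$edges
    lapply(rows, function(r) list(idx = e$dst[r], d = e$distance[r]))
  } else {
    x <- as.matrix(x)
    k <- min(k %||% (nrow(x) - 1L), nrow(x) - 1L)
    g <- knn_graph(x, k)
    neighbourhoods(g)
  }
}

# Gaussian weights calibrated to a target perplexity by binary search on the
# precision beta; entropy measured in bits. Degenerate all-equal distances
# fall back to uniform weights.
perplexity_weights <- function(d, perplexity, tol = 1e-5, n_iter = 64L) {
  d2 <- d^2
  if (max(d2) - min(d2) < 1e-300) return(rep(1 / length(d), length(d)))
  d2 <- d2 - min(d2)
  target <- log2(min(perplexity, length(d)))
  beta <- 1; lo <- 0; hi <- Inf
  for (it in seq_len(n_iter)) {
    w <- exp(-beta * d2)
    p <- w / sum(w)
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    if (abs(h - target) < tol) break
    if (h > target) {               # too flat: increase precision
      lo <- beta
      beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- (lo + beta) / 2
    }
  }
  p
}

#' Local inverse Simpson's index (LISI)
#'
#' For each cell, neighbour weights are calibrated so that the Gaussian kernel
#' over squared neighbour distances has Shannon entropy `log2(perplexity)`.
#' Per-label probabilities are the summed weights, and the cell's LISI is the
#' inverse Simpson's index `1 / sum_b p_b^2` — the effective number of labels
#' in its neighbourhood, between 1 (pure) and the number of labels (perfectly
#' mixed).
#'
#' @param x A [NeighborGraph] with distances, or a cells x d embedding (a
#'   `3 * perplexity`-nearest-neighbour graph is then built).
#' @param labels Per-cell label (batch for iLISI, cell type for cLISI).
#' @param perplexity Neighbourhood calibration target (default 30).
#' @return A [MetricResult]; `raw` is the mean per-cell LISI, `detail` the
#'   per-cell values. `scaled` is left `NA` here; see [ilisi()] / [clisi()].
#' @export
lisi <- function(x, labels, perplexity = 30) {
  labels <- as_ordered_factor(labels)
  if (nlevels(labels) < 2L) {
    warning("single label level: LISI is 1 by definition")
    return(MetricResult("lisi", 1, detail = rep(1, length(labels)),
                        params = list(perplexity = perplexity)))
  }
  nb <- neighbourhoods(x, k = 3L * ceiling(perplexity))
  lab_int <- as.integer(labels)
  vals <- vapply(seq_along(nb), function(i) {
    h <- nb[[i]]
    if (!length(h$idx)) return(NA_real_)
    p <- perplexity_weights(h$d, perplexity)
    pb <- tapply(p, lab_int[h$idx], sum)
    1 / sum(pb^2)
  }, numeric(1))
  MetricResult("lisi", mean(vals, na.rm = TRUE), detail = vals,
               params = list(perplexity = perplexity, n_labels = nlevels(labels)))
}

#' Batch-mixing iLISI and cell-type cLISI
#'
#' `ilisi` rescales the mean LISI over batch labels to
#' `(mean - 1) / (B - 1)` (1 = perfect mixing); `clisi` rescales over
#' cell-type labels to `(C - mean) / (C - 1)` (1 = perfect purity).
#'
#' @inheritParams lisi
#' @return A [MetricResult] with both `raw` (mean LISI) and `scaled` set.
#' @export
ilisi <- function(x, labels, perplexity = 30) {
  labels <- as_ordered_factor(labels)
  r <- lisi(x, labels, perplexity)
  B <- nlevels(labels)
  scaled <- if (B > 1L) (r$raw - 1) / (B - 1) else NA_real_
  MetricResult("ilisi", r$raw, scaled = min(max(scaled, 0), 1),
               detail = r$detail, params = r$params)
}

#' @rdname ilisi
#' @export
clisi <- function(x, labels, perplexity = 30) {
  labels <- as_ordered_factor(labels)
  r <- lisi(x, labels, perplexity)
  C <- nlevels(labels)
  scaled <- if (C > 1L) (C - r$raw) / (C - 1) else NA_real_
  MetricResult("clisi", r$raw, scaled = min(max(scaled, 0), 1),
               detail = r$detail, params = r$params)
}

#' kBET: chi-squared test of local batch composition
#'
#' For every cell, the batch composition of its k-neighbourhood is compared to
#' the global batch frequencies with a Pearson chi-squared test
#' (`df = B - 1`). The raw value is the rejection rate at level `alpha`; the
#' oriented score is the acceptance rate `1 - rejection`.
#'
#' @param g A [NeighborGraph].
#' @param batch_labels Per-cell batch label.
#' @param alpha Test level (default 0.05).
#' @return A [MetricResult]; `raw` = rejection rate, `scaled` = acceptance
#'   rate, `detail` = per-cell p-values.
#' @export
kbet <- function(g, batch_labels, alpha = 0.05) {
  batch_labels <- as_ordered_factor(batch_labels)
  batch_labels <- droplevels(batch_labels)   # frequency-0 batches excluded
  B <- nlevels(batch_labels)
  if (B < 2L) stop("kBET needs >= 2 batches with non-zero frequency")
  f <- as.numeric(table(batch_labels)) / length(batch_labels)
  nb <- neighbourhoods(g)
  lab_int <- as.integer(batch_labels)
  k_min <- min(vapply(nb, function(h) length(h$idx), integer(1)))
  if (k_min * min(f) < 1) {
    warning("k * min(batch frequency) < 1: kBET is under-powered")
  }
  pvals <- vapply(seq_along(nb), function(i) {
    idx <- nb[[i]]$idx
    if (!length(idx)) return(NA_real_)
    k <- length(idx)
    obs <- tabulate(lab_int[idx], nbins = B)
    expd <- k * f
    stat <- sum((obs - expd)^2 / expd)
    stats::pchisq(stat, df = B - 1, lower.tail = FALSE)
  }, numeric(1))
  rejection <- mean(pvals < alpha, na.rm = TRUE)
  MetricResult("kbet", rejection, scaled = 1 - rejection, detail = pvals,
               params = list(alpha = alpha, k = g$k, n_batches = B))
}

# weighted per-component R^2 of PC scores on a design; shared by pcr_batch and
# cell-cycle conservation
pcr_core <- function(x, design, n_pcs) {
  x <- as.matrix(x)
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  vars <- pc$sdev[seq_len(n_pcs)]^2
  if (sum(vars) <= 0) stop("input matrix is constant: PCR undefined")
  keep <- vars > 0
  r2 <- vapply(which(keep), function(j) {
    fit <- stats::lm.fit(cbind(1, design), pc$x[, j])
    1 - sum(fit$residuals^2) / sum((pc$x[, j] - mean(pc$x[, j]))^2)
  }, numeric(1))
  sum(vars[keep] * r2) / sum(vars[keep])
}

#' Principal-component regression on batch
#'
#' PCA of the input, then per component the R^2 of regressing scores on the
#' batch indicator; the raw value is the variance-weighted mean R^2 — the
#' fraction of (retained) variance explained by batch. Lower is better; the
#' oriented score is `1 - raw`.
#'
#' @param x Embedding or expression matrix (cells x features).
#' @param batch_labels Per-cell batch label.
#' @param n_pcs Number of principal components (default 50, capped by shape).
#' @return A [MetricResult]; `raw` in \[0, 1\], `scaled = 1 - raw`.
#' @export
pcr_batch <- function(x, batch_labels, n_pcs = 50L) {
  batch_labels <- as_ordered_factor(batch_labels)
  design <- stats::model.matrix(~ batch_labels)[, -1, drop = FALSE]
  raw <- pcr_core(x, design, n_pcs)
  MetricResult("pcr_batch", raw, scaled = 1 - raw,
               params = list(n_pcs = n_pcs, n_batches = nlevels(batch_labels)))
}

#' Before/after principal-component-regression comparison
#'
#' `score = clamp((raw_before - raw_after) / raw_before, 0, 1)`: the fraction
#' of batch-explained variance removed by the integration.
#'
#' @param x_before,x_after Matrices before and after integration.
#' @inheritParams pcr_batch
#' @return A [MetricResult] with `scaled` equal to the comparison score.
#' @export
pcr_comparison <- function(x_before, x_after, batch_labels, n_pcs = 50L) {
  rb <- pcr_batch(x_before, batch_labels, n_pcs)$raw
  ra <- pcr_batch(x_after, batch_labels, n_pcs)$raw
  if (rb == 0) {
    warning("no batch variance before integration: comparison score set to 0")
    score <- 0
  } else {
    score <- min(max((rb - ra) / rb, 0), 1)
  }
  MetricResult("pcr_comparison", score, scaled = score,
               params = list(n_pcs = n_pcs, raw_before = rb, raw_after = ra))
}

#' Density-PCA: kernel-density overlap of batches on principal components
#'
#' Per principal component and batch pair, 1-D Gaussian kernel density
#' estimates (Silverman's bandwidth) are evaluated on a common 512-point grid
#' spanning the pooled range plus three bandwidths on each side, and their
#' overlap `integral of min(f_a, f_b)` is computed. The per-component overlap
#' (mean over batch pairs) is combined across components by variance
#' weighting. 1 = identical batch distributions, 0 = disjoint.
#'
#' @param x PC-score matrix (columns treated as components), or any embedding
#'   when `n_pcs` is given, in which case PCA is applied first.
#' @param batch_labels Per-cell batch label.
#' @param n_pcs If non-`NULL`, run PCA on `x` and use this many components.
#' @return A [MetricResult]; `raw = scaled` = weighted mean overlap,
#'   `detail` = per-component overlaps.
#' @export
dpca <- function(x, batch_labels, n_pcs = NULL) {
  batch_labels <- as_ordered_factor(batch_labels)
  if (nlevels(batch_labels) < 2L) stop("DPCA needs >= 2 batches")
  x <- as.matrix(x)
  if (!is.null(n_pcs)) {
    n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
    x <- stats::prcomp(x, center = TRUE, rank. = n_pcs)$x
  }
  sizes <- table(batch_labels)
  eligible <- names(sizes)[sizes >= 2]
  if (length(eligible) < nlevels(batch_labels)) {
    warning(sprintf("batch(es) with < 2 cells excluded from DPCA: %s",
                    paste(setdiff(levels(batch_labels), eligible), collapse = ", ")))
  }
  if (length(eligible) < 2L) stop("fewer than 2 batches with >= 2 cells")
  pairs <- utils::combn(eligible, 2)
  per_pc <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      density_overlap(v[batch_labels == pairs[1, p]],
                      v[batch_labels == pairs[2, p]])
    }, numeric(1)))
  }, numeric(1))
  vars <- apply(x, 2, stats::var)
  raw <- if (sum(vars) > 0) sum(vars * per_pc) / sum(vars) else mean(per_pc)
  raw <- min(max(raw, 0), 1)
  MetricResult("dpca", raw, scaled = raw, detail = per_pc,
               params = list(n_pcs = ncol(x)))
}

# overlap coefficient of two 1-D samples via Gaussian KDE on a shared grid
density_overlap <- function(a, b, n_grid = 512L) {
  bw_a <- stats::bw.nrd0(a); bw_b <- stats::bw.nrd0(b)
  if (!is.finite(bw_a) || bw_a <= 0) bw_a <- max(abs(a), 1) * 1e-3
  if (!is.finite(bw_b) || bw_b <= 0) bw_b <- max(abs(b), 1) * 1e-3
  pad <- 3 * max(bw_a, bw_b)
  lo <- min(a, b) - pad; hi <- max(a, b) + pad
  fa <- stats::density(a, bw = bw_a, from = lo, to = hi, n = n_grid)$y
  fb <- stats::density(b, bw = bw_b, from = lo, to = hi, n = n_grid)$y
  min(sum(pmin(fa, fb)) * (hi - lo) / (n_grid - 1), 1)
}

#' Batch silhouette (batch-ASW)
#'
#' Within each cell-type group in which at least two batches are present,
#' silhouette widths are computed with *batch* as the cluster label; a cell
#' close to the batch boundary has `|s| ~ 0`, so the per-group score is the
#' mean of `1 - |s(i)|` (1 = batches indistinguishable within the cell type).
#' The raw value is the mean over eligible groups.
#'
#' @param embedding Cells x d matrix.
#' @param batch_labels Per-cell batch label.
#' @param celltype_labels Per-cell cell-type label (required).
#' @return A [MetricResult] (`raw = scaled`), or `raw = NA` when no cell-type
#'   group contains more than one batch.
#' @export
batch_asw <- function(embedding, batch_labels, celltype_labels) {
  embedding <- as.matrix(embedding)
  batch_labels <- as_ordered_factor(batch_labels)
  celltype_labels <- as_ordered_factor(celltype_labels)
  per_group <- vapply(levels(celltype_labels), function(ct) {
    ix <- which(celltype_labels == ct)
    bl <- droplevels(batch_labels[ix])
    if (nlevels(bl) < 2L || length(ix) <= nlevels(bl)) return(NA_real_)
    s <- silhouette_widths(embedding[ix, , drop = FALSE], bl)
    mean(1 - abs(s))
  }, numeric(1))
  if (all(is.na(per_group))) {
    warning("no cell-type group contains >= 2 batches: batch-ASW undefined")
    return(MetricResult("batch_asw", NA_real_, detail = per_group))
  }
  raw <- mean(per_group, na.rm = TRUE)
  MetricResult("batch_asw", raw, scaled = raw, detail = per_group)
}

# silhouette widths via cluster::silhouette (singleton clusters get width 0)
silhouette_widths <- function(x, labels) {
  labels <- as_ordered_factor(labels)
  sil <- cluster::silhouette(as.integer(labels), stats::dist(x))
  if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(labels))
}
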