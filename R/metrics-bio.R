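#' Normalized mutual information of two partitions
#'
#' Mutual information from the contingency table, normalised by default by the
#' arithmetic mean of the two entropies. Two single-cluster partitions are
#' identical, and the value is 1 by convention; otherwise a zero denominator
#' yields 0.
#'
#' @param a,b Partitions (factor/character/integer per cell, equal length).
#' @param normalization `"arithmetic"` (default), `"geometric"`, `"min"` or
#'   `"max"` mean of entropies.
#' @return A [MetricResult] (`raw = scaled`, in \[0, 1\]).
#' @export
nmi <- function(a, b, normalization = c("arithmetic", "geometric", "min", "max")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  ha <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hb <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  denom <- switch(normalization,
                  arithmetic = (ha + hb) / 2,
                  geometric = sqrt(ha * hb),
                  min = min(ha, hb),
                  max = max(ha, hb))
  raw <- if (ha == 0 && hb == 0) 1 else if (denom == 0) 0 else mi / denom
  raw <- min(max(raw, 0), 1)
  MetricResult("nmi", raw, scaled = raw, params = list(normalization = normalization))
}

#' Adjusted Rand index of two partitions
#'
#' Pair-counting agreement corrected for chance:
#' `ARI = (Index - Expected) / (Max - Expected)`. Identical partitions score
#' 1; a single-cluster partition against anything scores 0 (the
#' expected-index case). The raw value can be negative (worse-than-random
#' agreement), so the score table stores `max(raw, 0)`.
#'
#' @param a,b Partitions of the same cells.
#' @return A [MetricResult]; `raw` = ARI in (-1, 1\], `scaled = max(raw, 0)`.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  raw <- if (maximum == expected) {
    if (sum_ij == maximum) 1 else 0
  } else {
    (sum_ij - expected) / (maximum - expected)
  }
  MetricResult("ari", raw, scaled = min(max(raw, 0), 1))
}

#' Graph-based clustering matched to reference labels
#'
#' Runs modularity-based community detection (Louvain) on the connectivity
#' weights at each requested resolution and returns the partition that
#' maximises NMI against the supplied cell-type labels — the standard
#' pre-step for NMI/ARI scoring of an integration. The random seed and the
#' selected resolution are recorded on the result.
#'
#' @param g A [NeighborGraph]; connectivities are computed on the fly
#'   (UMAP-style kernel) when absent.
#' @param celltype_labels Per-cell reference labels.
#' @param resolutions Numeric vector of Louvain resolutions.
#' @param seed RNG seed used for every detection run.
#' @return A factor of cluster labels with attributes `resolution`, `nmi` and
#'   `seed`.
#' @export
cluster_for_labels <- function(g, celltype_labels,
                               resolutions = c(0.25, 0.5, 1, 2), seed = 0L) {
  if (!length(resolutions)) stop("resolutions must be non-empty")
  if (!has_connectivities(g)) g <- connectivities_from_distances(g, "umap_fuzzy_union")
  ig <- as_igraph(g, use_connectivities = TRUE)
  best <- NULL; best_nmi <- -Inf; best_res <- NA_real_
  for (r in resolutions) {
    memb <- withr::with_seed(seed,
      igraph::membership(igraph::cluster_louvain(ig, resolution = r)))
    score <- nmi(memb, celltype_labels)$raw
    if (score > best_nmi) {
      best <- memb; best_nmi <- score; best_res <- r
    }
  }
  out <- factor(best)
  attr(out, "resolution") <- best_res
  attr(out, "nmi") <- best_nmi
  attr(out, "seed") <- seed
  out
}

#' Cell-type silhouette (cell-type ASW)
#'
#' Mean silhouette width with cell types as clusters, affinely rescaled from
#' \[-1, 1\] to \[0, 1\]: `(ASW + 1) / 2`.
#'
#' @param embedding Cells x d matrix.
#' @param celltype_labels Per-cell cell-type label.
#' @return A [MetricResult]; `raw` = mean silhouette width, `scaled` its
#'   rescaling.
#' @export
celltype_asw <- function(embedding, celltype_labels) {
  celltype_labels <- as_ordered_factor(droplevels(as_ordered_factor(celltype_labels)))
  if (nlevels(celltype_labels) < 2L) {
    warning("fewer than 2 cell types: ASW undefined")
    return(MetricResult("celltype_asw", NA_real_))
  }
  s <- silhouette_widths(as.matrix(embedding), celltype_labels)
  raw <- mean(s)
  MetricResult("celltype_asw", raw, scaled = (raw + 1) / 2, detail = s)
}

#' Graph connectivity per cell-type label
#'
#' For every label, the subgraph induced by its cells is extracted (edges
#' leaving the label ignored, direction ignored) and scored as the fraction of
#' the label's cells inside its largest connected component. The raw value is
#' the mean over labels; it is 1 exactly when every label-induced subgraph is
#' connected. Singleton labels are trivially connected and contribute 1.
#'
#' @param g A [NeighborGraph].
#' @param celltype_labels Per-cell label.
#' @return A [MetricResult] (`raw = scaled`), `detail` = per-label fractions.
#' @export
graph_connectivity <- function(g, celltype_labels) {
  celltype_labels <- as_ordered_factor(celltype_labels)
  per_label <- vapply(levels(celltype_labels), function(lv) {
    ix <- which(celltype_labels == lv)
    comp <- connected_components(g, ix)
    max(tabulate(comp)) / length(ix)
  }, numeric(1))
  raw <- mean(per_label)
  MetricResult("graph_connectivity", raw, scaled = raw, detail = per_label)
}

#' scGraph: preservation of between-cell-type centroid distances
#'
#' Within each batch containing at least three cell types, cell-type centroids
#' are computed in the reference and in the integrated space and the two
#' vectors of pairwise centroid distances are compared by Spearman rank
#' correlation. The raw value is the mean correlation over eligible batches;
#' the oriented score is `(raw + 1) / 2`. Invariant under rigid motions and
#' uniform scaling of either space.
#'
#' @param embedding_reference,embedding_integrated Cells x d matrices (the
#'   dimensions may differ between the two spaces).
#' @param celltype_labels,batch_labels Per-cell labels.
#' @return A [MetricResult], or `raw = NA` when no batch has >= 3 cell types.
#' @export
scgraph <- function(embedding_reference, embedding_integrated,
                    celltype_labels, batch_labels) {
  ref <- as.matrix(embedding_reference)
  int <- as.matrix(embedding_integrated)
  celltype_labels <- as_ordered_factor(celltype_labels)
  batch_labels <- as_ordered_factor(batch_labels)
  per_batch <- vapply(levels(batch_labels), function(b) {
    ix <- which(batch_labels == b)
    types <- levels(droplevels(celltype_labels[ix]))
    if (length(types) < 3L) return(NA_real_)
    cen <- function(x) {
      m <- vapply(types, function(ct)
        colMeans(x[ix[celltype_labels[ix] == ct], , drop = FALSE]),
        numeric(ncol(x)))
      if (is.null(dim(m))) matrix(m, ncol = 1) else t(m)
    }
    d_ref <- as.vector(stats::dist(cen(ref)))
    d_int <- as.vector(stats::dist(cen(int)))
    if (stats::sd(d_ref) == 0 || stats::sd(d_int) == 0) return(NA_real_)
    stats::cor(d_ref, d_int, method = "spearman")
  }, numeric(1))
  if (all(is.na(per_batch))) {
    warning("no batch with >= 3 cell types: scGraph undefined")
    return(MetricResult("scgraph", NA_real_, detail = per_batch))
  }
  raw <- mean(per_batch, na.rm = TRUE)
  MetricResult("scgraph", raw, scaled = (raw + 1) / 2, detail = per_batch)
}

#' Per-cell gene-set module score
#'
#' Standard module-score construction: genes are binned by their mean
#' expression into `n_bins` equal-frequency bins and, for each gene of the
#' set, `n_ctrl` control genes are sampled (seeded) from its bin; the score is
#' the per-cell mean expression of the set minus the mean over the pooled
#' control draw.
#'
#' @param ds A [CellDataset].
#' @param layer Expression layer to score.
#' @param gene_set Character vector of gene names (columns of the layer).
#' @param n_bins Number of expression bins.
#' @param n_ctrl Control genes sampled per set gene.
#' @param seed RNG seed for the control draw.
#' @return Numeric per-cell score vector.
#' @export
score_gene_set <- function(ds, layer = NULL, gene_set, n_bins = 25L,
                           n_ctrl = 50L, seed = 0L) {
  layer <- pick_layer(ds, layer)
  x <- as.matrix(ds$layers[[layer]])
  genes <- colnames(x) %||% sprintf("gene%d", seq_len(ncol(x)))
  colnames(x) <- genes
  gene_set <- intersect(gene_set, genes)
  if (!length(gene_set)) stop("gene set shares no genes with the layer")
  avg <- colMeans(x)
  n_bins <- min(n_bins, ncol(x))
  bin <- as.integer(cut(rank(avg, ties.method = "first"),
                        breaks = n_bins, labels = FALSE, include.lowest = TRUE))
  names(bin) <- genes
  ctrl <- withr::with_seed(seed, unlist(lapply(gene_set, function(g) {
    # controls come from the gene's expression bin, excluding the set itself
    pool <- setdiff(genes[bin == bin[g]], gene_set)
    if (!length(pool)) pool <- genes[bin == bin[g]]
    sample(pool, size = min(n_ctrl, length(pool)), replace = length(pool) < n_ctrl)
  })))
  rowMeans(x[, gene_set, drop = FALSE]) - rowMeans(x[, ctrl, drop = FALSE])
}

#' Read a newline-delimited gene-set file
#'
#' Blank lines and `#` comments are ignored. Placeholder synthetic S/G2M sets
#' ship under `system.file("extdata", package = "scibench")`; real analyses
#' should supply organism-appropriate sets.
#'
#' @param path Text file with one gene symbol per line.
#' @return Character vector of gene names.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Cell-cycle conservation before vs after integration
#'
#' S-phase and G2M module scores are computed once from the expression layer.
#' Per batch, the variance of the (batch-restricted) principal components
#' explained jointly by the two scores is measured in the reference space
#' (`V_before`) and the integrated space (`V_after`); the per-batch score is
#' `1 - |V_after - V_before| / V_before`, clamped to \[0, 1\], and the raw
#' value the mean over batches. Batches with `V_before = 0` are skipped with a
#' warning.
#'
#' @param ds A [CellDataset] with an expression layer.
#' @param x_before,x_after Matrices/embeddings before and after integration.
#' @param s_genes,g2m_genes Cell-cycle gene sets.
#' @param n_pcs Components per batch-restricted PCA.
#' @param layer Expression layer used for the module scores.
#' @param seed Seed forwarded to [score_gene_set()].
#' @return A [MetricResult] (`raw = scaled`), `detail` = per-batch scores.
#' @export
cell_cycle_conservation <- function(ds, x_before, x_after, s_genes, g2m_genes,
                                    n_pcs = 50L, layer = NULL, seed = 0L) {
  s_score <- score_gene_set(ds, layer, s_genes, seed = seed)
  g2m_score <- score_gene_set(ds, layer, g2m_genes, seed = seed + 1L)
  covars <- cbind(S = s_score, G2M = g2m_score)
  x_before <- as.matrix(x_before); x_after <- as.matrix(x_after)
  per_batch <- vapply(levels(ds$batch), function(b) {
    ix <- which(ds$batch == b)
    vb <- pcr_core(x_before[ix, , drop = FALSE], covars[ix, , drop = FALSE], n_pcs)
    if (vb == 0) {
      warning(sprintf("batch '%s' has no cell-cycle variance before integration: skipped", b))
      return(NA_real_)
    }
    va <- pcr_core(x_after[ix, , drop = FALSE], covars[ix, , drop = FALSE], n_pcs)
    min(max(1 - abs(va - vb) / vb, 0), 1)
  }, numeric(1))
  raw <- mean(per_batch, na.rm = TRUE)
  MetricResult("cc_conservation", raw, scaled = raw, detail = per_batch,
               params = list(n_pcs = n_pcs))
}
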