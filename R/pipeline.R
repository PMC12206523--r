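#' Built-in integration method registry
#'
#' Maps method names to their runner functions so the CLI and
#' [run_integrations()] share a single dispatch path; external methods enter
#' as imported embeddings through the same registry.
#'
#' @return Named list of functions `(ds, ...) -> IntegrationOutput`.
#' @export
integration_registry <- function() {
  list(
    combat = function(ds, ...) combat_fit_transform(ds, ...),
    mnn = function(ds, ...) mnn_correct(ds, ...),
    bbknn = function(ds, ...) bbknn_integrate(ds, ...)
  )
}

#' Run several integration methods on one dataset
#'
#' @param ds A [CellDataset].
#' @param methods Character vector of registry names.
#' @param params Optional named list (per method) of argument lists.
#' @param import Optional named list of embedding CSV paths (or matrices) to
#'   include as external integration outputs of kind `"embedding"`.
#' @return Named list of [IntegrationOutput]s.
#' @export
run_integrations <- function(ds, methods = c("combat", "mnn", "bbknn"),
                             params = list(), import = list()) {
  reg <- integration_registry()
  unknown <- setdiff(methods, names(reg))
  if (length(unknown)) {
    stop(sprintf("unknown method(s): %s (registry: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(reg), collapse = ", ")))
  }
  outputs <- list()
  for (m in methods) {
    outputs[[m]] <- do.call(reg[[m]], c(list(ds), params[[m]] %||% list()))
  }
  for (nm in names(import)) {
    emb <- import[[nm]]
    if (is.character(emb)) emb <- read_embedding_csv(emb, ds)
    outputs[[nm]] <- IntegrationOutput(nm, "embedding", as.matrix(emb))
  }
  lapply(outputs, validate_output, ds = ds)
  outputs
}

# embedding used for the unintegrated reference and for matrix-kind outputs
pca_embedding <- function(x, n_pcs) {
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  stats::prcomp(as.matrix(x), center = TRUE, rank. = n_pcs)$x
}

#' Score integration outputs against a dataset
#'
#' Computes every applicable metric for each output plus an `"unintegrated"`
#' reference row, and assembles a [ScoreTable]. Outputs of kind `"matrix"` are
#' reduced by PCA to an embedding; graph outputs receive only graph-based
#' metrics (per [metric_applicability()]). The unintegrated reference
#' embedding is the PCA of the dataset's expression layer, or an existing
#' embedding named by `reference`.
#'
#' @param ds A [CellDataset] with batch (and ideally cell-type) labels.
#' @param outputs Named list of [IntegrationOutput]s.
#' @param metrics Metrics to compute (default: all applicable from
#'   [metric_registry()]; `cc_conservation` only when gene sets are given).
#' @param reference Name of a dataset embedding to use as the unintegrated
#'   reference, or `NULL` to use PCA of the default layer.
#' @param k Neighbours for derived kNN graphs.
#' @param perplexity LISI perplexity.
#' @param alpha kBET test level.
#' @param n_pcs Components for PCA-based metrics and derived embeddings.
#' @param resolutions Louvain resolutions for the NMI/ARI clustering pre-step.
#' @param s_genes,g2m_genes Optional cell-cycle gene sets enabling
#'   `cc_conservation`.
#' @param seed Seed for the (seeded) clustering and module-score steps.
#' @return A [ScoreTable] of oriented raw scores (rows: methods plus
#'   `"unintegrated"`).
#' @export
score_integrations <- function(ds, outputs, metrics = NULL, reference = NULL,
                               k = 30L, perplexity = 15, alpha = 0.05,
                               n_pcs = 20L, resolutions = c(0.25, 0.5, 1, 2),
                               s_genes = NULL, g2m_genes = NULL, seed = 0L) {
  reg <- metric_registry()
  if (is.null(metrics)) {
    metrics <- reg$metric
    if (is.null(s_genes) || is.null(g2m_genes)) {
      metrics <- setdiff(metrics, "cc_conservation")
    }
    if (is.null(ds$celltype)) {
      metrics <- setdiff(metrics, reg$metric[reg$needs_celltype])
    }
    metrics <- setdiff(metrics, "pcr_batch")  # reported through pcr_comparison
  }
  ref_emb <- if (!is.null(reference)) {
    ds$embeddings[[reference]] %||% stop(sprintf("no embedding '%s'", reference))
  } else if (length(ds$layers)) {
    pca_embedding(ds$layers[[pick_layer(ds, NULL)]], n_pcs)
  } else {
    ds$embeddings[[1]]
  }
  rows <- c("unintegrated", names(outputs))
  raw <- matrix(NA_real_, length(rows), length(metrics),
                dimnames = list(rows, metrics))
  for (rn in rows) {
    out <- if (rn == "unintegrated") {
      IntegrationOutput("unintegrated", "embedding", ref_emb)
    } else {
      outputs[[rn]]
    }
    emb <- switch(out$kind,
                  matrix = pca_embedding(out$payload, n_pcs),
                  embedding = out$payload,
                  graph = NULL)
    g <- if (out$kind == "graph") out$payload else knn_graph(emb, k = min(k, n_cells(ds) - 1L))
    part <- if (!is.null(ds$celltype) && any(c("nmi", "ari") %in% metrics)) {
      cluster_for_labels(g, ds$celltype, resolutions, seed = seed)
    }
    for (m in metrics) {
      if (!metric_applicability(out, m)) next
      raw[rn, m] <- tryCatch(switch(m,
        ilisi = ilisi(g, ds$batch, perplexity)$scaled,
        kbet = kbet(g, ds$batch, alpha)$scaled,
        pcr_batch = pcr_batch(emb, ds$batch, n_pcs)$scaled,
        pcr_comparison = if (rn == "unintegrated") NA_real_ else
          pcr_comparison(ref_emb, emb, ds$batch, n_pcs)$scaled,
        dpca = dpca(emb, ds$batch)$scaled,
        batch_asw = batch_asw(emb, ds$batch, ds$celltype)$scaled,
        clisi = clisi(g, ds$celltype, perplexity)$scaled,
        nmi = nmi(part, ds$celltype)$scaled,
        ari = ari(part, ds$celltype)$scaled,
        celltype_asw = celltype_asw(emb, ds$celltype)$scaled,
        graph_connectivity = graph_connectivity(g, ds$celltype)$scaled,
        scgraph = if (rn == "unintegrated") NA_real_ else
          scgraph(ref_emb, emb, ds$celltype, ds$batch)$scaled,
        cc_conservation = if (rn == "unintegrated") NA_real_ else
          cell_cycle_conservation(ds, ref_emb, emb, s_genes, g2m_genes,
                                  n_pcs, seed = seed)$scaled
      ), error = function(e) NA_real_)
    }
  }
  ScoreTable(raw,
             category = stats::setNames(reg$category, reg$metric)[metrics],
             orientation = stats::setNames(rep("higher_better", length(metrics)), metrics))
}

#' One-call benchmark: integrate, score, aggregate
#'
#' @inheritParams score_integrations
#' @param methods Built-in methods to run.
#' @param w_batch,w_bio Composite weights.
#' @param rescale_mode Rescaling mode for the composites.
#' @param ... Passed to [score_integrations()].
#' @return List with elements `outputs`, `scores` (raw [ScoreTable]),
#'   `composites` (ranked `CompositeScores`).
#' @export
benchmark_integrations <- function(ds, methods = c("combat", "mnn", "bbknn"),
                                   w_batch = 0.5, w_bio = 0.5,
                                   rescale_mode = "minmax_ranks", ...) {
  outputs <- run_integrations(ds, methods)
  scores <- score_integrations(ds, outputs, ...)
  composites <- overall_and_rank(
    composite_scores(scores, w_batch, w_bio, rescale_mode))
  list(outputs = outputs, scores = scores, composites = composites)
}
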