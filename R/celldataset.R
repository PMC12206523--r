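#' Cell-level expression bundle
#'
#' `CellDataset` is the central container of scibench: one or more cells x genes
#' expression layers, a per-cell batch label, an optional per-cell cell-type
#' label, named low-dimensional embeddings, named neighbour graphs and an
#' optional per-gene variable-feature flag. All components must agree on the
#' number and order of cells (and, for layers, of genes).
#'
#' @param layers Named list of cells x genes matrices (base or `Matrix` sparse).
#'   Conventional layer names are `"counts"` (non-negative integers) and
#'   `"data"` (normalised real values). May be empty if at least one embedding
#'   is supplied.
#' @param batch Per-cell batch label (factor or character). Levels are
#'   case-sensitive and kept in order of first appearance when coerced.
#' @param celltype Optional per-cell cell-type label.
#' @param embeddings Named list of cells x d numeric matrices.
#' @param graphs Named list of [NeighborGraph] objects.
#' @param var_features Optional logical flag per gene.
#' @param barcodes Optional cell identifiers; defaults to `cell1..cellN` or the
#'   row names of the first layer/embedding.
#'
#' @return An object of class `CellDataset`.
#' @export
CellDataset <- function(layers = list(), batch, celltype = NULL,
                        embeddings = list(), graphs = list(),
                        var_features = NULL, barcodes = NULL) {
  stopifnot(is.list(layers), is.list(embeddings), is.list(graphs))
  batch <- as_ordered_factor(batch)
  celltype <- if (!is.null(celltype)) as_ordered_factor(celltype)
  n <- length(batch)

  if (is.null(barcodes)) {
    src <- c(layers, embeddings)
    barcodes <- if (length(src) && !is.null(rownames(src[[1]]))) {
      rownames(src[[1]])
    } else {
      sprintf("cell%d", seq_len(n))
    }
  }
  ds <- structure(
    list(layers = layers, batch = batch, celltype = celltype,
         embeddings = embeddings, graphs = graphs,
         var_features = var_features, barcodes = as.character(barcodes)),
    class = "CellDataset"
  )
  validate_cell_dataset(ds)
  ds
}

# factor with levels in order of first appearance (case-sensitive)
as_ordered_factor <- function(x) {
  if (is.factor(x)) return(x)
  x <- as.character(x)
  factor(x, levels = unique(x))
}

validate_cell_dataset <- function(ds) {
  n <- length(ds$batch)
  if (n < 1L) stop("CellDataset must contain at least one cell")
  if (length(ds$layers) == 0L && length(ds$embeddings) == 0L) {
    stop("CellDataset needs at least one layer or one embedding")
  }
  if (length(ds$layers) && is.null(names(ds$layers))) {
    stop("layers must be named")
  }
  if (length(ds$barcodes) != n) {
    stop(sprintf("barcodes length (%d) does not match cell count (%d)",
                 length(ds$barcodes), n))
  }
  n_genes <- NULL
  for (nm in names(ds$layers)) {
    m <- ds$layers[[nm]]
    if (nrow(m) != n) {
      stop(sprintf("layer '%s' has %d rows but dataset has %d cells",
                   nm, nrow(m), n))
    }
    if (is.null(n_genes)) n_genes <- ncol(m)
    if (ncol(m) != n_genes) {
      stop(sprintf("layer '%s' has %d genes; expected %d", nm, ncol(m), n_genes))
    }
    if (nm == "counts" && min_value(m) < 0) {
      stop("'counts' layer contains negative entries")
    }
  }
  for (nm in names(ds$embeddings)) {
    if (nrow(ds$embeddings[[nm]]) != n) {
      stop(sprintf("embedding '%s' has %d rows but dataset has %d cells",
                   nm, nrow(ds$embeddings[[nm]]), n))
    }
  }
  for (nm in names(ds$graphs)) {
    g <- ds$graphs[[nm]]
    if (!inherits(g, "NeighborGraph")) {
      stop(sprintf("graph '%s' is not a NeighborGraph", nm))
    }
    if (g$n_cells != n) {
      stop(sprintf("graph '%s' covers %d cells but dataset has %d",
                   nm, g$n_cells, n))
    }
  }
  if (!is.null(ds$celltype) && length(ds$celltype) != n) {
    stop("celltype labels do not match cell count")
  }
  if (!is.null(ds$var_features)) {
    if (is.null(n_genes)) stop("var_features supplied without any layer")
    if (length(ds$var_features) != n_genes) {
      stop("var_features length does not match gene count")
    }
  }
  invisible(ds)
}

min_value <- function(m) {
  if (inherits(m, "sparseMatrix")) min(m@x, 0) else min(m)
}

#' @export
print.CellDataset <- function(x, ...) {
  cat(sprintf("CellDataset: %d cells, %d genes\n", n_cells(x), n_genes(x)))
  cat(sprintf("  layers: %s\n", paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  batch levels (%d): %s\n", nlevels(x$batch),
              paste(utils::head(levels(x$batch), 8), collapse = ", ")))
  if (!is.null(x$celltype)) {
    cat(sprintf("  cell types: %d\n", nlevels(x$celltype)))
  }
  if (length(x$embeddings)) {
    cat(sprintf("  embeddings: %s\n", paste(names(x$embeddings), collapse = ", ")))
  }
  if (length(x$graphs)) {
    cat(sprintf("  graphs: %s\n", paste(names(x$graphs), collapse = ", ")))
  }
  invisible(x)
}

#' Number of cells / genes in a dataset
#' @param ds A [CellDataset].
#' @return Integer count.
#' @export
n_cells <- function(ds) length(ds$batch)

#' @rdname n_cells
#' @export
n_genes <- function(ds) {
  if (length(ds$layers)) ncol(ds$layers[[1]]) else 0L
}

#' Reorder the cells of a dataset
#'
#' Applies a permutation to every cell-indexed component (layers, labels,
#' embeddings, graphs). Applying a permutation followed by its inverse restores
#' the original dataset exactly.
#'
#' @param ds A [CellDataset].
#' @param perm Integer permutation of `seq_len(n_cells(ds))`; `perm[i]` gives
#'   the old index of the cell placed at new position `i`.
#' @return The permuted [CellDataset].
#' @export
permute_cells <- function(ds, perm) {
  n <- n_cells(ds)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- integer(n); inv[perm] <- seq_len(n)  # new position of old cell i
  CellDataset(
    layers = lapply(ds$layers, function(m) m[perm, , drop = FALSE]),
    batch = ds$batch[perm],
    celltype = if (!is.null(ds$celltype)) ds$celltype[perm],
    embeddings = lapply(ds$embeddings, function(m) m[perm, , drop = FALSE]),
    graphs = lapply(ds$graphs, relabel_graph, map = inv),
    var_features = ds$var_features,
    barcodes = ds$barcodes[perm]
  )
}

#' One integration method's output
#'
#' Tags a result with its kind so downstream metric applicability can be
#' decided: corrected expression matrices and embeddings support PCA-based and
#' silhouette metrics, while graph outputs support only graph-based metrics.
#'
#' @param method_name Name of the integration method.
#' @param kind One of `"matrix"`, `"embedding"`, `"graph"`.
#' @param payload A cells x genes matrix, a cells x d embedding, or a
#'   [NeighborGraph], matching `kind`.
#' @param params Optional named list of parameters used (for provenance).
#' @return An `IntegrationOutput` object.
#' @export
IntegrationOutput <- function(method_name, kind = c("matrix", "embedding", "graph"),
                              payload, params = list()) {
  kind <- match.arg(kind)
  if (kind == "graph") {
    if (!inherits(payload, "NeighborGraph")) {
      stop("kind 'graph' requires a NeighborGraph payload")
    }
  } else if (!is.matrix(payload) && !inherits(payload, "Matrix")) {
    stop(sprintf("kind '%s' requires a matrix payload", kind))
  }
  structure(list(method_name = method_name, kind = kind,
                 payload = payload, params = params),
            class = "IntegrationOutput")
}

#' @export
print.IntegrationOutput <- function(x, ...) {
  dim_txt <- if (x$kind == "graph") {
    sprintf("%d cells, %d edges", x$payload$n_cells, nrow(x$payload$edges))
  } else {
    paste(dim(x$payload), collapse = " x ")
  }
  cat(sprintf("IntegrationOutput '%s' (%s): %s\n", x$method_name, x$kind, dim_txt))
  invisible(x)
}

#' Check output payload against a source dataset
#' @param out An [IntegrationOutput].
#' @param ds The source [CellDataset].
#' @return `out`, invisibly; errors if the cell counts disagree.
#' @export
validate_output <- function(out, ds) {
  n_out <- if (out$kind == "graph") out$payload$n_cells else nrow(out$payload)
  if (n_out != n_cells(ds)) {
    stop(sprintf("output '%s' covers %d cells but dataset has %d",
                 out$method_name, n_out, n_cells(ds)))
  }
  invisible(out)
}
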