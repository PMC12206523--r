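#' Write a dataset to an on-disk directory bundle
#'
#' The bundle is a plain-text, diff-friendly directory:
#' * `manifest.json` — matrix orientation, layer file map, component inventory
#' * `<layer>.mtx` — one MatrixMarket file per layer (the first layer is also
#'   the canonical `matrix.mtx`), written genes x cells
#' * `barcodes.tsv`, `features.tsv` — cell and gene identifiers (features.tsv
#'   carries the variable-feature flag when present)
#' * `obs.tsv` — per-cell table with `barcode`, `batch` and, when present,
#'   `celltype` (the column is omitted when no cell-type labels exist)
#' * `embeddings/<name>.csv` — header = dimension names, first column barcode
#' * `graphs/<name>.csv` — edge list `src,dst,distance,connectivity`
#'
#' @param ds A [CellDataset].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_bundle()]
#' @export
write_bundle <- function(ds, path) {
  validate_cell_dataset(ds)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop(sprintf("cannot create bundle directory '%s'", path))
  layer_files <- character(0)
  for (nm in names(ds$layers)) {
    f <- if (nm == names(ds$layers)[1]) "matrix.mtx" else sprintf("layer_%s.mtx", nm)
    m <- methods::as(methods::as(Matrix::Matrix(t(ds$layers[[nm]]), sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(m, file.path(path, f))
    layer_files[nm] <- f
  }
  writeLines(ds$barcodes, file.path(path, "barcodes.tsv"))
  if (n_genes(ds) > 0) {
    genes <- colnames(ds$layers[[1]])
    if (is.null(genes)) genes <- sprintf("gene%d", seq_len(n_genes(ds)))
    feat <- data.frame(gene = genes)
    if (!is.null(ds$var_features)) feat$var_feature <- ds$var_features
    utils::write.table(feat, file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  obs <- data.frame(barcode = ds$barcodes, batch = as.character(ds$batch))
  if (!is.null(ds$celltype)) obs$celltype <- as.character(ds$celltype)
  utils::write.table(obs, file.path(path, "obs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(ds$embeddings)) {
    dir.create(file.path(path, "embeddings"), showWarnings = FALSE)
    for (nm in names(ds$embeddings)) {
      emb <- ds$embeddings[[nm]]
      dims <- colnames(emb)
      if (is.null(dims)) dims <- sprintf("dim%d", seq_len(ncol(emb)))
      df <- data.frame(barcode = ds$barcodes, emb)
      names(df) <- c("barcode", dims)
      utils::write.csv(df, file.path(path, "embeddings", paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (length(ds$graphs)) {
    dir.create(file.path(path, "graphs"), showWarnings = FALSE)
    for (nm in names(ds$graphs)) {
      write_graph_csv(ds$graphs[[nm]],
                      file.path(path, "graphs", paste0(nm, ".csv")))
    }
  }
  manifest <- list(
    format = "scibench-bundle", version = 1L,
    orientation = "genes_x_cells",
    n_cells = n_cells(ds), n_genes = n_genes(ds),
    layers = as.list(layer_files),
    has_celltype = !is.null(ds$celltype),
    embeddings = as.list(names(ds$embeddings)),
    graphs = lapply(ds$graphs, function(g)
      list(k = g$k, directed = g$directed))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset bundle from disk
#'
#' Inverse of [write_bundle()]. The manifest declares the on-disk matrix
#' orientation; in-memory layers are always cells x genes.
#'
#' @param path Bundle directory.
#' @return A [CellDataset].
#' @export
read_bundle <- function(path) {
  mf_file <- file.path(path, "manifest.json")
  if (!file.exists(mf_file)) stop(sprintf("no manifest.json in '%s'", path))
  mf <- jsonlite::read_json(mf_file, simplifyVector = TRUE)
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  obs_file <- file.path(path, "obs.tsv")
  if (!file.exists(obs_file)) stop("bundle lacks obs.tsv")
  obs <- utils::read.delim(obs_file, colClasses = "character")
  if (!"batch" %in% names(obs)) {
    stop("schema error: obs.tsv has no 'batch' column")
  }
  n <- length(barcodes)
  if (nrow(obs) != n) {
    stop(sprintf("dimension error: obs.tsv has %d rows but barcodes.tsv has %d",
                 nrow(obs), n))
  }
  genes <- NULL; var_features <- NULL
  feat_file <- file.path(path, "features.tsv")
  if (file.exists(feat_file)) {
    feat <- utils::read.delim(feat_file)
    genes <- as.character(feat$gene)
    if ("var_feature" %in% names(feat)) var_features <- as.logical(feat$var_feature)
  }
  layers <- list()
  for (nm in names(mf$layers)) {
    f <- file.path(path, mf$layers[[nm]])
    m <- as.matrix(Matrix::readMM(f))
    if (identical(mf$orientation, "genes_x_cells")) m <- t(m)
    if (nrow(m) != n) {
      stop(sprintf("dimension error: %s has %d cells but barcodes.tsv has %d",
                   mf$layers[[nm]], nrow(m), n))
    }
    if (!is.null(genes)) {
      if (ncol(m) != length(genes)) {
        stop(sprintf("dimension error: %s has %d genes but features.tsv has %d",
                     mf$layers[[nm]], ncol(m), length(genes)))
      }
      colnames(m) <- genes
    }
    rownames(m) <- barcodes
    layers[[nm]] <- m
  }
  embeddings <- list()
  for (nm in unlist(mf$embeddings)) {
    df <- utils::read.csv(file.path(path, "embeddings", paste0(nm, ".csv")),
                          check.names = FALSE)
    if (nrow(df) != n) {
      stop(sprintf("dimension error: embedding '%s' has %d rows but bundle has %d cells",
                   nm, nrow(df), n))
    }
    emb <- as.matrix(df[, -1, drop = FALSE])
    rownames(emb) <- df[[1]]
    embeddings[[nm]] <- emb
  }
  graphs <- list()
  for (nm in names(mf$graphs)) {
    gi <- mf$graphs[[nm]]
    graphs[[nm]] <- read_graph_csv(file.path(path, "graphs", paste0(nm, ".csv")),
                                   n_cells = n, k = gi$k, directed = gi$directed)
  }
  CellDataset(layers = layers, batch = obs$batch,
              celltype = if ("celltype" %in% names(obs)) obs$celltype,
              embeddings = embeddings, graphs = graphs,
              var_features = var_features, barcodes = barcodes)
}

#' Serialize a neighbour graph as an edge-list CSV
#'
#' Columns `src,dst,distance,connectivity` with 1-based indices; connectivity
#' is left empty when not yet computed.
#'
#' @param g A [NeighborGraph].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_graph_csv <- function(g, path) {
  utils::write.csv(g$edges, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_graph_csv
#' @param n_cells,k,directed Graph attributes not stored in the CSV.
#' @export
read_graph_csv <- function(path, n_cells, k = NA_integer_, directed = TRUE) {
  e <- utils::read.csv(path)
  NeighborGraph(e, n_cells = n_cells, k = k, directed = directed)
}

#' Import an external embedding from CSV
#'
#' Expects the layout written by [write_bundle()]: header = dimension names,
#' first column = cell barcode. Rows are matched to the dataset's barcodes.
#'
#' @param path CSV file.
#' @param ds Optional [CellDataset] against which barcodes are validated and
#'   ordered.
#' @return A cells x d numeric matrix.
#' @export
read_embedding_csv <- function(path, ds = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop(sprintf("schema error: '%s' needs a barcode column plus >= 1 dimension", path))
  emb <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(emb)) stop(sprintf("schema error: non-numeric dimensions in '%s'", path))
  rownames(emb) <- as.character(df[[1]])
  if (!is.null(ds)) {
    idx <- match(ds$barcodes, rownames(emb))
    if (anyNA(idx)) {
      stop(sprintf("schema error: '%s' is missing %d dataset barcodes",
                   path, sum(is.na(idx))))
    }
    emb <- emb[idx, , drop = FALSE]
  }
  emb
}
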