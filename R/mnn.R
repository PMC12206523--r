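#' Mutual-nearest-neighbour batch correction
#'
#' Batches are merged sequentially in their level order (or a user-supplied
#' order). At each merge, mutual nearest neighbours between the growing
#' reference and the incoming batch are identified: a pair (r, c) is mutual
#' when c is among r's `k` nearest cells of the incoming batch *and* r is among
#' c's `k` nearest cells of the reference. Pair difference vectors (reference
#' minus incoming) define corrections; every incoming cell receives a
#' Gaussian-kernel-weighted average of the pair vectors, with weights
#' `exp(-d^2 / (2 sigma^2))` on its input-space distances to the paired
#' incoming cells. The corrected batch is appended to the reference.
#'
#' @param ds A [CellDataset].
#' @param use Name of an embedding (preferred) or layer to correct.
#' @param k Number of cross-batch neighbours per direction.
#' @param sigma Gaussian smoothing bandwidth, in input-space distance units.
#'   Default: half the root-mean-square distance between mutual pairs of the
#'   first merge (data-scale adaptive, deterministic).
#' @param cos_norm Optionally L2-normalise cells before distance computations
#'   (correction vectors are still computed and applied in the original space).
#' @param merge_order Optional character vector of batch levels.
#' @return An [IntegrationOutput] of kind `"embedding"` (or `"matrix"` when a
#'   layer was corrected) with attribute `"pairs"`: a `data.frame` of mutual
#'   pairs (`ref`, `target`, global cell indices) per merge step.
#' @export
mnn_correct <- function(ds, use = NULL, k = 20L, sigma = NULL,
                        cos_norm = FALSE, merge_order = NULL) {
  if (is.null(use)) {
    use <- if (length(ds$embeddings)) names(ds$embeddings)[1] else pick_layer(ds, NULL)
  }
  if (use %in% names(ds$embeddings)) {
    x <- as.matrix(ds$embeddings[[use]]); kind <- "embedding"
  } else {
    x <- as.matrix(ds$layers[[pick_layer(ds, use)]]); kind <- "matrix"
  }
  res <- mnn_correct_matrix(x, ds$batch, k = k, sigma = sigma,
                            cos_norm = cos_norm, merge_order = merge_order)
  out <- IntegrationOutput("mnn", kind, res$corrected,
                           params = list(use = use, k = k, sigma = res$sigma))
  attr(out, "pairs") <- res$pairs
  out
}

#' @rdname mnn_correct
#' @param x Numeric cells x features matrix.
#' @param batch Per-cell batch label.
#' @export
mnn_correct_matrix <- function(x, batch, k = 20L, sigma = NULL,
                               cos_norm = FALSE, merge_order = NULL) {
  x <- as.matrix(x)
  batch <- as_ordered_factor(batch)
  stopifnot(nrow(x) == length(batch), k >= 1L)
  levels_ <- merge_order %||% levels(batch)
  if (!setequal(levels_, levels(batch))) stop("merge_order must list every batch level")
  if (length(levels_) < 2L) stop("MNN correction needs >= 2 batches")

  norm_rows <- function(m) {
    if (!cos_norm) return(m)
    nrm <- sqrt(rowSums(m^2)); nrm[nrm == 0] <- 1
    m / nrm
  }
  corrected <- x
  ref_idx <- which(batch == levels_[1])
  pairs_all <- list()
  for (step in seq(2L, length(levels_))) {
    tgt_idx <- which(batch == levels_[step])
    ref <- norm_rows(corrected[ref_idx, , drop = FALSE])
    tgt_orig <- corrected[tgt_idx, , drop = FALSE]
    tgt <- norm_rows(tgt_orig)
    pr <- mutual_pairs(ref, tgt, k)
    if (nrow(pr) == 0L) {
      stop(sprintf("no mutual nearest-neighbour pairs between '%s' and the reference; try a larger k",
                   levels_[step]))
    }
    diffs <- corrected[ref_idx[pr$ref], , drop = FALSE] - tgt_orig[pr$target, , drop = FALSE]
    pd <- sqrt(rowSums(diffs^2))
    if (is.null(sigma)) sigma <- max(sqrt(mean(pd^2)) / 2, .Machine$double.eps)
    # distances from each incoming cell to the paired incoming cells
    d2 <- cross_dist2(tgt, tgt[pr$target, , drop = FALSE])
    w <- exp(-(d2 - matrixStats_rowMins(d2)) / (2 * sigma^2))
    corr <- (w %*% diffs) / rowSums(w)
    corrected[tgt_idx, ] <- tgt_orig + corr
    pairs_all[[levels_[step]]] <- data.frame(
      step = step - 1L, ref = ref_idx[pr$ref], target = tgt_idx[pr$target])
    ref_idx <- c(ref_idx, tgt_idx)
  }
  list(corrected = corrected, pairs = do.call(rbind, pairs_all), sigma = sigma)
}

matrixStats_rowMins <- function(m) apply(m, 1, min)

# mutual k-nearest cross-batch pairs between two point sets
mutual_pairs <- function(ref, tgt, k) {
  d2 <- cross_dist2(ref, tgt)
  k_rt <- min(k, ncol(d2)); k_tr <- min(k, nrow(d2))
  nn_rt <- t(apply(d2, 1, function(r) order(r, seq_along(r))[seq_len(k_rt)]))
  nn_tr <- t(apply(d2, 2, function(cl) order(cl, seq_along(cl))[seq_len(k_tr)]))
  ref_i <- rep(seq_len(nrow(d2)), each = k_rt)
  tgt_i <- as.vector(t(nn_rt))
  back <- matrix(FALSE, nrow(d2), ncol(d2))
  back[cbind(as.vector(t(nn_tr)), rep(seq_len(ncol(d2)), each = k_tr))] <- TRUE
  keep <- back[cbind(ref_i, tgt_i)]
  data.frame(ref = ref_i[keep], target = tgt_i[keep])
}
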