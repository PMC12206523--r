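#' Ground-truth parameter bundle for the synthetic generator
#'
#' Draws and stores every parameter of the generative model so that datasets
#' are exactly reproducible from the bundle: Gaussian-mixture cell types in a
#' latent space (`centroids`, pairwise separation scale `s`), per-batch latent
#' shift vectors of magnitude `m`, per-gene loadings mapping latent positions
#' to log-means, per-gene per-batch additive (log-scale) and multiplicative
#' (signal-scaling) effects, negative-binomial dispersion `theta`, log-normal
#' library sizes, and an optional cell-cycle program.
#'
#' @param n_batches Number of batches.
#' @param n_types Number of cell types.
#' @param cells_per_batch Cells per batch (recycled to `n_batches`).
#' @param d Latent dimension.
#' @param s Expected pairwise separation of cell-type centroids.
#' @param m Magnitude of each batch's latent shift (0 = no latent batch
#'   effect). May be a vector of per-batch magnitudes.
#' @param sigma Within-type latent standard deviation.
#' @param n_genes Number of genes.
#' @param theta Negative-binomial dispersion (size); larger = closer to
#'   Poisson.
#' @param batch_lfc_sd SD of per-gene additive batch effects on the log-mean
#'   scale (0 = none).
#' @param batch_mult_sd SD (log-scale) of per-gene multiplicative batch
#'   effects that scale the biological signal (0 = none).
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters.
#' @param type_props Cell-type proportions per batch (default equal).
#' @param cc_program Add a cell-cycle program?
#' @param n_cc_genes Genes per cell-cycle set (S and G2M).
#' @param cc_amplitude Log-scale amplitude of the cell-cycle signal.
#' @param seed RNG seed; all draws (parameters here, cells in
#'   [simulate_latent()] / [simulate_counts()]) derive deterministically
#'   from it.
#' @return A `SyntheticTruth` object.
#' @export
synthetic_truth <- function(n_batches = 4L, n_types = 8L, cells_per_batch = 250L,
                            d = 10L, s = 6, m = 3, sigma = 1,
                            n_genes = 400L, theta = 2,
                            batch_lfc_sd = 0, batch_mult_sd = 0,
                            libsize_meanlog = log(5000), libsize_sdlog = 0.3,
                            type_props = NULL, cc_program = FALSE,
                            n_cc_genes = 25L, cc_amplitude = 1, seed = 0L) {
  stopifnot(n_batches >= 1L, n_types >= 1L, all(m >= 0), theta > 0, sigma >= 0)
  cells_per_batch <- rep_len(as.integer(cells_per_batch), n_batches)
  m <- rep_len(m, n_batches)
  if (is.null(type_props)) type_props <- rep(1 / n_types, n_types)
  stopifnot(length(type_props) == n_types, abs(sum(type_props) - 1) < 1e-8)
  truth <- withr::with_seed(as.integer(seed), {
    centroids <- matrix(stats::rnorm(n_types * d, sd = s / sqrt(2 * d)), n_types, d)
    shifts <- t(vapply(seq_len(n_batches), function(b) {
      v <- stats::rnorm(d)
      v / sqrt(sum(v^2)) * m[b]
    }, numeric(d)))
    loadings <- matrix(stats::rnorm(n_genes * d, sd = 1 / sqrt(d)), n_genes, d)
    base_logmean <- stats::rnorm(n_genes, mean = log(0.5), sd = 1)
    add_effects <- matrix(stats::rnorm(n_batches * n_genes, sd = batch_lfc_sd),
                          n_batches, n_genes)
    mult_effects <- matrix(exp(stats::rnorm(n_batches * n_genes, sd = batch_mult_sd)),
                           n_batches, n_genes)
    cc_genes <- if (cc_program) {
      ix <- sample.int(n_genes, 2L * n_cc_genes)
      list(s = ix[seq_len(n_cc_genes)], g2m = ix[n_cc_genes + seq_len(n_cc_genes)])
    }
    list(centroids = centroids, shifts = shifts, loadings = loadings,
         base_logmean = base_logmean, add_effects = add_effects,
         mult_effects = mult_effects, cc_genes = cc_genes)
  })
  structure(c(truth,
              list(n_batches = n_batches, n_types = n_types,
                   cells_per_batch = cells_per_batch, d = d, s = s, m = m,
                   sigma = sigma, n_genes = n_genes, theta = theta,
                   batch_lfc_sd = batch_lfc_sd, batch_mult_sd = batch_mult_sd,
                   libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
                   type_props = type_props, cc_program = cc_program,
                   n_cc_genes = n_cc_genes, cc_amplitude = cc_amplitude,
                   seed = as.integer(seed))),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "SyntheticTruth: %d batches x ~%d cells, %d types, d=%d, s=%g, m=[%s], %d genes (seed %d)\n",
    x$n_batches, x$cells_per_batch[1], x$n_types, x$d, x$s,
    paste(x$m, collapse = ","), x$n_genes, x$seed))
  invisible(x)
}

#' Draw latent positions and labels
#'
#' A cell of type `t` in batch `b` is `Normal(centroid_t + shift_b, sigma^2 I)`
#' in the latent space. The returned dataset carries the embedding
#' `"latent_true"` plus batch and cell-type labels; gene-level layers are
#' added by [simulate_counts()]. Fully deterministic given the truth's seed.
#'
#' @param truth A [synthetic_truth()] bundle.
#' @return A [CellDataset] with embedding `"latent_true"`.
#' @export
simulate_latent <- function(truth) {
  n_total <- sum(truth$cells_per_batch)
  withr::with_seed(truth$seed + 1L, {
    batch <- rep(seq_len(truth$n_batches), truth$cells_per_batch)
    type <- unlist(lapply(seq_len(truth$n_batches), function(b) {
      counts <- round_props(truth$cells_per_batch[b], truth$type_props)
      rep(seq_len(truth$n_types), counts)
    }))
    z <- truth$centroids[type, , drop = FALSE] +
      truth$shifts[batch, , drop = FALSE] +
      matrix(stats::rnorm(n_total * truth$d, sd = truth$sigma), n_total, truth$d)
    rownames(z) <- sprintf("cell%05d", seq_len(n_total))
    CellDataset(embeddings = list(latent_true = z),
                batch = sprintf("batch%d", batch),
                celltype = sprintf("type%02d", type))
  })
}

# largest-remainder apportionment of n cells to proportions p
round_props <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate negative-binomial counts from latent positions
#'
#' Per-gene log-means are `base_g + mult_bg * (z_i . loadings_g) + add_bg`
#' (multiplicative batch effects scale the biological signal, additive ones
#' shift the log-mean), multiplied by the cell's log-normal library-size
#' factor; counts are drawn `NegativeBinomial(mean, theta)`. With the
#' cell-cycle program on, each cell gets a phase `phi ~ U(0, 2*pi)` and the S
#' and G2M gene sets receive `cc_amplitude * max(0, sin phi)` /
#' `max(0, cos phi)` on the log-mean; the phase is stored as embedding
#' `"cc_phase"` and the gene sets are recoverable via [cc_gene_sets()].
#'
#' @param truth A [synthetic_truth()] bundle.
#' @param latent Optional [CellDataset] from [simulate_latent()]; generated if
#'   missing.
#' @return A [CellDataset] with a `"counts"` layer, a log1p-normalised
#'   `"data"` layer, and the latent embedding.
#' @export
simulate_counts <- function(truth, latent = NULL) {
  if (is.null(latent)) latent <- simulate_latent(truth)
  z <- latent$embeddings[["latent_true"]]
  n <- nrow(z)
  batch_int <- as.integer(latent$batch)
  withr::with_seed(truth$seed + 2L, {
    signal <- tcrossprod(z, truth$loadings)              # cells x genes
    signal <- signal * truth$mult_effects[batch_int, , drop = FALSE]
    log_mu <- sweep(signal, 2, truth$base_logmean, "+") +
      truth$add_effects[batch_int, , drop = FALSE]
    phase <- NULL
    if (truth$cc_program) {
      phase <- stats::runif(n, 0, 2 * pi)
      log_mu[, truth$cc_genes$s] <- log_mu[, truth$cc_genes$s] +
        truth$cc_amplitude * pmax(0, sin(phase))
      log_mu[, truth$cc_genes$g2m] <- log_mu[, truth$cc_genes$g2m] +
        truth$cc_amplitude * pmax(0, cos(phase))
    }
    lib <- stats::rlnorm(n, truth$libsize_meanlog, truth$libsize_sdlog)
    lib <- lib / mean(lib)
    mu <- exp(pmin(log_mu, 30)) * lib
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = truth$theta),
                     n, truth$n_genes)
    dimnames(counts) <- list(rownames(z), sprintf("gene%04d", seq_len(truth$n_genes)))
    data <- log1p(counts / pmax(rowSums(counts), 1) * 1e4)
    embeddings <- latent$embeddings
    if (!is.null(phase)) embeddings$cc_phase <- matrix(phase, ncol = 1,
                                                       dimnames = list(rownames(z), "phase"))
    CellDataset(layers = list(counts = counts, data = data),
                batch = latent$batch, celltype = latent$celltype,
                embeddings = embeddings, barcodes = latent$barcodes)
  })
}

#' Cell-cycle gene sets of a synthetic truth
#' @param truth A [synthetic_truth()] with `cc_program = TRUE`.
#' @return List with character vectors `s` and `g2m`.
#' @export
cc_gene_sets <- function(truth) {
  if (!truth$cc_program) stop("truth has no cell-cycle program")
  list(s = sprintf("gene%04d", truth$cc_genes$s),
       g2m = sprintf("gene%04d", truth$cc_genes$g2m))
}

#' Named generator presets
#'
#' * `well_mixed` — 4 batches x 250 cells, 8 types, no batch effect (`m = 0`,
#'   no gene-level effects): the null condition for mixing metrics.
#' * `shifted` — same design with latent shift `m = 3` and per-gene additive
#'   effects (`sd = 0.3`): a clear but correctable batch effect.
#' * `nested_atlas` — the atlas condition: 4 studies x 2 samples x 1250 cells
#'   (10 000 cells in 8 batches) and 17 cell types, with study-level latent
#'   shifts of magnitude 6 and extra sample-within-study shifts of magnitude
#'   3 (nested batch structure).
#'
#' @param name Preset name.
#' @param seed RNG seed.
#' @param cells_per_batch Optional override for the per-batch cell count
#'   (e.g. to run the atlas design at reduced size).
#' @return A [synthetic_truth()] bundle.
#' @export
preset <- function(name = c("well_mixed", "shifted", "nested_atlas"),
                   seed = 0L, cells_per_batch = NULL) {
  name <- match.arg(name)
  truth <- switch(name,
    well_mixed = synthetic_truth(n_batches = 4L, n_types = 8L,
                                 cells_per_batch = cells_per_batch %||% 250L,
                                 m = 0, batch_lfc_sd = 0, seed = seed),
    shifted = synthetic_truth(n_batches = 4L, n_types = 8L,
                              cells_per_batch = cells_per_batch %||% 250L,
                              m = 3, batch_lfc_sd = 0.3, seed = seed),
    nested_atlas = nested_atlas_truth(seed, cells_per_batch %||% 1250L)
  )
  truth$preset <- name
  truth
}

# 4 studies x 2 samples: batch shift = study shift (|.|=6) + sample shift (|.|=3)
nested_atlas_truth <- function(seed, cells_per_batch) {
  truth <- synthetic_truth(n_batches = 8L, n_types = 17L,
                           cells_per_batch = cells_per_batch,
                           d = 12L, s = 6, m = 0, batch_lfc_sd = 0.3,
                           n_genes = 1000L, seed = seed)
  truth$study <- rep(seq_len(4L), each = 2L)
  truth$shifts <- withr::with_seed(as.integer(seed) + 3L, {
    unit <- function() { v <- stats::rnorm(truth$d); v / sqrt(sum(v^2)) }
    study_shift <- t(vapply(seq_len(4L), function(i) unit() * 6, numeric(truth$d)))
    t(vapply(seq_len(8L), function(b) {
      study_shift[truth$study[b], ] + unit() * 3
    }, numeric(truth$d)))
  })
  truth$m <- sqrt(rowSums(truth$shifts^2))
  truth
}

#' Oracle integration: subtract the true batch shifts
#'
#' Removes each cell's known latent batch shift — the best possible latent
#' integration for data generated by [simulate_latent()]. Used as the upper
#' anchor in ordering tests.
#'
#' @param ds A [CellDataset] holding the `"latent_true"` embedding.
#' @param truth The generating [synthetic_truth()].
#' @return An [IntegrationOutput] of kind `"embedding"`.
#' @export
oracle_integration <- function(ds, truth) {
  z <- ds$embeddings[["latent_true"]]
  corrected <- z - truth$shifts[as.integer(ds$batch), , drop = FALSE]
  IntegrationOutput("oracle", "embedding", corrected)
}

#' Serialize a truth bundle to JSON (and back)
#'
#' Round-trips every parameter, including the drawn matrices, so presets can
#' be stored as plain-text config files.
#'
#' @param truth A [synthetic_truth()].
#' @param path JSON file.
#' @return `path` / the restored `SyntheticTruth`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("centroids", "shifts", "loadings", "add_effects", "mult_effects")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.matrix(obj[[f]])
  }
  if (!is.null(obj$cc_genes)) obj$cc_genes <- lapply(obj$cc_genes, as.integer)
  int_fields <- c("n_batches", "n_types", "cells_per_batch", "d", "n_genes",
                  "n_cc_genes", "seed")
  for (f in int_fields) obj[[f]] <- as.integer(obj[[f]])
  structure(obj, class = "SyntheticTruth")
}
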