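#' Empirical-Bayes location/scale batch adjustment (ComBat-style)
#'
#' From-scratch implementation of the parametric empirical-Bayes batch
#' correction of Johnson's location/scale model. Genes are standardised
#' (grand mean and optional covariate effects removed, divided by the pooled
#' standard deviation), per-batch additive (`gamma`) and multiplicative
#' (`delta^2`) effects are estimated, shrunk towards their across-gene priors
#' (normal prior on `gamma`, inverse-gamma on `delta^2`, hyperparameters by
#' method of moments, joint fixed-point iteration), and the adjusted values are
#' restored to the original scale.
#'
#' @param ds A [CellDataset].
#' @param layer Layer to correct (default `"data"`, falling back to the first
#'   layer present).
#' @param parametric Must be `TRUE`; only the parametric empirical-Bayes
#'   variant is implemented.
#' @param covariates Optional numeric cells x p matrix of biological
#'   covariates whose effects are protected during standardisation.
#' @param tol Relative tolerance of the EB fixed-point iteration.
#' @param max_iter Maximum fixed-point iterations.
#' @return An [IntegrationOutput] of kind `"matrix"` whose payload has the same
#'   cells x genes shape as the input layer. The fitted [CombatModel] is
#'   attached as attribute `"model"`.
#' @export
combat_fit_transform <- function(ds, layer = NULL, parametric = TRUE,
                                 covariates = NULL, tol = 1e-4, max_iter = 100L) {
  if (!parametric) stop("only the parametric empirical-Bayes variant is implemented")
  layer <- pick_layer(ds, layer)
  x <- as.matrix(ds$layers[[layer]])
  fit <- combat_correct(x, ds$batch, covariates = covariates,
                        tol = tol, max_iter = max_iter)
  out <- IntegrationOutput("combat", "matrix", fit$corrected,
                           params = list(layer = layer))
  attr(out, "model") <- fit$model
  out
}

pick_layer <- function(ds, layer) {
  if (is.null(layer)) {
    layer <- if ("data" %in% names(ds$layers)) "data" else names(ds$layers)[1]
  }
  if (is.null(layer) || !layer %in% names(ds$layers)) {
    stop(sprintf("layer '%s' not found", layer %||% "<none>"))
  }
  layer
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname combat_fit_transform
#' @param x Numeric cells x genes matrix.
#' @param batch Per-cell batch label.
#' @export
combat_correct <- function(x, batch, covariates = NULL,
                           tol = 1e-4, max_iter = 100L) {
  x <- as.matrix(x)
  batch <- as_ordered_factor(batch)
  stopifnot(nrow(x) == length(batch))
  n_b <- table(batch)
  if (any(n_b < 2L)) {
    stop(sprintf("batch '%s' has a single cell; ComBat needs >= 2 cells per batch",
                 names(n_b)[which(n_b < 2L)[1]]))
  }
  B <- nlevels(batch)
  if (B < 2L) {
    # single batch: nothing to correct
    return(list(corrected = x, model = NULL))
  }
  y <- t(x)                                   # genes x cells, ComBat convention
  n <- ncol(y); G <- nrow(y)

  # genes constant across all cells carry no batch information: left unchanged
  constant <- apply(y, 1, function(r) stats::var(r) == 0)
  if (any(constant)) {
    message(sprintf("%d constant gene(s) left unchanged by ComBat", sum(constant)))
  }
  active <- which(!constant)
  yg <- y[active, , drop = FALSE]

  design <- stats::model.matrix(~ 0 + batch)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    design <- cbind(design, covariates)
  }
  beta <- t(solve(crossprod(design), crossprod(design, t(yg))))  # genes x p
  grand_mean <- as.vector(beta[, seq_len(B), drop = FALSE] %*% (as.numeric(n_b) / n))
  stand_mean <- matrix(grand_mean, length(active), n)
  if (!is.null(covariates)) {
    stand_mean <- stand_mean +
      beta[, -(seq_len(B)), drop = FALSE] %*% t(covariates)
  }
  var_pooled <- rowMeans((yg - t(design %*% t(beta)))^2)
  var_pooled[var_pooled <= 0] <- .Machine$double.eps
  z <- (yg - stand_mean) / sqrt(var_pooled)

  batch_idx <- lapply(levels(batch), function(b) which(batch == b))
  gamma_hat <- sapply(batch_idx, function(ix) rowMeans(z[, ix, drop = FALSE]))
  delta_hat <- sapply(batch_idx, function(ix) apply(z[, ix, drop = FALSE], 1, stats::var))
  delta_hat[delta_hat <= 0] <- .Machine$double.eps

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(B)) {
    eb <- eb_fixed_point(z[, batch_idx[[b]], drop = FALSE],
                         gamma_hat[, b], delta_hat[, b],
                         tol = tol, max_iter = max_iter)
    gamma_star[, b] <- eb$gamma
    delta_star[, b] <- eb$delta
  }

  adj <- z
  for (b in seq_len(B)) {
    ix <- batch_idx[[b]]
    adj[, ix] <- (z[, ix, drop = FALSE] - gamma_star[, b]) / sqrt(delta_star[, b])
  }
  corrected_g <- adj * sqrt(var_pooled) + stand_mean
  out <- y
  out[active, ] <- corrected_g
  model <- structure(
    list(grand_mean = grand_mean, var_pooled = var_pooled,
         gamma = gamma_star, delta = delta_star,
         batch_levels = levels(batch), constant_genes = which(constant)),
    class = "CombatModel")
  list(corrected = t(out), model = model)
}

# joint EB fixed point for one batch: normal prior on gamma, inverse-gamma on
# delta^2, hyperparameters by method of moments (as in the parametric
# location/scale model)
eb_fixed_point <- function(zb, g_hat, d_hat, tol = 1e-4, max_iter = 100L) {
  nb <- ncol(zb)
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  if (!is.finite(t2) || t2 <= 0) t2 <- .Machine$double.eps
  m <- mean(d_hat); s2 <- stats::var(d_hat)
  if (!is.finite(s2) || s2 <= 0) s2 <- .Machine$double.eps
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_new <- g_hat; d_new <- d_hat
  change <- Inf; it <- 0L
  while (change > tol && it < max_iter) {
    g_old <- g_new; d_old <- d_new
    g_new <- (nb * t2 * g_hat + d_old * g_bar) / (nb * t2 + d_old)
    sum2 <- rowSums((zb - g_new)^2)
    d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), .Machine$double.eps),
                  abs(d_new - d_old) / d_old)
    it <- it + 1L
  }
  list(gamma = g_new, delta = d_new, iterations = it)
}
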