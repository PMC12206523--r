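#' Built-in metric registry
#'
#' One row per metric known to the scoring pipeline: its score-table category
#' (batch correction vs bio-conservation, following the two blocks of the
#' benchmark layout), its orientation as stored (all built-in metrics are
#' stored oriented so that higher = better), whether it needs numerical
#' components (an embedding or matrix — such metrics cannot be computed for
#' graph-only outputs) and whether it needs cell-type labels.
#'
#' @return A `data.frame` with columns `metric`, `category`, `orientation`,
#'   `needs_embedding`, `needs_celltype`.
#' @export
metric_registry <- function() {
  data.frame(
    metric = c("ilisi", "kbet", "pcr_batch", "pcr_comparison", "dpca", "batch_asw",
               "clisi", "nmi", "ari", "celltype_asw", "graph_connectivity",
               "scgraph", "cc_conservation"),
    category = c(rep("batch", 6), rep("bio", 7)),
    orientation = "higher_better",
    needs_embedding = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                        FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    needs_celltype = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                       TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Is a metric applicable to an integration output?
#'
#' Metrics that require numerical components (PCA-based scores, silhouettes,
#' scGraph, cell-cycle conservation) cannot be computed for graph-kind
#' outputs; graph-based metrics apply to every kind because a kNN graph can
#' always be derived from an embedding or matrix.
#'
#' @param output An [IntegrationOutput] (or its `kind` string).
#' @param metric Metric name from [metric_registry()].
#' @return Logical flag.
#' @export
metric_applicability <- function(output, metric) {
  kind <- if (inherits(output, "IntegrationOutput")) output$kind else output
  reg <- metric_registry()
  if (!metric %in% reg$metric) stop(sprintf("unknown metric '%s'", metric))
  !(kind == "graph" && reg$needs_embedding[reg$metric == metric])
}

#' Min-max rescaling of a score table
#'
#' Per metric column: values are first oriented (lower-better columns are
#' negated) and then either min-max rescaled directly (`minmax_scores`) or
#' replaced by average ranks which are then min-max rescaled
#' (`minmax_ranks`). Rank rescaling is invariant under any strictly monotone
#' transform of the raw column, which is what makes rank-based rescaling more
#' stable when integrations are added or removed. Constant columns map to 0.5
#' and missing entries stay missing. Columns with fewer than two non-missing
#' values are treated as constant.
#'
#' @param table A [ScoreTable].
#' @param mode `"minmax_scores"` or `"minmax_ranks"`.
#' @return A [ScoreTable] with values in \[0, 1\], all orientations
#'   `higher_better`, and its `rescaled` field set to `mode`.
#' @export
rescale_scores <- function(table, mode = c("minmax_ranks", "minmax_scores")) {
  mode <- match.arg(mode)
  raw <- table$raw
  out <- raw
  for (m in colnames(raw)) {
    v <- raw[, m]
    if (table$orientation[m] == "lower_better") v <- -v
    ok <- !is.na(v)
    if (sum(ok) == 0L) next
    if (mode == "minmax_ranks") v[ok] <- rank(v[ok], ties.method = "average")
    rng <- range(v[ok])
    out[, m] <- if (diff(rng) == 0) ifelse(ok, 0.5, NA_real_) else (v - rng[1]) / diff(rng)
  }
  ScoreTable(out, category = table$category,
             orientation = stats::setNames(rep("higher_better", ncol(raw)), colnames(raw)),
             rescaled = mode)
}

#' Composite batch-correction, bio-conservation and overall scores
#'
#' Each composite is the mean of the method's non-missing rescaled metrics of
#' that category, and the overall score their weighted sum
#' `overall = w_batch * batch + w_bio * bio`. A method whose metrics of a
#' category are all missing gets a missing composite (and a missing overall).
#'
#' @param table A [ScoreTable]; rescaled with [rescale_scores()] first unless
#'   `rescale_mode = "none"` or the table is already rescaled.
#' @param w_batch,w_bio Non-negative weights summing to 1 (default 0.5/0.5).
#' @param rescale_mode `"minmax_ranks"` (default), `"minmax_scores"` or
#'   `"none"`.
#' @return A `CompositeScores` data.frame with columns `method`,
#'   `batch_correction`, `bio_conservation`, `overall`; weights and mode are
#'   attached as attributes.
#' @export
composite_scores <- function(table, w_batch = 0.5, w_bio = 0.5,
                             rescale_mode = c("minmax_ranks", "minmax_scores", "none")) {
  rescale_mode <- match.arg(rescale_mode)
  if (abs(w_batch + w_bio - 1) > 1e-8 || w_batch < 0 || w_bio < 0) {
    stop("weights must be non-negative and sum to 1")
  }
  if (rescale_mode != "none" && table$rescaled == "none") {
    table <- rescale_scores(table, rescale_mode)
  }
  cat_mean <- function(row, cat) {
    v <- row[table$category == cat]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  batch <- apply(table$raw, 1, cat_mean, cat = "batch")
  bio <- apply(table$raw, 1, cat_mean, cat = "bio")
  cs <- data.frame(method = rownames(table$raw),
                   batch_correction = batch, bio_conservation = bio,
                   overall = w_batch * batch + w_bio * bio,
                   row.names = NULL, stringsAsFactors = FALSE)
  attr(cs, "weights") <- c(w_batch = w_batch, w_bio = w_bio)
  attr(cs, "rescale_mode") <- if (table$rescaled != "none") table$rescaled else "none"
  class(cs) <- c("CompositeScores", "data.frame")
  cs
}

#' Rank methods by overall score
#'
#' Descending by overall score; ties broken by bio-conservation score, then by
#' method name (ascending), so the ranking is invariant to the input order of
#' methods. Rank 1 is the best method. Methods with a missing overall score
#' are placed last.
#'
#' @param cs A `CompositeScores` table from [composite_scores()].
#' @return `cs` sorted by rank, with a `rank` column added.
#' @export
overall_and_rank <- function(cs) {
  ord <- order(-xtfrm(replace(cs$overall, is.na(cs$overall), -Inf)),
               -xtfrm(replace(cs$bio_conservation, is.na(cs$bio_conservation), -Inf)),
               cs$method)
  out <- cs[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
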