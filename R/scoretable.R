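#' Methods x metrics score table
#'
#' Holds the raw metric values for a set of integration methods together with
#' each metric's category (`batch` correction vs `bio` conservation) and
#' orientation (`higher_better` / `lower_better`). Missing entries are allowed
#' and mark metrics that were not evaluated for a method (for example PCA-based
#' metrics on a graph-only output).
#'
#' @param raw Numeric methods x metrics matrix with dimnames; `NA` marks a
#'   missing (not-evaluated) entry.
#' @param category Named character vector, one of `"batch"`/`"bio"` per metric.
#' @param orientation Named character vector, `"higher_better"` or
#'   `"lower_better"` per metric.
#' @param rescaled Rescaling already applied to `raw`:
#'   `"none"`, `"minmax_scores"` or `"minmax_ranks"`.
#' @return A `ScoreTable` object.
#' @export
ScoreTable <- function(raw, category, orientation = NULL, rescaled = "none") {
  raw <- as.matrix(raw)
  # R stores zero-length dimnames as NULL, so empty tables bypass the check
  if ((nrow(raw) > 0L && is.null(rownames(raw))) ||
      (ncol(raw) > 0L && is.null(colnames(raw)))) {
    stop("raw must carry method (row) and metric (column) names")
  }
  metrics <- colnames(raw) %||% character(0)
  if (is.null(orientation)) {
    orientation <- stats::setNames(rep("higher_better", length(metrics)), metrics)
  }
  category <- category[metrics]
  orientation <- orientation[metrics]
  if (anyNA(category) || !all(category %in% c("batch", "bio"))) {
    stop("every metric needs a category of 'batch' or 'bio'")
  }
  if (anyNA(orientation) || !all(orientation %in% c("higher_better", "lower_better"))) {
    stop("every metric needs an orientation")
  }
  names(category) <- names(orientation) <- metrics
  structure(list(raw = raw, category = category, orientation = orientation,
                 rescaled = rescaled),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, digits = 3, ...) {
  cat(sprintf("ScoreTable: %d methods x %d metrics (rescaled: %s)\n",
              nrow(x$raw), ncol(x$raw), x$rescaled))
  print(round(x$raw, digits))
  invisible(x)
}

#' @export
dim.ScoreTable <- function(x) dim(x$raw)

st_methods <- function(t) rownames(t$raw) %||% character(0)
st_metrics <- function(t) colnames(t$raw) %||% character(0)

#' Persist / load a score table
#'
#' CSV uses a lossless long layout (`method,metric,value,category,orientation`)
#' in which a missing score is an empty `value` field; JSON stores the matrix
#' with `null` for missing entries. Both formats round-trip exactly, and a
#' table written to both formats reads back identically.
#'
#' @param t A [ScoreTable].
#' @param path Output file.
#' @param format `"csv"` or `"json"`; default guessed from the file extension.
#' @return `path` (write) or a [ScoreTable] (read).
#' @export
write_scores <- function(t, path, format = NULL) {
  format <- resolve_score_format(path, format)
  if (format == "csv") {
    long <- expand.grid(method = st_methods(t), metric = st_metrics(t),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    long$value <- as.vector(t$raw)
    long$category <- unname(t$category[long$metric])
    long$orientation <- unname(t$orientation[long$metric])
    long$rescaled <- rep(t$rescaled, nrow(long))
    utils::write.csv(long, path, row.names = FALSE, na = "")
  } else {
    obj <- list(methods = st_methods(t), metrics = st_metrics(t),
                category = as.list(t$category),
                orientation = as.list(t$orientation),
                rescaled = t$rescaled,
                raw = apply(t$raw, 1, function(r) as.list(r), simplify = FALSE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path, format = NULL) {
  format <- resolve_score_format(path, format)
  if (format == "csv") {
    long <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("method", "metric", "value", "category", "orientation")
    if (!all(need %in% names(long))) {
      stop(sprintf("schema error: '%s' lacks columns %s", path,
                   paste(setdiff(need, names(long)), collapse = ", ")))
    }
    methods_ <- unique(long$method)
    metrics_ <- unique(long$metric)
    raw <- matrix(NA_real_, length(methods_), length(metrics_),
                  dimnames = list(methods_, metrics_))
    raw[cbind(match(long$method, methods_), match(long$metric, metrics_))] <- long$value
    meta <- long[!duplicated(long$metric), ]
    if (length(methods_) == 0L) {
      return(ScoreTable(raw, category = stats::setNames(character(0), character(0)),
                        orientation = stats::setNames(character(0), character(0))))
    }
    ScoreTable(raw,
               category = stats::setNames(meta$category, meta$metric),
               orientation = stats::setNames(meta$orientation, meta$metric),
               rescaled = if ("rescaled" %in% names(long) && nrow(long)) long$rescaled[1] else "none")
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    methods_ <- as.character(unlist(obj$methods))
    metrics_ <- as.character(unlist(obj$metrics))
    raw <- matrix(NA_real_, length(methods_), length(metrics_),
                  dimnames = list(methods_, metrics_))
    if (length(methods_) == 0L || length(metrics_) == 0L) {
      return(ScoreTable(raw,
                        category = stats::setNames(character(0), character(0)),
                        orientation = stats::setNames(character(0), character(0))))
    }
    for (i in seq_along(methods_)) {
      row <- obj$raw[[i]]
      for (j in seq_along(metrics_)) {
        v <- row[[metrics_[j]]]
        if (!is.null(v)) raw[i, j] <- as.numeric(v)
      }
    }
    ScoreTable(raw,
               category = unlist(obj$category)[metrics_],
               orientation = unlist(obj$orientation)[metrics_],
               rescaled = if (!is.null(obj$rescaled)) obj$rescaled else "none")
  }
}

resolve_score_format <- function(path, format) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  match.arg(format, c("csv", "json"))
}
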