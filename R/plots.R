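#' Score visualisations: dotplot, lollipop, radar
#'
#' * `dotplot` — methods x metrics grid; dot size and colour encode the
#'   scaled score, missing entries draw no dot.
#' * `lollipop` — per-method composite scores (batch correction,
#'   bio-conservation, overall) as stems with end points.
#' * `radar` — one closed polygon per method over the metric axes (missing
#'   metrics are dropped from the axes).
#'
#' Layout is fully deterministic: methods and metrics keep their table order.
#'
#' @param table A [ScoreTable] (rescaled or raw) or, for `kind = "lollipop"`,
#'   optionally a `CompositeScores` table.
#' @param kind One of `"dotplot"`, `"lollipop"`, `"radar"`.
#' @param w_batch,w_bio Composite weights used when a lollipop needs to be
#'   derived from a [ScoreTable].
#' @return A `ggplot` object.
#' @export
plot_scores <- function(table, kind = c("dotplot", "lollipop", "radar"),
                        w_batch = 0.5, w_bio = 0.5) {
  kind <- match.arg(kind)
  if (inherits(table, "ScoreTable") && nrow(table$raw) == 0L) {
    stop("empty score table")
  }
  switch(kind,
         dotplot = plot_dotplot(table),
         lollipop = plot_lollipop(table, w_batch, w_bio),
         radar = plot_radar(table))
}

scores_long <- function(table) {
  raw <- table$raw
  df <- expand.grid(method = rownames(raw), metric = colnames(raw),
                    KEEP.OUT.ATTRS = FALSE)
  df$method <- factor(df$method, levels = rev(rownames(raw)))
  df$metric <- factor(df$metric, levels = colnames(raw))
  df$value <- as.vector(raw)
  df$category <- table$category[as.character(df$metric)]
  df
}

plot_dotplot <- function(table) {
  df <- scores_long(table)
  ggplot2::ggplot(df[!is.na(df$value), , drop = FALSE],
                  ggplot2::aes(x = .data$metric, y = .data$method,
                               size = .data$value, colour = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_continuous(limits = c(0, 1), range = c(0.5, 6)) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$category),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, size = "score", colour = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

plot_lollipop <- function(table, w_batch, w_bio) {
  cs <- if (inherits(table, "CompositeScores")) table else
    composite_scores(table, w_batch, w_bio,
                     rescale_mode = if (table$rescaled == "none") "minmax_ranks" else "none")
  df <- data.frame(
    method = rep(cs$method, 3),
    component = factor(rep(c("batch_correction", "bio_conservation", "overall"),
                           each = nrow(cs)),
                       levels = c("batch_correction", "bio_conservation", "overall")),
    value = c(cs$batch_correction, cs$bio_conservation, cs$overall))
  df$method <- factor(df$method, levels = rev(cs$method[order(-replace(cs$overall, is.na(cs$overall), -Inf))]))
  ggplot2::ggplot(df[!is.na(df$value), , drop = FALSE],
                  ggplot2::aes(x = .data$value, y = .data$method)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$value, yend = .data$method),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$component), size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$component)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "score", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

plot_radar <- function(table) {
  df <- scores_long(table)
  df <- df[!is.na(df$value), , drop = FALSE]
  # close the polygons
  first_metric <- levels(df$metric)[1]
  closing <- df[df$metric == first_metric, , drop = FALSE]
  df2 <- rbind(df, closing)
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$metric, y = .data$value,
                                    group = .data$method, colour = .data$method)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a score plot to SVG or PNG
#'
#' @param p A `ggplot` (from [plot_scores()]).
#' @param path Output file; format chosen by extension (`.svg` or `.png`).
#' @param width,height Size in inches.
#' @param dpi Resolution for PNG.
#' @return `path`, invisibly.
#' @export
save_plot <- function(p, path, width = 7, height = 5, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("svg", "png")) stop("path must end in .svg or .png")
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
    print(p)
    grDevices::dev.off()
  } else {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  }
  invisible(path)
}
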