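# ggplot2 graphics: matrix heatmaps (square/triangular), distance decay,
# saddle with its cutoff bars, aggregate grids, multi-window score heatmaps
# and pair-filter diagnostics. All functions return ggplot objects (or a
# patchwork composition for the saddle plot).

.matrix_long <- function(cm, region, oe = FALSE, log2 = FALSE) {
  M <- fetch(cm, region, oe = oe, log2 = log2)
  rows <- as.integer(rownames(M)); cols <- as.integer(colnames(M))
  out <- tidyr::expand_grid(i = seq_along(rows), j = seq_along(cols))
  out$value <- M[cbind(out$i, out$j)]
  out$x <- (cm$bins$start[cols[out$j]] + cm$bins$end[cols[out$j]]) / 2
  out$y <- (cm$bins$start[rows[out$i]] + cm$bins$end[rows[out$i]]) / 2
  out
}

#' Square contact-matrix heatmap
#'
#' @param cm A `contact_matrix`.
#' @param region Region to plot (string or tibble row).
#' @param oe,log2 Plot O/E (optionally log2) instead of normalised counts.
#' @return A ggplot object.
#' @export
plot_matrix <- function(cm, region, oe = FALSE, log2 = FALSE) {
  d <- .matrix_long(cm, region, oe = oe, log2 = log2)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (oe) (if (log2) "log2 O/E" else "O/E") else "contacts")
  if (oe) {
    p <- p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                           midpoint = if (log2) 0 else 1)
  } else {
    p <- p + ggplot2::scale_fill_gradient(low = "white", high = "darkred")
  }
  p + ggplot2::theme_minimal()
}

#' Triangular (rotated half-matrix) heatmap
#' @inheritParams plot_matrix
#' @return A ggplot object.
#' @export
plot_triangular <- function(cm, region, oe = FALSE, log2 = FALSE) {
  d <- .matrix_long(cm, region, oe = oe, log2 = log2)
  d <- d[d$y <= d$x, ]
  d$mid <- (d$x + d$y) / 2
  d$height <- (d$x - d$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$height, fill = .data$value)) +
    ggplot2::geom_tile(width = cm$bin_size, height = cm$bin_size) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::labs(x = NULL, y = "distance", fill = "contacts") +
    ggplot2::theme_minimal()
}

#' Distance-decay (expected value) plot
#' @param cm A `contact_matrix` (expected computed on demand), or several in
#'   a named list.
#' @return A ggplot object with log-log axes.
#' @export
plot_distance_decay <- function(cm) {
  if (inherits(cm, "contact_matrix")) cm <- list(sample = cm)
  d <- purrr::imap_dfr(cm, function(x, nm) {
    mutate(expected_profile(x), sample = nm)
  })
  d <- d[d$chrom == "genome-wide" & d$distance > 0 & !is.na(d$expected) & d$expected > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance, y = .data$expected,
                                  colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic distance (bp)", y = "expected contacts") +
    ggplot2::theme_minimal()
}

#' Saddle plot with EV-cutoff bars underneath
#' @param saddle A `saddle_result`.
#' @return A patchwork composition (heatmap over bar panel) when patchwork
#'   is installed, otherwise the heatmap alone.
#' @export
plot_saddle <- function(saddle) {
  d <- tidy(saddle)
  lab <- if (isTRUE(saddle$log2)) "mean log2 O/E" else "mean O/E"
  ph <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group2, y = .data$group1,
                                        fill = .data$mean_oe)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = if (isTRUE(saddle$log2)) 0 else 1) +
    ggplot2::labs(x = NULL, y = "EV group", fill = lab) +
    ggplot2::theme_minimal()
  bars <- tibble(group = seq_along(saddle$group_ev), ev = saddle$group_ev)
  pb <- ggplot2::ggplot(bars, ggplot2::aes(x = .data$group, y = .data$ev,
                                           fill = .data$ev > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "red", `FALSE` = "blue")) +
    ggplot2::labs(x = "EV group", y = "mean EV") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    return(patchwork::wrap_plots(ph, pb, ncol = 1, heights = c(4, 1)))
  }
  ph
}

#' Aggregate-grid heatmap
#' @param agg An `aggregate_result`.
#' @return A ggplot object.
#' @export
plot_aggregate <- function(agg) {
  d <- tidy(agg)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = agg$value) +
    ggplot2::theme_minimal()
}

#' Multi-window score heatmap ("flame plot")
#'
#' Visualises a multi-window score track (insulation across window sizes)
#' as a heatmap with the smallest window at the bottom.
#'
#' @param track Score-track tibble with several `score_<bp>` columns.
#' @param chrom Chromosome to plot (default: first).
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(track, chrom = NULL) {
  chrom <- chrom %||% track$chrom[1]
  cols <- grep("^score_", names(track), value = TRUE)
  w <- as.numeric(sub("score_", "", cols))
  d <- track[track$chrom == chrom, c("start", "end", cols)] |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "window", values_to = "score")
  d$window_bp <- w[match(d$window, cols)]
  d$window <- factor(d$window, levels = cols[order(w)])  # smallest at bottom
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$window, fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "darkorange", mid = "white",
                                  high = "darkgreen", midpoint = 0) +
    ggplot2::labs(x = "position (bp)", y = "window") +
    ggplot2::theme_minimal()
}

#' Pair-filter diagnostic plots
#'
#' @param diagnostics Output of [pair_diagnostics()].
#' @param stats Optional per-filter counts tibble from [filter_pairs()].
#' @return Named list of ggplot objects: `ligation_error`, `insert_size`
#'   and (with `stats`) `filters`.
#' @export
plot_pair_stats <- function(diagnostics, stats = NULL) {
  out <- list()
  le <- diagnostics$ligation_error
  out$ligation_error <- ggplot2::ggplot(
    le, ggplot2::aes(x = .data$sep_mid, y = .data$fraction,
                     colour = .data$orientation)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genomic separation (bp)", y = "fraction of pairs") +
    ggplot2::theme_minimal()
  out$insert_size <- ggplot2::ggplot(diagnostics$insert_size,
                                     ggplot2::aes(x = .data$insert_size)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = diagnostics$median_insert_size,
                        linetype = "dashed") +
    ggplot2::labs(x = "sum of restriction-site distances (bp)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(stats)) {
    d <- stats[!stats$filter %in% c("total"), ]
    out$filters <- ggplot2::ggplot(d, ggplot2::aes(x = .data$filter, y = .data$removed)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "read pairs") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
  out
}

#' @export
autoplot.contact_matrix <- function(object, region = NULL, ...) {
  region <- region %||% object$bins$chrom[1]
  plot_matrix(object, region, ...)
}

#' @export
autoplot.saddle_result <- function(object, ...) plot_saddle(object)

#' @export
autoplot.aggregate_result <- function(object, ...) plot_aggregate(object)

#' @export
autoplot.pca_result <- function(object, ...) {
  d <- object$coordinates
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  label = .data$sample)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * (object$explained_variance[2] %||% NA))) +
    ggplot2::theme_minimal()
}
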