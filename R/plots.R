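# Rendering layer: thin ggplot2 wrappers over the plot-data builders.
# All values shown come verbatim from the builder output; rendering never
# recomputes statistics.

cohort_fill <- function() ggplot2::scale_fill_manual(
  values = c(control = "firebrick2", treatment = "white"))
cohort_color <- function() ggplot2::scale_color_manual(
  values = c(control = "firebrick2", treatment = "grey30"))

#' Boxplot of per-sample intensity distributions
#'
#' Control samples red, treatment samples white; Tukey 1.5 IQR whiskers
#' with outliers as dots, straight from [build_distribution_summaries()].
#'
#' @param summaries Output of [build_distribution_summaries()].
#' @return A ggplot object.
#' @export
plot_boxplots <- function(summaries) {
  box <- summaries$boxplot
  box$sample_id <- factor(box$sample_id, levels = box$sample_id)
  out <- tidyr::unnest(box[, c("sample_id", "cohort", "outliers")],
                       "outliers")
  ggplot2::ggplot(box, ggplot2::aes(x = .data$sample_id)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$ymin, lower = .data$lower,
                   middle = .data$middle, upper = .data$upper,
                   ymax = .data$ymax, fill = .data$cohort),
      stat = "identity") +
    ggplot2::geom_point(data = out, ggplot2::aes(y = .data$outliers),
                        shape = 1, size = 0.8) +
    cohort_fill() +
    ggplot2::labs(x = "sample", y = "intensity") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Mean-variance / mean-median diagnostic plots
#'
#' @param summaries Output of [build_distribution_summaries()].
#' @param which `"variance"` or `"median"`.
#' @return A ggplot object, one panel per cohort.
#' @export
plot_mean_spread <- function(summaries, which = c("variance", "median")) {
  which <- match.arg(which)
  d <- if (which == "variance") summaries$mean_variance else summaries$mean_median
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data[[which]])) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = "peptide mean", y = paste("peptide", which)) +
    ggplot2::theme_bw()
}

#' @method autoplot positional_heatmap
#' @export
autoplot.positional_heatmap <- function(object, ...) {
  samples <- attr(object, "samples")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(samples$sample_id),
                              names_to = "sample_id", values_to = "value")
  long$sample_id <- factor(long$sample_id, levels = samples$sample_id)
  long$spot_id <- factor(long$spot_id,
                         levels = rev(object$spot_id[order(object$start)]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$spot_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "sample", y = "peptide (N- to C-terminus)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method autoplot synoptic_heatmap
#' @export
autoplot.synoptic_heatmap <- function(object, ...) {
  samples <- attr(object, "samples")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(samples$sample_id),
                              names_to = "sample_id", values_to = "value")
  long$sample_id <- factor(long$sample_id, levels = samples$sample_id)
  long$spot_id <- factor(long$spot_id, levels = rev(object$spot_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$spot_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "sample", y = "peptide (subset rank)") +
    ggplot2::theme_minimal()
}

#' @method autoplot band_profile
#' @export
autoplot.band_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  panels <- dplyr::bind_rows(
    tibble::tibble(panel = "control", position = d$position,
                   center = d$control_center, lower = d$control_lower,
                   upper = d$control_upper),
    tibble::tibble(panel = "treatment", position = d$position,
                   center = d$treatment_center, lower = d$treatment_lower,
                   upper = d$treatment_upper),
    tibble::tibble(panel = "effect (delta RFU)", position = d$position,
                   center = d$effect, lower = d$effect, upper = d$effect)
  )
  panels$panel <- factor(panels$panel,
                         levels = c("control", "treatment",
                                    "effect (delta RFU)"))
  # single-sample cohorts have no spread estimate; draw their center only
  banded <- panels[!is.na(panels$lower) & !is.na(panels$upper), ]
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(data = banded,
                         ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$center)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "peptide start position", y = "intensity") +
    ggplot2::theme_bw()
}

#' @method autoplot strip_data
#' @export
autoplot.strip_data <- function(object, seed = 1L, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$peptide, y = .data$value,
                               color = .data$cohort)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.2,
                                                            height = 0,
                                                            seed = seed)) +
    cohort_color() +
    ggplot2::labs(x = "peptide", y = "intensity") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method autoplot epitope_map
#' @export
autoplot.epitope_map <- function(object, ...) {
  lim <- attr(object, "color_limits")
  ggplot2::ggplot(tibble::as_tibble(object)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$lane - 0.4,
                                    ymax = .data$lane + 0.4,
                                    fill = .data$delta_rfu)) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = lim, name = "delta RFU") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "protein position", y = "lane") +
    ggplot2::theme_minimal()
}

#' Dendrogram of the UPGMA sample clustering
#'
#' @param result A `cluster_result` from [upgma_tree()].
#' @param color_by_cohort Color tip labels by cohort (`TRUE`) or leave
#'   uncoded (`FALSE`); both variants are part of the standard output.
#' @param cohorts Named cohort vector (as attached by [sample_vectors()]),
#'   required when `color_by_cohort = TRUE`.
#' @return A ggplot object drawing the merge tree.
#' @export
plot_dendrogram <- function(result, color_by_cohort = FALSE, cohorts = NULL) {
  hc <- result$tree
  stopifnot(!is.null(hc))
  n <- length(hc$labels)
  # leaf x positions in plotting order
  xpos <- setNames(match(seq_len(n), hc$order), seq_len(n))
  seg <- NULL
  node_x <- numeric(nrow(hc$merge)); node_y <- hc$height
  xy <- function(k) {
    if (k < 0) c(xpos[[as.character(-k)]], 0) else c(node_x[k], node_y[k])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- xy(hc$merge[i, 1]); b <- xy(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    seg <- dplyr::bind_rows(seg, tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], hc$height[i], hc$height[i]),
      yend = c(hc$height[i], hc$height[i], b[2])))
  }
  leaves <- tibble::tibble(x = unname(xpos), y = 0,
                           label = hc$labels,
                           cohort = if (!is.null(cohorts))
                             unname(cohorts[hc$labels]) else "sample")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "merge height (Euclidean)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
  if (color_by_cohort && !is.null(cohorts)) {
    p <- p + ggplot2::geom_point(data = leaves,
                                 ggplot2::aes(x = .data$x, y = .data$y,
                                              color = .data$cohort),
                                 size = 2) + cohort_color()
  }
  p
}

#' PCA scatter of clustered samples
#'
#' @param embed Output of [pca_embed()].
#' @param labels Optional cluster labels (named by sample) to shape the
#'   points by cluster.
#' @param color_by_cohort Color points by cohort; both the coded and
#'   uncoded variants are produced in a standard run.
#' @return A ggplot object.
#' @export
plot_pca <- function(embed, labels = NULL, color_by_cohort = TRUE) {
  d <- embed
  if (!is.null(labels)) d$cluster <- factor(labels[d$sample_id])
  ve <- attr(embed, "var_explained")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_bw()
  aes_extra <- ggplot2::aes()
  if (!is.null(labels) && color_by_cohort) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$cohort,
                                              shape = .data$cluster), size = 3) +
      cohort_color()
  } else if (!is.null(labels)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$cluster), size = 3)
  } else if (color_by_cohort) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$cohort), size = 3) +
      cohort_color()
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p
}

#' Render a plot to an image file
#'
#' Writes a ggplot (or any plot-data object with an [autoplot()] method)
#' to PNG (300 dpi), SVG, or PDF. Rendering never alters plot-data values.
#'
#' @param plot A ggplot object or a plot-data object with an `autoplot()`
#'   method.
#' @param path Output file path.
#' @param format `"png"`, `"svg"`, or `"pdf"`; defaults to the `path`
#'   extension.
#' @param width,height Device size in inches.
#' @param dpi Resolution for PNG output.
#' @return `path`, invisibly.
#' @export
render <- function(plot, path, format = tools::file_ext(path),
                   width = 7, height = 5, dpi = 300) {
  if (!format %in% c("png", "svg", "pdf")) {
    abort(sprintf("Unknown image format '%s'; use png, svg, or pdf.", format),
          class = "immunosig_validation_error")
  }
  if (!inherits(plot, "ggplot")) plot <- autoplot(plot)
  switch(format,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = dpi),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height))
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
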