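#' Plot methods
#'
#' `autoplot()` methods produce ggplot2 figures for the package's result
#' types; the matching `plot()` methods print them.
#'
#' @param object,x The object to plot.
#' @param ... Unused.
#' @name plots
NULL

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.composition <- function(object, ...) {
  d <- dplyr::arrange(object$composition, dplyr::desc(.data$fraction))
  d$cell_type <- factor(d$cell_type, levels = rev(d$cell_type))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "estimated fraction", y = NULL,
                  title = "Cell-type composition") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.reference_atlas <- function(object, ...) {
  d <- tidy.reference_atlas(object)
  d$block_id <- factor(d$block_id, levels = rev(rownames(object$A)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_type, y = .data$block_id,
                                  fill = .data$u)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#1b5e90", high = "#f8f4a6",
                                 limits = c(0, 1), name = "U proportion") +
    ggplot2::labs(x = NULL, y = NULL, title = "Reference atlas") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.methylation_segmentation <- function(object, ...) {
  d <- object$blocks
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start_bp, xend = .data$end_bp,
                                  y = .data$score, yend = .data$score)) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "block score",
                  title = "Methylation blocks") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.spike_experiment <- function(object, ...) {
  d <- object$estimates[object$estimates$cell_type == object$target_type, ]
  eps <- min(d$concentration[d$concentration > 0]) / 3
  d$conc_plot <- pmax(d$concentration, eps)
  d$frac_plot <- pmax(d$fraction, eps / 3, na.rm = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_plot, y = .data$frac_plot)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10(labels = function(v) sprintf("%g%%", 100 * v)) +
    ggplot2::scale_y_log10(labels = function(v) sprintf("%g%%", 100 * v)) +
    ggplot2::labs(x = "true spike-in fraction (0 shown at left edge)",
                  y = "estimated fraction",
                  title = sprintf("Spike-in series: %s", object$target_type)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.mixture_recovery <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$true, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "true fraction", y = "estimated fraction",
                  title = "Mixture recovery") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
plot.composition <- function(x, ...) print(autoplot.composition(x, ...))

#' @rdname plots
#' @export
plot.reference_atlas <- function(x, ...) print(autoplot.reference_atlas(x, ...))

#' @rdname plots
#' @export
plot.spike_experiment <- function(x, ...) print(autoplot.spike_experiment(x, ...))

#' @rdname plots
#' @export
plot.mixture_recovery <- function(x, ...) print(autoplot.mixture_recovery(x, ...))
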