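#' Broom-style tidiers
#'
#' `tidy()` returns the per-unit results of a fitted object as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A fitted object (`composition`, `methylation_segmentation`,
#'   `reference_atlas`, `spike_experiment`, `mixture_recovery`).
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.composition <- function(x, ...) {
  x$composition
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.composition <- function(x, ...) {
  tibble(residual = x$residual, n_markers_used = x$n_markers_used,
         n_markers_dropped = length(x$dropped),
         degenerate = x$degenerate, weighted = x$weighted)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.methylation_segmentation <- function(x, ...) {
  x$blocks
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.methylation_segmentation <- function(x, ...) {
  tibble(n_blocks = nrow(x$blocks), total_score = x$total_score,
         max_block_bp = x$params$max_block_bp,
         alpha_c = x$params$alpha_c, alpha_t = x$params$alpha_t)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.reference_atlas <- function(x, ...) {
  long <- as_tibble(x$A, rownames = "block_id")
  long <- tidyr::pivot_longer(long, -"block_id",
                              names_to = "cell_type", values_to = "u")
  long$imputed <- as.vector(t(x$missing))[
    match(paste(long$block_id, long$cell_type),
          paste(rep(rownames(x$A), each = ncol(x$A)),
                rep(colnames(x$A), nrow(x$A))))]
  dplyr::left_join(long,
                   x$markers[, c("block_id", "group", "direction")],
                   by = "block_id")
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.reference_atlas <- function(x, ...) {
  tibble(n_markers = nrow(x$A), n_cell_types = ncol(x$A),
         n_imputed = sum(x$missing),
         min_cpgs = x$params$min_cpgs,
         u_threshold = x$params$u_threshold,
         m_threshold = x$params$m_threshold)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.spike_experiment <- function(x, ...) {
  x$estimates
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.spike_experiment <- function(x, ...) {
  dl <- detection_limit(x)
  tibble(target_type = x$target_type,
         detection_limit = dl$detection_limit,
         zero_max = dl$zero_max,
         repetitions = x$params$repetitions)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.mixture_recovery <- function(x, ...) {
  x$estimates
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.mixture_recovery <- function(x, ...) {
  tibble(mae = x$mae, n_mixtures = x$params$n_mixtures,
         k_components = x$params$k_components)
}
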