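#' Cell-type-specific methylation markers
#'
#' Markers are blocks differentially methylated in exactly one cell-type
#' group versus all others. To tolerate outliers, the contrast compares
#' quantiles rather than extremes: for unmethylated (direction `"U"`)
#' markers, the default delta is the 2.5th percentile of the background
#' minus the 75th percentile of the target, so one aberrant target sample
#' and a handful of background samples are forgiven. Low-coverage block
#' means, whose estimation error is large, are first replaced by the neutral
#' value 0.5, which shrinks their delta and downgrades their rank.
#'
#' @name markers
NULL

#' Replace low-coverage block means by a neutral fill value
#'
#' Entries with fewer than `min_obs` observations (sequenced CpG calls), or
#' missing entirely, are replaced by `fill_value`; all others pass through.
#' Adds/overwrites the column `value`.
#'
#' @param beta Long block-by-sample table from [block_means()] /
#'   [beta_table()] (columns `mean`, `n_obs`).
#' @param min_obs Minimum observations for a mean to be trusted (default 25).
#' @param fill_value Neutral substitute (default 0.5).
#' @return `beta` with a `value` column.
#' @export
fill_low_coverage <- function(beta, min_obs = 25, fill_value = 0.5) {
  stopifnot(fill_value >= 0, fill_value <= 1)
  dplyr::mutate(beta, value = ifelse(
    is.na(.data$mean) | .data$n_obs < min_obs, fill_value, .data$mean))
}

#' Quantile-contrast methylation delta
#'
#' Direction `"U"` (target unmethylated):
#' `Q_bg_quant(background) - Q_(1 - tg_quant)(target)`.
#' Direction `"M"` (target methylated):
#' `Q_tg_quant(target) - Q_(1 - bg_quant)(background)`.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param target,background Non-empty numeric vectors of block means in
#'   `[0, 1]`.
#' @param direction `"U"` or `"M"`.
#' @param tg_quant,bg_quant Quantile parameters in (0, 0.5) (defaults 0.25
#'   and 0.025).
#' @return List with `delta`, `tg_quantile_value`, `bg_quantile_value`.
#' @export
marker_delta <- function(target, background, direction = c("U", "M"),
                         tg_quant = 0.25, bg_quant = 0.025) {
  direction <- match.arg(direction)
  if (length(target) == 0 || length(background) == 0) {
    abort("empty target or background group")
  }
  stopifnot(tg_quant > 0, tg_quant < 0.5, bg_quant > 0, bg_quant < 0.5)
  if (direction == "U") {
    tq <- quantile_lin(target, 1 - tg_quant)
    bq <- quantile_lin(background, bg_quant)
    delta <- bq - tq
  } else {
    tq <- quantile_lin(target, tg_quant)
    bq <- quantile_lin(background, 1 - bg_quant)
    delta <- tq - bq
  }
  list(delta = delta, tg_quantile_value = tq, bg_quantile_value = bq)
}

# Row-wise type-7 quantile of a matrix (blocks x samples).
row_quantile <- function(m, p) {
  apply(m, 1, quantile_lin, probs = p)
}

marker_table_for_sets <- function(mat, blocks, target_cols, background_cols,
                                  group, direction, tg_quant, bg_quant) {
  tg <- mat[, target_cols, drop = FALSE]
  bg <- mat[, background_cols, drop = FALSE]
  if (direction == "U") {
    tq <- row_quantile(tg, 1 - tg_quant)
    bq <- row_quantile(bg, bg_quant)
    delta <- bq - tq
  } else {
    tq <- row_quantile(tg, tg_quant)
    bq <- row_quantile(bg, 1 - bg_quant)
    delta <- tq - bq
  }
  out <- blocks
  out$group <- group
  out$direction <- direction
  out$delta <- unname(delta)
  out$tg_quantile_value <- unname(tq)
  out$bg_quantile_value <- unname(bq)
  out
}

order_marker_records <- function(records, chrom_levels) {
  records$.chrom_ord <- match(records$chrom, chrom_levels)
  records <- dplyr::arrange(records, dplyr::desc(.data$delta),
                            dplyr::desc(.data$n_cpgs),
                            .data$.chrom_ord, .data$start_bp)
  records$.chrom_ord <- NULL
  records$rank <- seq_len(nrow(records))
  records
}

#' Rank one-vs-all cell-type markers
#'
#' For every group (and, when a `supergroup` column is present, every
#' supergroup: the union of its member groups' samples), contrasts the
#' group's samples against all other samples with [marker_delta()] on the
#' low-coverage-filled block means, and ranks blocks by delta (descending;
#' ties broken by `n_cpgs` descending, then genomic position).
#'
#' @param beta Long block-by-sample table (`block_id`, `sample`, `mean`,
#'   `n_obs`) as from [beta_table()].
#' @param blocks Block tibble; filtered to `min_cpgs` and
#'   `length_range_bp` before ranking.
#' @param groups Tibble `sample_id`, `group`, optional `supergroup`.
#' @param direction `"U"` (target unmethylated) or `"M"`.
#' @param top_n Markers kept per group (default 25); `Inf` keeps all.
#' @param min_cpgs Minimum CpGs per block (default 5).
#' @param length_range_bp Admissible genomic block length (default
#'   `c(10, 1500)`).
#' @param tg_quant,bg_quant Quantile parameters (defaults 0.25, 0.025).
#' @param min_obs,fill_value Low-coverage fill rule (defaults 25, 0.5); see
#'   [fill_low_coverage()].
#' @param min_delta Optional minimal delta a marker must reach.
#' @param include_supergroups Also rank supergroups (default `TRUE` when the
#'   `groups` table defines any).
#' @return Marker tibble: block columns plus `group`, `direction`, `delta`,
#'   `tg_quantile_value`, `bg_quantile_value`, `rank`.
#' @export
rank_markers <- function(beta, blocks, groups, direction = c("U", "M"),
                         top_n = 25, min_cpgs = 5,
                         length_range_bp = c(10, 1500),
                         tg_quant = 0.25, bg_quant = 0.025,
                         min_obs = 25, fill_value = 0.5,
                         min_delta = NULL, include_supergroups = TRUE) {
  direction <- match.arg(direction)
  blocks <- dplyr::filter(
    blocks, .data$n_cpgs >= min_cpgs,
    (.data$end_bp - .data$start_bp) >= length_range_bp[1],
    (.data$end_bp - .data$start_bp) <= length_range_bp[2])
  if (nrow(blocks) == 0) abort("no blocks pass the size filters")
  filled <- fill_low_coverage(beta, min_obs = min_obs,
                              fill_value = fill_value)
  wide <- tidyr::pivot_wider(
    filled[, c("block_id", "sample", "value")],
    names_from = "sample", values_from = "value")
  wide <- wide[match(blocks$block_id, wide$block_id), , drop = FALSE]
  if (anyNA(wide$block_id)) abort("`beta` is missing some blocks")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  chrom_levels <- unique(blocks$chrom)

  sets <- split(groups$sample_id, groups$group)
  if (include_supergroups && "supergroup" %in% names(groups) &&
      any(!is.na(groups$supergroup))) {
    sg <- groups[!is.na(groups$supergroup), , drop = FALSE]
    sets <- c(sets, split(sg$sample_id, sg$supergroup))
  }
  out <- purrr::imap(sets, function(samples, g) {
    tg_cols <- match(samples, colnames(mat))
    if (anyNA(tg_cols)) abort(sprintf("samples of group %s missing from beta", g))
    bg_cols <- setdiff(seq_len(ncol(mat)), tg_cols)
    if (length(tg_cols) == 0 || length(bg_cols) == 0) {
      abort(sprintf("group %s has an empty target or background set", g))
    }
    rec <- marker_table_for_sets(mat, blocks, tg_cols, bg_cols, g,
                                 direction, tg_quant, bg_quant)
    rec <- order_marker_records(rec, chrom_levels)
    if (!is.null(min_delta)) rec <- rec[rec$delta >= min_delta, , drop = FALSE]
    head(rec, top_n)
  })
  dplyr::bind_rows(out)
}

#' Deduplicate markers selected by both a group and its supergroup
#'
#' When an atlas combines basic-group and supergroup marker runs, a block
#' selected by both is kept once, attributed to the more specific (basic)
#' group; among equally specific claims the larger delta wins.
#'
#' @param records Marker tibble from [rank_markers()].
#' @param groups Group table (used to tell basic groups from supergroups).
#' @return Deduplicated marker tibble.
#' @export
dedup_markers <- function(records, groups) {
  basic <- unique(groups$group)
  records$.is_basic <- records$group %in% basic
  records <- dplyr::arrange(records, .data$block_id,
                            dplyr::desc(.data$.is_basic),
                            dplyr::desc(.data$delta))
  records <- dplyr::distinct(records, .data$block_id, .keep_all = TRUE)
  records$.is_basic <- NULL
  records
}

#' Two-set quantile marker selection (epithelial/endoderm style)
#'
#' Identical machinery to [rank_markers()] but for an explicit pair of
#' sample sets rather than one-vs-all groups, with symmetric quantile
#' parameters and a delta threshold. With the defaults, a block is retained
#' when the target's 90th-percentile methylation is lower than the
#' background's 10th percentile by at least 0.4.
#'
#' @param beta,blocks As in [rank_markers()].
#' @param target_samples,background_samples Character vectors of sample ids.
#' @param tg_quant,bg_quant Quantile parameters (defaults 0.1, 0.1).
#' @param min_delta Minimal delta to retain (default 0.4).
#' @param direction `"U"` or `"M"`.
#' @inheritParams rank_markers
#' @return Marker tibble (all blocks passing `min_delta`, ranked).
#' @export
two_set_markers <- function(beta, blocks, target_samples, background_samples,
                            tg_quant = 0.1, bg_quant = 0.1, min_delta = 0.4,
                            direction = c("U", "M"), min_cpgs = 5,
                            length_range_bp = c(10, 1500), min_obs = 25,
                            fill_value = 0.5) {
  direction <- match.arg(direction)
  if (length(target_samples) == 0 || length(background_samples) == 0) {
    abort("empty target or background set")
  }
  groups <- tibble(
    sample_id = c(target_samples, background_samples),
    group = rep(c("target", "background"),
                c(length(target_samples), length(background_samples))),
    supergroup = NA_character_)
  rec <- rank_markers(beta, blocks, groups, direction = direction,
                      top_n = Inf, min_cpgs = min_cpgs,
                      length_range_bp = length_range_bp,
                      tg_quant = tg_quant, bg_quant = bg_quant,
                      min_obs = min_obs, fill_value = fill_value,
                      min_delta = min_delta, include_supergroups = FALSE)
  rec[rec$group == "target", , drop = FALSE]
}
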