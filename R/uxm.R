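#' Fragment-level U/X/M classification
#'
#' Every sequenced fragment with enough CpG calls is classified by its
#' methylated-call fraction `f = #C / (#C + #T)`: U (mostly unmethylated)
#' when `f <= u_threshold`, M (mostly methylated) when `f >= m_threshold`,
#' X (mixed) otherwise. Both comparisons are inclusive, so with the default
#' 0.25/0.75 thresholds a 4-CpG fragment is U with at most one methylated
#' call and M with at least three. No-call characters never count except
#' through the eligibility requirement of `min_cpgs` observed calls.
#'
#' @param patterns Character vector of C/T/. patterns.
#' @param min_cpgs Minimum observed calls for a fragment to be classified
#'   (default 4; 3 is used for low-coverage mixture analysis).
#' @param u_threshold,m_threshold Classification thresholds (defaults
#'   0.25/0.75; 0.15/0.85 for the unmethylated-region catalogue).
#' @return Character vector over `"U"`, `"X"`, `"M"`, `"excluded"`.
#' @export
classify_fragments <- function(patterns, min_cpgs = 4,
                               u_threshold = 0.25, m_threshold = 0.75) {
  stopifnot(u_threshold >= 0, u_threshold < m_threshold, m_threshold <= 1)
  n_c <- stringr::str_count(patterns, stringr::fixed("C"))
  n_t <- stringr::str_count(patterns, stringr::fixed("T"))
  n <- n_c + n_t
  f <- ifelse(n > 0, n_c / n, NA_real_)
  out <- rep("excluded", length(patterns))
  elig <- n >= min_cpgs
  out[elig & f <= u_threshold] <- "U"
  out[elig & f >= m_threshold] <- "M"
  out[elig & f > u_threshold & f < m_threshold] <- "X"
  out
}

# Clip fragment patterns to a CpG-index window [start_cpg, end_cpg).
# Returns the clipped substring ("" when no overlap).
clip_patterns <- function(start_cpg_frag, patterns, start_cpg, end_cpg) {
  len <- nchar(patterns)
  s <- pmax(start_cpg, start_cpg_frag)
  e <- pmin(end_cpg, start_cpg_frag + len)
  out <- character(length(patterns))
  ok <- e > s
  out[ok] <- substr(patterns[ok], (s - start_cpg_frag + 1L)[ok],
                    (e - start_cpg_frag)[ok])
  out
}

#' Per-region U/X/M fragment proportions
#'
#' For each block, fragments overlapping it are clipped to the block's CpG
#' range (a fragment spanning the boundary contributes its inside part, it
#' is not discarded), classified with [classify_fragments()], and tallied
#' with their multiplicities. Proportions are over classified (non-excluded)
#' fragments; a block with no eligible fragment gets zero counts and `NA`
#' proportions.
#'
#' @param fragments Fragment tibble (one sample or pooled), sorted.
#' @param blocks Block tibble.
#' @inheritParams classify_fragments
#' @return Tibble: `block_id`, `n_U`, `n_X`, `n_M`, `total`, `u`, `x`, `m`.
#' @export
region_uxm <- function(fragments, blocks, min_cpgs = 4,
                       u_threshold = 0.25, m_threshold = 0.75) {
  res <- matrix(0L, nrow = nrow(blocks), ncol = 3,
                dimnames = list(NULL, c("U", "X", "M")))
  for (cm in unique(blocks$chrom)) {
    bsel <- which(blocks$chrom == cm)
    fr <- fragments[fragments$chrom == cm, , drop = FALSE]
    if (nrow(fr) == 0) next
    fr <- fr[order(fr$start_cpg), , drop = FALSE]
    starts <- fr$start_cpg
    maxlen <- max(nchar(fr$pattern))
    for (bi in bsel) {
      b0 <- blocks$start_cpg[bi]; b1 <- blocks$end_cpg[bi]
      hi <- findInterval(b1 - 1L, starts)        # starts < b1
      if (hi == 0) next
      lo <- findInterval(b0 - maxlen, starts) + 1L
      if (lo > hi) next
      sl <- lo:hi
      clipped <- clip_patterns(starts[sl], fr$pattern[sl], b0, b1)
      cls <- classify_fragments(clipped, min_cpgs, u_threshold, m_threshold)
      for (lab in c("U", "X", "M")) {
        res[bi, lab] <- res[bi, lab] + sum(fr$count[sl][cls == lab])
      }
    }
  }
  total <- rowSums(res)
  tibble(block_id = blocks$block_id,
         n_U = res[, "U"], n_X = res[, "X"], n_M = res[, "M"],
         total = total,
         u = ifelse(total > 0, res[, "U"] / total, NA_real_),
         x = ifelse(total > 0, res[, "X"] / total, NA_real_),
         m = ifelse(total > 0, res[, "M"] / total, NA_real_))
}

#' Genome-wide unmethylated-region catalogue for one cell type
#'
#' Classifies the pooled fragments of one cell type over blocks of at least
#' `block_min_cpgs` CpGs with strict thresholds (by default a fragment is U
#' at <= 15% methylated calls, M at >= 85%), and retains the blocks in which
#' at least `u_fraction_min` of classified fragments are unmethylated.
#' Blocks with no eligible fragment are excluded.
#'
#' @param fragments Pooled fragment tibble (all replicates of the cell
#'   type; see [pool_fragments()]).
#' @param blocks Block tibble.
#' @param u_fraction_min Minimum U-fragment fraction to retain (default
#'   0.85).
#' @param block_min_cpgs Minimum CpGs per block (default 4).
#' @param min_cpgs Minimum observed calls per fragment (default 4).
#' @param u_threshold,m_threshold Fragment thresholds (defaults 0.15/0.85).
#' @return The retained blocks joined with their U/X/M statistics.
#' @export
unmethylated_catalogue <- function(fragments, blocks, u_fraction_min = 0.85,
                                   block_min_cpgs = 4, min_cpgs = 4,
                                   u_threshold = 0.15, m_threshold = 0.85) {
  blocks <- filter_blocks(blocks, block_min_cpgs)
  stats <- region_uxm(fragments, blocks, min_cpgs = min_cpgs,
                      u_threshold = u_threshold, m_threshold = m_threshold)
  keep <- stats$total > 0 & stats$u >= u_fraction_min
  dplyr::bind_cols(blocks[keep, , drop = FALSE],
                   stats[keep, setdiff(names(stats), "block_id"),
                         drop = FALSE])
}
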