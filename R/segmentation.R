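#' Genome segmentation into homogeneous methylation blocks
#'
#' The generative model treats each block as inducing, per sample, a
#' Bernoulli distribution over methylation calls: every sequenced CpG
#' observation in block i and sample k is an i.i.d. draw from
#' Bernoulli(theta_i^k). The score of a block is its log-likelihood under the
#' plug-in Bayes estimate of theta (with pseudocounts), summed over samples,
#' and dynamic programming finds the segmentation of each chromosome's CpGs
#' that maximizes the total score subject to a maximal genomic block span.
#'
#' @name segmentation
NULL

#' Bayes estimator of a block's methylation level
#'
#' `(n_meth + alpha_c) / (n_meth + n_unmeth + alpha_c + alpha_t)`; the
#' pseudocounts regularize the estimate strictly inside (0, 1) and control
#' the trade-off between overfitting (short blocks) and generalization
#' (long blocks).
#'
#' @param n_meth,n_unmeth Non-negative observation counts (vectorized).
#' @param alpha_c,alpha_t Positive pseudocounts (default 1, Laplace
#'   smoothing).
#' @return Estimate(s) in (0, 1).
#' @export
estimate_theta <- function(n_meth, n_unmeth, alpha_c = 1, alpha_t = 1) {
  if (alpha_c <= 0 || alpha_t <= 0) abort("pseudocounts must be positive")
  stopifnot(all(n_meth >= 0), all(n_unmeth >= 0))
  (n_meth + alpha_c) / (n_meth + n_unmeth + alpha_c + alpha_t)
}

#' Log-likelihood score of one block
#'
#' `sum_k [ n_meth^k log(theta_k) + n_unmeth^k log(1 - theta_k) ]` with
#' `theta_k` from [estimate_theta()]. Always <= 0; equals 0 iff all samples
#' have zero observations.
#'
#' @param n_meth,n_unmeth Per-sample observation counts (equal-length
#'   vectors).
#' @param alpha_c,alpha_t Positive pseudocounts.
#' @return Scalar log-likelihood (natural log).
#' @export
block_log_likelihood <- function(n_meth, n_unmeth, alpha_c = 1, alpha_t = 1) {
  th <- estimate_theta(n_meth, n_unmeth, alpha_c, alpha_t)
  sum(n_meth * log(th) + n_unmeth * log1p(-th))
}

# DP over one chromosome. meth/unmeth: K x n matrices; pos: 0-based CpG
# positions. Returns list(score, starts) where starts are the 1-based site
# indices opening each block.
dp_segment_chrom <- function(meth, unmeth, pos, max_block_bp,
                             alpha_c, alpha_t, tie_tolerance) {
  n <- length(pos)
  csC <- row_cumsum0(meth)
  csT <- row_cumsum0(unmeth)
  tt <- numeric(n + 1)
  back <- integer(n)
  lo_ptr <- 1L
  for (i in seq_len(n)) {
    # smallest admissible block start j: span pos[i] - pos[j] + 1 <= cap;
    # a single-CpG block (j = i, span 1) is always admissible
    while (pos[i] - pos[lo_ptr] + 1 > max_block_bp) lo_ptr <- lo_ptr + 1L
    cand <- (lo_ptr - 1L):(i - 1L)              # candidate i' values
    nc <- csC[, i + 1] - csC[, cand + 1, drop = FALSE]
    nt <- csT[, i + 1] - csT[, cand + 1, drop = FALSE]
    th <- (nc + alpha_c) / (nc + nt + alpha_c + alpha_t)
    ll <- colSums(nc * log(th) + nt * log1p(-th))
    tot <- tt[cand + 1] + ll
    best <- max(tot)
    # tie rule: smallest i' (longest last block) within tolerance
    pick <- cand[which(tot >= best - tie_tolerance)[1]]
    tt[i + 1] <- best
    back[i] <- pick
  }
  starts <- integer(0)
  i <- n
  while (i > 0L) {
    starts <- c(back[i] + 1L, starts)
    i <- back[i]
  }
  list(score = tt[n + 1], starts = starts)
}

#' Segment CpG sites into methylation blocks
#'
#' Multichannel dynamic programming over the CpG sites covered by `counts`:
#' each chromosome is segmented separately into contiguous, exhaustive,
#' non-overlapping blocks maximizing the summed [block_log_likelihood()],
#' subject to a maximal genomic span per block. Linear distance between
#' consecutive CpGs is otherwise ignored by the model.
#'
#' @param counts A [site_counts()] object (samples x CpG sites).
#' @param index The [cpg_index_from_positions()] the counts are anchored to.
#' @param max_block_bp Maximal genomic span of one block, measured from the
#'   first CpG's position to the last CpG's position + 1 (default 5000).
#'   A single-CpG block is always admissible.
#' @param alpha_c,alpha_t Positive pseudocounts (default 1).
#' @param tie_tolerance Score tolerance within which candidate extensions
#'   are considered tied; ties prefer the longest last block, which
#'   canonically minimizes the number of blocks on degenerate (e.g. all-zero)
#'   input.
#' @return An object of class `methylation_segmentation`: a list with
#'   `blocks` (block tibble with per-block `score`), `total_score`, and
#'   `params`. `tidy()` returns the blocks, `glance()` the fit summary.
#' @export
segment_blocks <- function(counts, index, max_block_bp = 5000,
                           alpha_c = 1, alpha_t = 1,
                           tie_tolerance = 1e-9) {
  stopifnot(inherits(counts, "site_counts"), inherits(index, "cpg_index"))
  if (alpha_c <= 0 || alpha_t <= 0) abort("pseudocounts must be positive")
  if (max_block_bp < 1) abort("`max_block_bp` must be >= 1")
  nsite <- ncol(counts$meth)
  if (nsite < 1) abort("at least one CpG site is required")
  if (counts$start_cpg < 1 || counts$start_cpg + nsite - 1 > index$n) {
    abort("`counts` CpG range exceeds the CpG index")
  }
  coords <- cpg_index_to_coord(index,
                               seq(counts$start_cpg, length.out = nsite))
  total <- 0
  out_blocks <- list()
  for (cm in unique(coords$chrom)) {
    sel <- which(coords$chrom == cm)
    res <- dp_segment_chrom(
      counts$meth[, sel, drop = FALSE], counts$unmeth[, sel, drop = FALSE],
      coords$pos[sel], max_block_bp, alpha_c, alpha_t, tie_tolerance)
    total <- total + res$score
    gstart <- counts$start_cpg + sel[1] - 1L
    bstart <- gstart + res$starts - 1L
    bend <- c(bstart[-1], gstart + length(sel))
    b <- blocks_from_cpg_ranges(index, bstart, bend)
    out_blocks[[cm]] <- b
  }
  blocks <- dplyr::bind_rows(out_blocks)
  bm <- block_means(counts, blocks)
  score <- vapply(split(bm, factor(bm$block_id, levels = blocks$block_id)),
                  function(d) block_log_likelihood(d$n_meth, d$n_unmeth,
                                                   alpha_c, alpha_t),
                  numeric(1))
  blocks$score <- unname(score)
  structure(
    list(blocks = blocks, total_score = total,
         params = list(max_block_bp = max_block_bp, alpha_c = alpha_c,
                       alpha_t = alpha_t, tie_tolerance = tie_tolerance)),
    class = "methylation_segmentation")
}

#' @export
print.methylation_segmentation <- function(x, ...) {
  cat(sprintf("<methylation_segmentation> %d blocks, total score %.4f\n",
              nrow(x$blocks), x$total_score))
  invisible(x)
}

#' Exhaustive segmentation oracle
#'
#' Enumerates every segmentation obeying the span cap (exponential in the
#' number of CpGs; refused above `max_n`) and returns the best total score
#' with one optimal segmentation. Intended as an independent check of
#' [segment_blocks()] on tiny instances.
#'
#' @inheritParams segment_blocks
#' @param max_n Refuse inputs with more CpGs than this (default 20).
#' @return List with `score` and `blocks` (block tibble).
#' @export
brute_force_segment <- function(counts, index, max_block_bp = 5000,
                                alpha_c = 1, alpha_t = 1, max_n = 20) {
  stopifnot(inherits(counts, "site_counts"))
  nsite <- ncol(counts$meth)
  if (nsite > max_n) abort(sprintf("too many CpGs for enumeration (%d)", nsite))
  coords <- cpg_index_to_coord(index,
                               seq(counts$start_cpg, length.out = nsite))
  total <- 0
  out_blocks <- list()
  for (cm in unique(coords$chrom)) {
    sel <- which(coords$chrom == cm)
    meth <- counts$meth[, sel, drop = FALSE]
    unmeth <- counts$unmeth[, sel, drop = FALSE]
    pos <- coords$pos[sel]
    n <- length(sel)
    block_score <- function(a, b) {   # sites a..b inclusive
      if (b > a && pos[b] - pos[a] + 1 > max_block_bp) return(-Inf)
      nc <- rowSums(meth[, a:b, drop = FALSE])
      nt <- rowSums(unmeth[, a:b, drop = FALSE])
      block_log_likelihood(nc, nt, alpha_c, alpha_t)
    }
    best <- -Inf; best_cuts <- NULL
    n_cuts <- n - 1L
    for (mask in 0:(2^n_cuts - 1)) {
      cuts <- if (n_cuts > 0) which(bitwAnd(mask, 2^(0:(n_cuts - 1))) > 0) else integer(0)
      bounds <- c(0L, cuts, n)
      sc <- 0
      for (j in seq_len(length(bounds) - 1L)) {
        sc <- sc + block_score(bounds[j] + 1L, bounds[j + 1L])
        if (sc == -Inf) break
      }
      if (sc > best) {
        best <- sc
        best_cuts <- bounds
      }
    }
    total <- total + best
    gstart <- counts$start_cpg + sel[1] - 1L
    bstart <- gstart + best_cuts[-length(best_cuts)]
    bend <- gstart + best_cuts[-1]
    out_blocks[[cm]] <- blocks_from_cpg_ranges(index, bstart, bend)
  }
  list(score = total, blocks = dplyr::bind_rows(out_blocks))
}
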