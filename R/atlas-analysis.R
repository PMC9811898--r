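#' Sample-level comparative analyses of a methylation atlas
#'
#' Utilities for comparing whole methylomes at block resolution:
#' interindividual dissimilarity, selection of the most variable blocks,
#' nearest-neighbour imputation plus L1 agglomerative clustering with tree
#' export, and association of markers with nearby overexpressed genes.
#'
#' @name atlas_analysis
NULL

#' Interindividual methylation dissimilarity
#'
#' The fraction of eligible blocks in which two samples' average methylation
#' differs by at least `delta`. A block is eligible when it has at least
#' `min_cpgs` CpGs and at least `min_obs` observations (sequenced CpG calls)
#' in both samples.
#'
#' @param beta Long block-by-sample table from [beta_table()].
#' @param blocks Block tibble (for `n_cpgs`).
#' @param sample_a,sample_b Sample ids.
#' @param min_cpgs,min_obs Eligibility thresholds (defaults 3 and 10).
#' @param delta Methylation difference counted as discordant (default 0.5).
#' @return One-row tibble: `sample_a`, `sample_b`, `dissimilarity`,
#'   `n_eligible`.
#' @export
pairwise_dissimilarity <- function(beta, blocks, sample_a, sample_b,
                                   min_cpgs = 3, min_obs = 10, delta = 0.5) {
  ok_blocks <- blocks$block_id[blocks$n_cpgs >= min_cpgs]
  a <- beta[beta$sample == sample_a & beta$block_id %in% ok_blocks, ]
  b <- beta[beta$sample == sample_b & beta$block_id %in% ok_blocks, ]
  m <- match(a$block_id, b$block_id)
  elig <- !is.na(m) & a$n_obs >= min_obs & b$n_obs[m] >= min_obs &
    !is.na(a$mean) & !is.na(b$mean[m])
  n_eligible <- sum(elig)
  if (n_eligible == 0) abort("no eligible blocks shared by the two samples")
  diff <- abs(a$mean[elig] - b$mean[m][elig])
  tibble(sample_a = sample_a, sample_b = sample_b,
         dissimilarity = mean(diff >= delta), n_eligible = n_eligible)
}

#' All-pairs dissimilarity table
#'
#' @inheritParams pairwise_dissimilarity
#' @param samples Optional subset of sample ids (default: all in `beta`).
#' @return Tibble of unordered pairs with their dissimilarities.
#' @export
dissimilarity_table <- function(beta, blocks, samples = NULL,
                                min_cpgs = 3, min_obs = 10, delta = 0.5) {
  samples <- samples %||% unique(beta$sample)
  pairs <- utils::combn(samples, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    pairwise_dissimilarity(beta, blocks, pairs[1, i], pairs[2, i],
                           min_cpgs = min_cpgs, min_obs = min_obs,
                           delta = delta)
  })
}

#' Select the most variable blocks
#'
#' Restricts to blocks with at least `min_cpgs` CpGs that have at least
#' `min_obs` observations in at least `coverage_sample_frac` of the samples,
#' then keeps the top `top_frac` by across-sample variance of block means
#' (low-coverage entries are excluded from the variance as missing).
#' Deterministic: ties are broken by input block order.
#'
#' @param beta Long block-by-sample table.
#' @param blocks Block tibble.
#' @param top_frac Fraction of eligible blocks to keep (default 0.01).
#' @param min_cpgs Minimum CpGs per block (default 4).
#' @param min_obs Minimum observations per entry (default 10).
#' @param coverage_sample_frac Required fraction of well-covered samples
#'   (default 2/3).
#' @return The selected blocks (tibble) with an added `variance` column.
#' @export
select_variable_blocks <- function(beta, blocks, top_frac = 0.01,
                                   min_cpgs = 4, min_obs = 10,
                                   coverage_sample_frac = 2 / 3) {
  blocks <- filter_blocks(blocks, min_cpgs)
  beta <- beta[beta$block_id %in% blocks$block_id, ]
  beta$value <- ifelse(beta$n_obs >= min_obs, beta$mean, NA_real_)
  n_samples <- length(unique(beta$sample))
  stats_tb <- dplyr::summarise(
    dplyr::group_by(beta, .data$block_id),
    n_covered = sum(!is.na(.data$value)),
    variance = if (sum(!is.na(.data$value)) >= 2)
      stats::var(.data$value, na.rm = TRUE) else NA_real_,
    .groups = "drop")
  stats_tb <- stats_tb[match(blocks$block_id, stats_tb$block_id), ]
  eligible <- !is.na(stats_tb$n_covered) &
    stats_tb$n_covered >= coverage_sample_frac * n_samples &
    !is.na(stats_tb$variance)
  n_keep <- floor(top_frac * sum(eligible))
  idx <- which(eligible)
  ord <- idx[order(-stats_tb$variance[idx], idx)]
  sel <- sort(utils::head(ord, n_keep))
  out <- blocks[sel, , drop = FALSE]
  out$variance <- stats_tb$variance[sel]
  out
}

#' K-nearest-neighbour imputation of a block-by-sample matrix
#'
#' Missing entries are replaced by the average of the `k` nearest samples
#' (L1 distance over mutually observed blocks) that observe the entry.
#' Blocks missing in every sample are dropped with a warning.
#'
#' @param mat Numeric matrix, blocks x samples, with `NA` for missing.
#' @param k Neighbour count (default 5).
#' @return Imputed matrix (possibly fewer rows).
#' @export
impute_knn <- function(mat, k = 5) {
  all_missing <- rowSums(!is.na(mat)) == 0
  if (any(all_missing)) {
    warn(sprintf("dropping %d all-missing block(s)", sum(all_missing)))
    mat <- mat[!all_missing, , drop = FALSE]
  }
  ns <- ncol(mat)
  d <- matrix(Inf, ns, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      shared <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (any(shared)) d[i, j] <- mean(abs(mat[shared, i] - mat[shared, j]))
    }
  }
  out <- mat
  for (j in seq_len(ns)) {
    mi <- which(is.na(mat[, j]))
    if (length(mi) == 0) next
    ord <- order(d[j, ])
    for (b in mi) {
      donors <- ord[!is.na(mat[b, ord]) & ord != j]
      donors <- utils::head(donors, k)
      out[b, j] <- mean(mat[b, donors])
    }
  }
  out
}

#' Impute and cluster samples by block methylation
#'
#' Marks low-coverage entries missing, imputes them with [impute_knn()],
#' and clusters the samples by agglomerative hierarchical clustering on the
#' L1 (manhattan) distance between their block-mean profiles.
#'
#' @param beta Long block-by-sample table.
#' @param blocks Block tibble (typically from [select_variable_blocks()]).
#' @param min_obs Entries with fewer observations are treated as missing
#'   (default 10).
#' @param k Imputation neighbour count (default 5).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `methylome_clustering`: list with `hclust`,
#'   `tree` (an [ape::as.phylo()] object), and `matrix` (the imputed
#'   blocks x samples matrix).
#' @export
cluster_samples <- function(beta, blocks, min_obs = 10, k = 5,
                            linkage = "average") {
  beta <- beta[beta$block_id %in% blocks$block_id, ]
  beta$value <- ifelse(beta$n_obs >= min_obs, beta$mean, NA_real_)
  wide <- tidyr::pivot_wider(beta[, c("block_id", "sample", "value")],
                             names_from = "sample", values_from = "value")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$block_id
  mat <- impute_knn(mat, k = k)
  hc <- stats::hclust(stats::dist(t(mat), method = "manhattan"),
                      method = linkage)
  structure(list(hclust = hc, tree = ape::as.phylo(hc), matrix = mat),
            class = "methylome_clustering")
}

#' @export
print.methylome_clustering <- function(x, ...) {
  cat(sprintf("<methylome_clustering> %d samples over %d blocks\n",
              ncol(x$matrix), nrow(x$matrix)))
  invisible(x)
}

#' Export a clustering tree in newick format
#'
#' @param clustering A [cluster_samples()] result (or an `ape` phylo).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(clustering, path) {
  tree <- if (inherits(clustering, "methylome_clustering")) clustering$tree
          else clustering
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Marker-gene association tiers
#'
#' Associates each marker with neighbouring genes and grades the association
#' by distance, absolute expression and relative overexpression of the gene
#' in the marker's matching condition. Expression is standardized twice:
#' per gene across conditions (z-scores), then per condition across genes
#' (column-wise standardization), highlighting the most overexpressed genes
#' of each condition; the tier rules use this final z-score.
#'
#' Tier rules (best, i.e. lowest-numbered, tier whose conditions all hold):
#' tier 1 distance <= 5 kb, expression >= 10 TPM, z >= 1.5; tier 2 as tier 1
#' with distance <= 50 kb; tier 3 distance <= 750 kb, expression >= 25 TPM,
#' z >= 5; tier 4 as tier 3 with z >= 3.5.
#'
#' @param markers Marker tibble (needs `block_id`, `chrom`, `start_bp`,
#'   `end_bp`, `group`).
#' @param expression Tibble with a `gene` column and one numeric column per
#'   condition (TPM semantics, non-negative).
#' @param tss Tibble `gene`, `chrom`, `tss` (0-based TSS coordinate).
#' @param condition_map Named character vector mapping marker `group` to an
#'   expression condition (column name).
#' @param max_distance_bp Candidate-gene gathering radius (default 750 kb,
#'   the largest tier distance).
#' @return Tibble: `block_id`, `group`, `gene`, `condition`, `distance_bp`,
#'   `expression`, `z`, `tier` (integer or `NA` when unclassified).
#' @export
marker_gene_tiers <- function(markers, expression, tss, condition_map,
                              max_distance_bp = 750000) {
  conds <- unname(condition_map[markers$group])
  if (anyNA(conds)) {
    abort(sprintf("no condition mapped for group %s",
                  markers$group[is.na(conds)][1]))
  }
  if (!all(conds %in% names(expression))) {
    abort(sprintf("condition absent from expression matrix: %s",
                  setdiff(conds, names(expression))[1]))
  }
  mat <- as.matrix(expression[, setdiff(names(expression), "gene"),
                              drop = FALSE])
  rownames(mat) <- expression$gene
  if (any(mat < 0)) abort("expression values must be non-negative")
  z1 <- t(scale(t(mat)))       # per gene across conditions
  z2 <- scale(z1)              # per condition across genes
  out <- purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    cand <- tss[tss$chrom == markers$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    dist <- pmax(0L,
                 pmax(markers$start_bp[i] - cand$tss,
                      cand$tss - (markers$end_bp[i] - 1L)))
    keep <- dist <= max_distance_bp & cand$gene %in% rownames(mat)
    if (!any(keep)) return(NULL)
    cond <- conds[i]
    g <- cand$gene[keep]
    tibble(block_id = markers$block_id[i], group = markers$group[i],
           gene = g, condition = cond, distance_bp = dist[keep],
           expression = unname(mat[g, cond]), z = unname(z2[g, cond]))
  })
  if (nrow(out) == 0) return(out)
  out$tier <- assign_tier(out$distance_bp, out$expression, out$z)
  out
}

assign_tier <- function(distance_bp, expression, z) {
  tier <- rep(NA_integer_, length(distance_bp))
  tier[distance_bp <= 750000 & expression >= 25 & z >= 3.5] <- 4L
  tier[distance_bp <= 750000 & expression >= 25 & z >= 5] <- 3L
  tier[distance_bp <= 50000 & expression >= 10 & z >= 1.5] <- 2L
  tier[distance_bp <= 5000 & expression >= 10 & z >= 1.5] <- 1L
  tier
}
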