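#' Reference atlas of U-fragment proportions
#'
#' The atlas is a markers x cell-types matrix `A` in which cell `A[i, j]`
#' holds the proportion of U (mostly unmethylated) fragments of marker i in
#' the pooled replicates of cell type j. It is the design matrix of the
#' fragment-level deconvolution fit.
#'
#' @name reference_atlas
NULL

#' Build a reference atlas
#'
#' Pools each group's replicate fragment files, computes per-marker U/X/M
#' proportions ([region_uxm()]), and assembles the U proportions into the
#' atlas matrix. A marker with zero eligible fragments in some group gets a
#' flagged imputed entry: the marker's own-group prior (1 for direction U,
#' 0 for direction M) when the uncovered group is the marker's source group,
#' otherwise the column mean of the observed entries. Markers uncovered in
#' more than `max_missing_frac` of groups are excluded.
#'
#' @param markers Marker tibble (blocks with a `group` and, optionally,
#'   `direction` column), e.g. from [rank_markers()].
#' @param group_fragments Named list (one element per cell type) of fragment
#'   tibbles, or of lists of fragment tibbles (replicates, pooled here).
#' @param min_cpgs,u_threshold,m_threshold Fragment classification
#'   parameters (defaults 4, 0.25, 0.75).
#' @param max_missing_frac Maximum tolerated fraction of uncovered groups
#'   per marker (default 0.2).
#' @param index Optional CpG index used to sanity-check pooled fragments.
#' @return An object of class `reference_atlas`: list with `A` (matrix),
#'   `markers` (tibble), `missing` (logical matrix of imputed cells),
#'   `params`.
#' @export
build_atlas <- function(markers, group_fragments, min_cpgs = 4,
                        u_threshold = 0.25, m_threshold = 0.75,
                        max_missing_frac = 0.2, index = NULL) {
  stopifnot(length(group_fragments) > 0, !is.null(names(group_fragments)))
  if (!"direction" %in% names(markers)) markers$direction <- "U"
  if (!is.null(index) &&
      any(markers$end_cpg - 1L > index$n | markers$start_cpg < 1L)) {
    abort("marker outside the CpG index")
  }
  pooled <- lapply(group_fragments, function(x) {
    if (is.data.frame(x)) x else pool_fragments(x, index = index)
  })
  cols <- lapply(pooled, function(fr) {
    region_uxm(fr, markers, min_cpgs = min_cpgs,
               u_threshold = u_threshold, m_threshold = m_threshold)$u
  })
  A <- do.call(cbind, cols)
  rownames(A) <- markers$block_id
  missing <- is.na(A)
  keep <- rowMeans(missing) <= max_missing_frac
  A <- A[keep, , drop = FALSE]
  missing <- missing[keep, , drop = FALSE]
  markers <- markers[keep, , drop = FALSE]
  for (j in seq_len(ncol(A))) {
    mi <- which(missing[, j])
    if (length(mi) == 0) next
    colmean <- mean(A[!missing[, j], j])
    if (is.nan(colmean)) colmean <- 0.5
    own <- markers$group[mi] == colnames(A)[j]
    prior <- ifelse(markers$direction[mi] == "U", 1, 0)
    A[mi, j] <- ifelse(own, prior, colmean)
  }
  structure(
    list(A = A, markers = markers, missing = missing,
         params = list(min_cpgs = min_cpgs, u_threshold = u_threshold,
                       m_threshold = m_threshold)),
    class = "reference_atlas")
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf("<reference_atlas> %d markers x %d cell types (%d imputed cells)\n",
              nrow(x$A), ncol(x$A), sum(x$missing)))
  invisible(x)
}

#' U-fragment profile of an input sample
#'
#' Counts U fragments (`n_U`) and total classified fragments (`n_total`) of
#' the input at each atlas marker; the derived proportion `u` forms the
#' response vector of the deconvolution fit.
#'
#' @param fragments Fragment tibble of the input (e.g. cfDNA) sample.
#' @param atlas A [build_atlas()] object, or a marker/block tibble.
#' @param min_cpgs Minimum observed calls per fragment; defaults to the
#'   atlas's own setting.
#' @param u_threshold,m_threshold Classification thresholds; default to the
#'   atlas's.
#' @return Tibble: `block_id`, `n_U`, `n_total`, `u`.
#' @export
uxm_profile <- function(fragments, atlas, min_cpgs = NULL,
                        u_threshold = NULL, m_threshold = NULL) {
  if (inherits(atlas, "reference_atlas")) {
    blocks <- atlas$markers
    p <- atlas$params
  } else {
    blocks <- atlas
    p <- list(min_cpgs = 4, u_threshold = 0.25, m_threshold = 0.75)
  }
  stats <- region_uxm(fragments, blocks,
                      min_cpgs = min_cpgs %||% p$min_cpgs,
                      u_threshold = u_threshold %||% p$u_threshold,
                      m_threshold = m_threshold %||% p$m_threshold)
  tibble(block_id = stats$block_id, n_U = stats$n_U,
         n_total = stats$total, u = stats$u)
}

#' Deconvolve a mixed methylome against a reference atlas
#'
#' Solves the non-negative least-squares problem `min |A x - b|_2, x >= 0`
#' and normalizes the coefficients to fractions summing to one. Unweighted:
#' `b` holds the input's U proportions at the atlas markers. Weighted: `b`
#' holds U counts and each atlas row is multiplied by the marker's total
#' fragment coverage `C_i`, i.e. `min |diag(C) A x - b|_2`, so well-covered
#' markers dominate. Markers without coverage in the input are dropped from
#' the fit (equivalent to weight 0).
#'
#' @param atlas A [build_atlas()] object.
#' @param profile A [uxm_profile()] tibble aligned by `block_id`.
#' @param weighted Use the coverage-weighted formulation (default `FALSE`).
#' @return An object of class `composition`: list with `composition`
#'   (tibble `cell_type`, `coefficient`, `fraction`), `residual` (norm),
#'   `n_markers_used`, `dropped` (uncovered marker ids), `degenerate`
#'   (`TRUE` when the fit is all-zero and fractions are undefined),
#'   `weighted`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
deconvolve <- function(atlas, profile, weighted = FALSE) {
  stopifnot(inherits(atlas, "reference_atlas"))
  m <- match(rownames(atlas$A), profile$block_id)
  n_U <- profile$n_U[m]
  n_total <- profile$n_total[m]
  n_U[is.na(n_U)] <- 0L
  n_total[is.na(n_total)] <- 0L
  covered <- n_total > 0
  if (!any(covered)) abort("no signal: all atlas markers uncovered in the input")
  if (sum(covered) < ncol(atlas$A)) {
    warn("fewer covered markers than cell types; composition may be unidentifiable")
  }
  if (weighted) {
    Afit <- atlas$A[covered, , drop = FALSE] * n_total[covered]
    b <- n_U[covered]
  } else {
    Afit <- atlas$A[covered, , drop = FALSE]
    b <- n_U[covered] / n_total[covered]
  }
  fit <- pracma::lsqnonneg(Afit, b)
  x <- pmax(fit$x, 0)
  s <- sum(x)
  degenerate <- s <= 0
  structure(
    list(composition = tibble(
           cell_type = colnames(atlas$A),
           coefficient = x,
           fraction = if (degenerate) rep(NA_real_, length(x)) else x / s),
         residual = sqrt(sum((Afit %*% x - b)^2)),
         n_markers_used = sum(covered),
         dropped = rownames(atlas$A)[!covered],
         degenerate = degenerate,
         weighted = weighted),
    class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> %d cell types, %d markers used, residual %.4g%s\n",
              nrow(x$composition), x$n_markers_used, x$residual,
              if (x$degenerate) " [degenerate: all-zero fit]" else ""))
  top <- dplyr::arrange(x$composition, dplyr::desc(.data$fraction))
  print(utils::head(top, 5))
  invisible(x)
}

#' Self-deconvolution of pure reference samples
#'
#' Deconvolves each pure replicate against the atlas and reports the
#' fraction assigned to its own (expected) cell type — the standard purity
#' check of a reference atlas.
#'
#' @param atlas A [build_atlas()] object.
#' @param samples Named list of fragment tibbles (pure replicates).
#' @param groups Tibble `sample_id`, `group` giving each replicate's
#'   expected cell type.
#' @param weighted Passed to [deconvolve()].
#' @param min_cpgs Optional override of the atlas fragment filter.
#' @return Tibble: `sample_id`, `expected_type`, `expected_fraction`,
#'   `top_type`, `top_fraction`.
#' @export
self_deconvolution <- function(atlas, samples, groups, weighted = FALSE,
                               min_cpgs = NULL) {
  purrr::imap_dfr(samples, function(fr, nm) {
    comp <- deconvolve(atlas, uxm_profile(fr, atlas, min_cpgs = min_cpgs),
                       weighted = weighted)$composition
    expected <- groups$group[match(nm, groups$sample_id)]
    top <- comp[which.max(comp$fraction), , drop = FALSE]
    tibble(sample_id = nm, expected_type = expected,
           expected_fraction = comp$fraction[comp$cell_type == expected],
           top_type = top$cell_type, top_fraction = top$fraction)
  })
}

#' Read / write a reference atlas as TSV
#'
#' Tab-separated with header: marker metadata columns (`block_id`, `chrom`,
#' `start_bp`, `end_bp`, `start_cpg`, `end_cpg`, `n_cpgs`, `group`,
#' `direction`) followed by one column per cell type holding U proportions.
#'
#' @param atlas A `reference_atlas`.
#' @param path File path.
#' @return `read_atlas()` returns a `reference_atlas` (with an empty
#'   `missing` flag matrix); `write_atlas()` returns `path` invisibly.
#' @export
write_atlas <- function(atlas, path) {
  meta_cols <- c("block_id", "chrom", "start_bp", "end_bp", "start_cpg",
                 "end_cpg", "n_cpgs", "group", "direction")
  df <- cbind(as.data.frame(atlas$markers[, meta_cols]),
              as.data.frame(atlas$A, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_cols <- c("block_id", "chrom", "start_bp", "end_bp", "start_cpg",
                 "end_cpg", "n_cpgs", "group", "direction")
  if (!all(meta_cols %in% names(df))) {
    abort("not an atlas TSV: missing marker metadata columns")
  }
  A <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(A) <- df$block_id
  structure(
    list(A = A, markers = as_tibble(df[, meta_cols]),
         missing = matrix(FALSE, nrow(A), ncol(A)),
         params = list(min_cpgs = 4, u_threshold = 0.25, m_threshold = 0.75)),
    class = "reference_atlas")
}
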