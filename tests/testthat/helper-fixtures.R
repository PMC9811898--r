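# Small fixture builders shared across test files.

# A block tibble without an underlying CpG index: blocks of `n_cpgs` CpGs,
# `len_bp` long, spaced 1 kb apart on chr1.
make_blocks <- function(n, n_cpgs = 5, len_bp = 100) {
  n_cpgs <- rep_len(n_cpgs, n)
  len_bp <- rep_len(len_bp, n)
  start_bp <- seq_len(n) * 1000L
  start_cpg <- cumsum(c(1L, n_cpgs[-n]))
  tibble::tibble(
    block_id = sprintf("chr1:%d-%d", start_bp, start_bp + len_bp),
    chrom = "chr1", start_bp = start_bp, end_bp = start_bp + len_bp,
    start_cpg = start_cpg, end_cpg = start_cpg + n_cpgs, n_cpgs = n_cpgs)
}

# Long beta table from a blocks x samples matrix of means, constant n_obs.
beta_from_matrix <- function(mat, blocks, n_obs = 100) {
  stopifnot(nrow(mat) == nrow(blocks))
  samples <- colnames(mat) %||% paste0("s", seq_len(ncol(mat)))
  tibble::tibble(
    block_id = rep(blocks$block_id, times = ncol(mat)),
    sample = rep(samples, each = nrow(mat)),
    n_meth = NA_integer_, n_unmeth = NA_integer_,
    n_obs = rep_len(n_obs, length(mat)),
    mean = as.vector(mat))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Fragments for one homogeneous region: `n` fragments of pattern `pat`.
region_frags <- function(start_cpg, pat, n = 1) {
  tibble::tibble(chrom = "chr1", start_cpg = as.integer(start_cpg),
                 pattern = pat, count = as.integer(n))
}
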