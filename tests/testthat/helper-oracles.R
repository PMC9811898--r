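# Independent oracles used to cross-check the implementation.

# Non-negative least squares by projected gradient descent: an independent
# check of the active-set solver. Converges for this convex problem with
# step 1/L, L the largest eigenvalue of A'A.
pg_nnls <- function(A, b, iters = 200000, tol = 1e-12) {
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  L <- max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) return(rep(0, ncol(A)))
  x <- rep(0, ncol(A))
  for (i in seq_len(iters)) {
    g <- AtA %*% x - Atb
    x_new <- pmax(0, x - as.vector(g) / L)
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

# Quadratic all-pairs interval overlap oracle (0-based half-open).
overlap_oracle <- function(blocks, ann) {
  vapply(seq_len(nrow(blocks)), function(i) {
    any(ann$chrom == blocks$chrom[i] &
          ann$start < blocks$end_bp[i] &
          ann$end > blocks$start_bp[i])
  }, logical(1))
}

# Random valid fragment records on a single chromosome, sorted.
random_fragments <- function(n, max_cpg = 500, max_len = 8) {
  pat <- vapply(seq_len(n), function(i) {
    len <- sample.int(max_len, 1)
    chars <- sample(c("C", "T", "."), len, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
    chars[1] <- sample(c("C", "T"), 1)
    chars[len] <- sample(c("C", "T"), 1)
    paste(chars, collapse = "")
  }, character(1))
  out <- tibble::tibble(chrom = "chr1",
                        start_cpg = sort(sample.int(max_cpg, n, replace = TRUE)),
                        pattern = pat,
                        count = sample.int(5, n, replace = TRUE))
  out
}

# Random site_counts + cpg_index instances for segmentation checks; gaps
# occasionally exceed the span cap so the cap constraint is exercised.
random_seg_instance <- function(n_max = 14, k_max = 3, depth_max = 20,
                                big_gap_prob = 0.2) {
  n <- sample(2:n_max, 1)
  k <- sample.int(k_max, 1)
  gaps <- ifelse(runif(n - 1) < big_gap_prob,
                 sample(4000:7000, n - 1, replace = TRUE),
                 sample(2:200, n - 1, replace = TRUE))
  pos <- cumsum(c(sample.int(1000, 1), gaps))
  idx <- cpg_index_from_positions(list(chr1 = pos))
  meth <- matrix(rpois(k * n, runif(1, 0.5, depth_max / 2)), nrow = k)
  unmeth <- matrix(rpois(k * n, runif(1, 0.5, depth_max / 2)), nrow = k)
  counts <- site_counts(meth, unmeth, 1L, paste0("s", seq_len(k)))
  list(counts = counts, index = idx)
}
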