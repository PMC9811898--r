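make_beta_pair <- function(a_means, b_means, n_obs = 50) {
  blocks <- make_blocks(length(a_means), n_cpgs = 4)
  beta <- tibble::tibble(
    block_id = rep(blocks$block_id, 2),
    sample = rep(c("a", "b"), each = length(a_means)),
    n_meth = NA_integer_, n_unmeth = NA_integer_,
    n_obs = rep_len(n_obs, 2 * length(a_means)),
    mean = c(a_means, b_means))
  list(beta = beta, blocks = blocks)
}

test_that("dissimilarity counts discordant eligible blocks", {
  x <- make_beta_pair(rep(0.2, 10), rep(0.2, 10))
  expect_equal(pairwise_dissimilarity(x$beta, x$blocks, "a", "b")$dissimilarity, 0)

  y <- make_beta_pair(rep(0, 10), rep(1, 10))
  expect_equal(pairwise_dissimilarity(y$beta, y$blocks, "a", "b")$dissimilarity, 1)

  a <- c(0, 0, 0, 0.1, 0.1, 0.1, 0.1, 0.2, 0.2, 0.2)
  b <- c(0.9, 0.8, 0.6, 0.2, 0.15, 0.2, 0.1, 0.25, 0.2, 0.3)
  z <- make_beta_pair(a, b)   # exactly 3 of 10 differ by >= 0.5
  r <- pairwise_dissimilarity(z$beta, z$blocks, "a", "b")
  expect_equal(r$dissimilarity, 0.3)
  expect_equal(r$n_eligible, 10L)
})

test_that("dissimilarity is symmetric, monotone in delta, and guards coverage", {
  set.seed(51)
  x <- make_beta_pair(runif(30), runif(30))
  d_ab <- pairwise_dissimilarity(x$beta, x$blocks, "a", "b")$dissimilarity
  d_ba <- pairwise_dissimilarity(x$beta, x$blocks, "b", "a")$dissimilarity
  expect_equal(d_ab, d_ba)
  deltas <- c(0.35, 0.4, 0.45, 0.5)
  vals <- vapply(deltas, function(d) {
    pairwise_dissimilarity(x$beta, x$blocks, "a", "b", delta = d)$dissimilarity
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))

  # blocks failing coverage in either sample are ineligible
  y <- make_beta_pair(rep(0, 10), rep(1, 10))
  y$beta$n_obs[y$beta$sample == "b"][1:4] <- 5L
  expect_equal(pairwise_dissimilarity(y$beta, y$blocks, "a", "b")$n_eligible, 6L)
  y$beta$n_obs <- 2L
  expect_error(pairwise_dissimilarity(y$beta, y$blocks, "a", "b"),
               "eligible")
  tbl <- dissimilarity_table(x$beta, x$blocks)
  expect_equal(nrow(tbl), 1L)
})

test_that("variable-block selection is deterministic and finds planted variance", {
  set.seed(52)
  n <- 1000
  blocks <- make_blocks(n, n_cpgs = 5)
  ns <- 12
  mat <- matrix(0.5 + rnorm(n * ns, 0, 0.01), n, ns,
                dimnames = list(NULL, paste0("s", 1:ns)))
  planted <- sample.int(n, 100)
  mat[planted, ] <- matrix(rep(c(0.05, 0.95), length.out = ns * 100),
                           100, ns, byrow = TRUE)
  beta <- beta_from_matrix(pmin(pmax(mat, 0), 1), blocks)
  sel <- select_variable_blocks(beta, blocks, top_frac = 0.01)
  expect_equal(nrow(sel), floor(0.01 * n))
  expect_true(all(sel$block_id %in% blocks$block_id[planted]))
  expect_identical(sel, select_variable_blocks(beta, blocks, top_frac = 0.01))

  # a constant table is resolved by position order
  const <- beta_from_matrix(matrix(0.5, 100, 4), make_blocks(100))
  s2 <- select_variable_blocks(const, make_blocks(100), top_frac = 0.05)
  expect_equal(s2$block_id, make_blocks(100)$block_id[1:5])

  # low-coverage blocks are not considered
  beta2 <- beta
  beta2$n_obs[beta2$block_id %in% blocks$block_id[planted]] <- 3L
  s3 <- select_variable_blocks(beta2, blocks, top_frac = 0.01)
  expect_false(any(s3$block_id %in% blocks$block_id[planted]))
})

test_that("imputation is the identity without missingness and fills by neighbours", {
  set.seed(53)
  mat <- matrix(runif(40), 10, 4)
  expect_equal(impute_knn(mat), mat)

  m2 <- cbind(c(rep(0.1, 5), NA), matrix(0.1, 6, 3),
              matrix(0.9, 6, 2))
  filled <- impute_knn(m2, k = 2)
  expect_equal(filled[6, 1], 0.1)   # nearest columns are the 0.1 ones
  m3 <- rbind(m2, NA)
  expect_warning(f3 <- impute_knn(m3, k = 2), "all-missing")
  expect_equal(nrow(f3), 6L)
})

test_that("clustering separates planted groups and exports newick", {
  set.seed(54)
  blocks <- make_blocks(60, n_cpgs = 5)
  g1 <- matrix(0.05 + rnorm(60 * 3, 0, 0.02), 60, 3)
  g2 <- matrix(0.95 + rnorm(60 * 3, 0, 0.02), 60, 3)
  mat <- pmin(pmax(cbind(g1, g2), 0), 1)
  colnames(mat) <- c(paste0("lo", 1:3), paste0("hi", 1:3))
  beta <- beta_from_matrix(mat, blocks)
  beta$n_obs[sample.int(nrow(beta), 20)] <- 2L   # some entries go missing
  cl <- cluster_samples(beta, blocks)
  split2 <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(split2[paste0("lo", 1:3)])), 1L)
  expect_equal(length(unique(split2[paste0("hi", 1:3)])), 1L)
  expect_false(split2[["lo1"]] == split2[["hi1"]])

  p <- tempfile(fileext = ".nwk")
  export_newick(cl, p)
  tree <- ape::read.tree(p)
  expect_setequal(tree$tip.label, colnames(mat))

  # permuting sample order leaves the 2-group split invariant
  perm <- sample(colnames(mat))
  beta_p <- beta
  beta_p$sample <- factor(beta_p$sample, levels = perm)
  beta_p <- dplyr::arrange(beta_p, .data$sample)
  beta_p$sample <- as.character(beta_p$sample)
  cl2 <- cluster_samples(beta_p, blocks)
  split2b <- stats::cutree(cl2$hclust, k = 2)[names(split2)]
  expect_equal(length(unique(split2b[paste0("lo", 1:3)])), 1L)
  expect_false(split2b[["lo1"]] == split2b[["hi1"]])
})

test_that("tier rules grade distance, expression and z-score", {
  # (3 kb, 50 TPM, z 2) -> tier 1; (40 kb, 12 TPM, z 1.6) -> tier 2, failing
  # only the tier-1 distance; (600 kb, 30 TPM, z 4) -> tier 4, meeting the
  # tier-3 distance/expression but not its z
  d <- c(3000, 40000, 600000, 600000, 600000)
  e <- c(50, 12, 30, 30, 12)
  z <- c(2, 1.6, 5.5, 4, 9)
  base <- fragmeth:::assign_tier(d, e, z)
  expect_equal(base, c(1L, 2L, 3L, 4L, NA))
  # relaxing any threshold input never removes a gene from a tier
  expect_true(all(is.na(base) |
                    fragmeth:::assign_tier(d, e, z + 1) <= base))
  expect_true(all(is.na(base) |
                    fragmeth:::assign_tier(d, e + 10, z) <= base))
  expect_true(all(is.na(base) |
                    fragmeth:::assign_tier(pmax(d - 2500, 0), e, z) <= base))
})

test_that("marker-gene association standardizes twice and maps conditions", {
  expr <- tibble::tibble(
    gene = paste0("g", 1:12),
    condA = c(50, rep(1, 5), rep(2, 6)),
    condB = c(1, 30, rep(1, 4), rep(2, 6)),
    condC = c(1, 1, 40, 12, 28, 30, rep(2, 6)))
  markers <- make_blocks(2, n_cpgs = 5)
  markers$group <- c("tA", "tB")
  markers$start_bp <- c(1000L, 1000L); markers$end_bp <- c(1100L, 1100L)
  tss <- tibble::tibble(gene = c("g1", "g2", "g3"), chrom = "chr1",
                        tss = c(4000L, 41000L, 900000L))
  cmap <- c(tA = "condA", tB = "condB")
  tiers <- marker_gene_tiers(markers, expr, tss, cmap)

  # distance to the TSS point from the block interval
  expect_equal(tiers$distance_bp[tiers$group == "tA" & tiers$gene == "g1"],
               4000 - (1100 - 1))
  # candidates beyond the gathering radius are absent
  expect_false("g3" %in% tiers$gene)
  # raw expression is reported in the marker's matching condition
  expect_equal(tiers$expression[tiers$group == "tB" & tiers$gene == "g2"], 30)
  # the reported tier is assign_tier() of the reported columns
  expect_equal(tiers$tier,
               fragmeth:::assign_tier(tiers$distance_bp, tiers$expression,
                                      tiers$z))
  # the condition's own overexpressed gene scores a high final z
  expect_gt(tiers$z[tiers$group == "tA" & tiers$gene == "g1"], 1.5)
  expect_error(marker_gene_tiers(markers, expr, tss, c(tA = "condX")),
               "condition|mapped")
  expect_error(marker_gene_tiers(markers, dplyr::mutate(expr, condA = -condA),
                                 tss, cmap), "non-negative")
})
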