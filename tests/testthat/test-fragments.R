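test_that("PAT parsing and invariant rejection", {
  p <- tempfile(fileext = ".pat")
  writeLines("chr1\t5\tCCT\t2", p)
  fr <- read_pat(p)
  expect_equal(fr, tibble::tibble(chrom = "chr1", start_cpg = 5L,
                                  pattern = "CCT", count = 2L))
  writeLines(c("chr1\t5\tCCT\t2", "chr1\t6\t.CT.\t1"), p)
  expect_error(read_pat(p), "line 2")
  writeLines("chr1\t5\tCXT\t1", p)
  expect_error(read_pat(p), "pattern")
  writeLines("chr1\t5\tCCT\t0", p)
  expect_error(read_pat(p), "count")
  writeLines("chr1\t5\tCCT", p)
  expect_error(read_pat(p), "4 tab-separated")
})

test_that("unsorted input is rejected unless explicitly allowed", {
  p <- tempfile(fileext = ".pat")
  writeLines(c("chr1\t9\tCT\t1", "chr1\t5\tCT\t1"), p)
  expect_error(read_pat(p), "unsorted")
  expect_equal(nrow(read_pat(p, unsorted = TRUE)), 2L)
  writeLines(c("chr1\t5\tCT\t1", "chr2\t1\tCT\t1", "chr1\t9\tCT\t1"), p)
  expect_error(read_pat(p), "unsorted")
})

test_that("fragment files round-trip, including gzip", {
  set.seed(1)
  fr <- sort_fragments(random_fragments(1000))
  for (ext in c(".pat", ".pat.gz")) {
    p <- tempfile(fileext = ext)
    write_pat(fr, p)
    expect_equal(read_pat(p), fr)
  }
})

test_that("per-site tallies follow the pattern characters", {
  fr <- tibble::tibble(chrom = "chr1", start_cpg = 5L, pattern = "CCT",
                       count = 2L)
  sc <- counts_from_fragments(fr, c(5, 8))
  expect_equal(as.vector(sc$meth), c(2L, 2L, 0L))
  expect_equal(as.vector(sc$unmeth), c(0L, 0L, 2L))

  # no-call contributes nothing
  sc2 <- counts_from_fragments(region_frags(5, "C.C"), c(5, 8))
  expect_equal(as.vector(sc2$meth), c(1L, 0L, 1L))
  expect_equal(as.vector(sc2$unmeth), c(0L, 0L, 0L))

  # empty input and range clipping
  empty <- counts_from_fragments(fr[0, ], c(5, 8))
  expect_true(all(empty$meth == 0) && all(empty$unmeth == 0))
  clipped <- counts_from_fragments(fr, c(6, 7))
  expect_equal(as.vector(clipped$meth), 2L)
})

test_that("tallies are linear in fragment multiplicity", {
  set.seed(2)
  fr <- sort_fragments(random_fragments(200))
  rng <- c(1, max(fr$start_cpg) + 10)
  once <- counts_from_fragments(fr, rng)
  split2 <- fr[rep(seq_len(nrow(fr)), fr$count), ]
  split2$count <- 1L
  twice <- counts_from_fragments(split2, rng)
  expect_equal(once$meth, twice$meth)
  expect_equal(once$unmeth, twice$unmeth)
})

test_that("pooling is a multiset union and validates the index", {
  a <- region_frags(1, "CCT", 2)
  doubled <- pool_fragments(list(a, a))
  expect_equal(doubled$count, 4L)
  expect_equal(pool_fragments(list(a[0, ], a)), a)

  # pooling then counting equals summing per-sample counts
  set.seed(3)
  s1 <- sort_fragments(random_fragments(100))
  s2 <- sort_fragments(random_fragments(100))
  rng <- c(1, 520)
  pooled <- counts_from_fragments(pool_fragments(list(s1, s2)), rng)
  sep <- counts_from_samples(list(a = s1, b = s2), rng)
  expect_equal(as.vector(pooled$meth), as.vector(colSums(sep$meth)))

  idx <- cpg_index_from_positions(list(chr1 = c(2L, 10L)))
  bad <- region_frags(1, "CCT", 1)  # 3 calls but chr1 has 2 CpGs
  expect_error(pool_fragments(list(bad), index = idx), "outside")
  expect_error(pool_fragments(list(region_frags(1, "CT", 1) |>
                                     dplyr::mutate(chrom = "chrX")),
                              index = idx), "absent")
})

test_that("block means aggregate counts and are additive", {
  sc <- site_counts(matrix(c(4L, 5L, 0L), 1), matrix(c(1L, 0L, 0L), 1),
                    1L, "s")
  b <- make_blocks(1, n_cpgs = 3)
  bm <- block_means(sc, b)
  expect_equal(bm$mean, 0.9)
  expect_equal(bm$n_obs, 10L)

  zero <- block_means(site_counts(matrix(0L, 1, 3), matrix(0L, 1, 3), 1L, "s"), b)
  expect_true(is.na(zero$mean))
  expect_equal(zero$n_obs, 0L)

  # concatenation of two sub-blocks equals pooled-count mean
  set.seed(4)
  m <- matrix(rpois(10, 4), 1); u <- matrix(rpois(10, 4), 1)
  sc2 <- site_counts(m, u, 1L, "s")
  halves <- tibble::tibble(block_id = c("a", "b"), chrom = "chr1",
                           start_bp = c(0L, 50L), end_bp = c(50L, 100L),
                           start_cpg = c(1L, 6L), end_cpg = c(6L, 11L),
                           n_cpgs = 5L)
  whole <- halves[1, ]; whole$end_cpg <- 11L; whole$n_cpgs <- 10L
  bmh <- block_means(sc2, halves)
  bmw <- block_means(sc2, whole)
  expect_equal(bmw$n_meth, sum(bmh$n_meth))
  expect_equal(bmw$mean, sum(bmh$n_meth) / sum(bmh$n_obs))
})

test_that("block files round-trip and malformed BED lines are located", {
  b <- make_blocks(5, n_cpgs = c(1, 3, 5, 2, 4))
  p <- tempfile(fileext = ".bed")
  write_blocks(b, p)
  expect_equal(read_blocks(p), b)

  writeLines(c("chr1\t10\t20\t1\t3", "chr1\t30\tx\t4\t6"), p)
  expect_error(read_blocks(p), "line 2")
  writeLines(c("chr1\t100\t200"), p)
  bed <- read_bed(p)
  expect_equal(bed$start, 100L)
  writeLines(c("chr1\t100\t200", "chr1\t5"), p)
  expect_error(read_bed(p), "line 2")
})

test_that("interval overlap flags match the half-open convention and oracle", {
  blocks <- make_blocks(2)
  blocks$start_bp <- c(100L, 100L); blocks$end_bp <- c(200L, 200L)
  ann <- tibble::tibble(chrom = "chr1", start = c(150L, 200L),
                        end = c(300L, 300L))
  expect_true(intersect_blocks(blocks[1, ], ann[1, ])$overlaps)
  expect_false(intersect_blocks(blocks[1, ], ann[2, ])$overlaps)

  set.seed(5)
  for (i in 1:20) {
    nb <- sample(1:15, 1); na <- sample(1:15, 1)
    bl <- tibble::tibble(chrom = sample(c("c1", "c2"), nb, TRUE),
                         start_bp = sample.int(500, nb))
    bl$end_bp <- bl$start_bp + sample.int(100, nb, TRUE)
    bl$block_id <- as.character(seq_len(nb))
    an <- tibble::tibble(chrom = sample(c("c1", "c2"), na, TRUE),
                         start = sample.int(500, na))
    an$end <- an$start + sample.int(100, na, TRUE)
    expect_equal(intersect_blocks(bl, an)$overlaps, overlap_oracle(bl, an))
  }
})

test_that("near-start mode flags TSS proximity within the distance", {
  blocks <- make_blocks(1)
  blocks$start_bp <- 5000L; blocks$end_bp <- 5100L
  tss <- tibble::tibble(chrom = "chr1", start = 6050L, end = 6051L)
  expect_false(intersect_blocks(blocks, tss, mode = "overlap")$overlaps)
  expect_true(intersect_blocks(blocks, tss, mode = "near_start",
                               max_dist = 1000)$overlaps)
  expect_false(intersect_blocks(blocks, tss, mode = "near_start",
                                max_dist = 900)$overlaps)
})
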