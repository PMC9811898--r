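# A tiny two-type atlas over two marker blocks, built from explicit
# fragments: block 1 unmethylated in typeA only, block 2 in typeB only.
tiny_atlas <- function() {
  markers <- make_blocks(2, n_cpgs = 4)
  markers$group <- c("typeA", "typeB")
  markers$direction <- "U"
  frA <- dplyr::bind_rows(region_frags(1, "TTTT", 20),
                          region_frags(5, "CCCC", 20))
  frB <- dplyr::bind_rows(region_frags(1, "CCCC", 20),
                          region_frags(5, "TTTT", 20))
  build_atlas(markers, list(typeA = frA, typeB = frB))
}

test_that("atlas entries are pooled U proportions", {
  atl <- tiny_atlas()
  expect_equal(unname(atl$A), matrix(c(1, 0, 0, 1), 2))

  # pooling two replicates {U:3} and {U:1, M:4} gives 4/8
  markers <- make_blocks(1, n_cpgs = 4)
  markers$group <- "t"; markers$direction <- "U"
  r1 <- region_frags(1, "TTTT", 3)
  r2 <- dplyr::bind_rows(region_frags(1, "TTTT", 1),
                         region_frags(1, "CCCC", 4))
  atl2 <- build_atlas(markers, list(t = list(r1, r2)))
  expect_equal(unname(atl2$A[1, 1]), 0.5)
})

test_that("uncovered atlas cells get flagged direction-aware priors", {
  markers <- make_blocks(2, n_cpgs = 4)
  markers$group <- c("tA", "tB"); markers$direction <- "U"
  frA <- dplyr::bind_rows(region_frags(1, "TTTT", 10),
                          region_frags(5, "CCCC", 10))
  frB <- region_frags(1, "CCCC", 10)   # no coverage at marker 2
  atl <- build_atlas(markers, list(tA = frA, tB = frB),
                     max_missing_frac = 0.5)
  expect_true(atl$missing[2, "tB"])
  expect_equal(unname(atl$A[2, "tB"]), 1)   # own marker, direction U
  expect_equal(unname(atl$A[2, "tA"]), 0)   # observed

  # markers uncovered in too many groups are excluded
  frB0 <- region_frags(9, "CCCC", 10)  # covers neither marker
  atl2 <- build_atlas(markers[1, ], list(tA = frA, tB = frB0),
                      max_missing_frac = 0.2)
  expect_equal(nrow(atl2$A), 0L)
})

test_that("profiles feed closed-form least-squares solutions", {
  atl <- tiny_atlas()
  # identity atlas: b = (0.3, 0.1) normalizes to (0.75, 0.25)
  prof <- tibble::tibble(block_id = rownames(atl$A),
                         n_U = c(30L, 10L), n_total = c(100L, 100L),
                         u = c(0.3, 0.1))
  comp <- deconvolve(atl, prof)
  expect_equal(comp$composition$fraction, c(0.75, 0.25))
  # b equal to one column: indicator composition
  prof2 <- tibble::tibble(block_id = rownames(atl$A),
                          n_U = c(100L, 0L), n_total = c(100L, 100L),
                          u = c(1, 0))
  expect_equal(deconvolve(atl, prof2)$composition$fraction, c(1, 0))
})

test_that("the active-set optimum clips negative unconstrained solutions", {
  atl <- tiny_atlas()
  atl$A <- matrix(c(1, 0, 1, 1), 2,
                  dimnames = list(rownames(atl$A), colnames(atl$A)))
  prof <- tibble::tibble(block_id = rownames(atl$A),
                         n_U = c(0L, 100L), n_total = c(100L, 100L))
  comp <- deconvolve(atl, prof)
  expect_equal(comp$composition$coefficient, c(0, 0.5), tolerance = 1e-9)
  expect_equal(comp$composition$fraction, c(0, 1))
  # unconstrained solution would be (-1, 1): NNLS must differ
  expect_false(isTRUE(all.equal(comp$composition$coefficient, c(-1, 1))))
})

test_that("solver matches the projected-gradient oracle on random atlases", {
  set.seed(41)
  atl <- tiny_atlas()
  for (i in 1:25) {
    A <- matrix(runif(9), 3, 3,
                dimnames = list(paste0("m", 1:3), paste0("t", 1:3)))
    b <- runif(3)
    atl3 <- atl
    atl3$A <- A
    atl3$markers <- make_blocks(3, n_cpgs = 4)
    atl3$markers$group <- colnames(A); atl3$markers$direction <- "U"
    atl3$markers$block_id <- rownames(A)
    prof <- tibble::tibble(block_id = rownames(A),
                           n_U = round(b * 1000), n_total = 1000L)
    comp <- deconvolve(atl3, prof)
    oracle <- pg_nnls(A, round(b * 1000) / 1000)
    expect_equal(comp$composition$coefficient, as.vector(oracle),
                 tolerance = 1e-6)
  }
})

test_that("weighted and unweighted fits agree at equal coverage", {
  set.seed(42)
  atl <- tiny_atlas()
  prof <- tibble::tibble(block_id = rownames(atl$A),
                         n_U = c(37L, 12L), n_total = c(200L, 200L))
  un <- deconvolve(atl, prof)$composition$fraction
  we <- deconvolve(atl, prof, weighted = TRUE)$composition$fraction
  expect_equal(un, we, tolerance = 1e-9)
})

test_that("weighted fits downweight poorly covered markers", {
  # two markers for typeB disagree: u = 1 at coverage 1 vs u = 0 at
  # coverage 1000; the unweighted fit averages them, the weighted fit
  # follows the well-covered marker
  atl <- tiny_atlas()
  atl$markers <- make_blocks(3, n_cpgs = 4)
  atl$markers$group <- c("typeA", "typeB", "typeB")
  atl$markers$direction <- "U"
  atl$A <- matrix(c(1, 0, 0, 0, 1, 1), 3,
                  dimnames = list(atl$markers$block_id, c("typeA", "typeB")))
  atl$missing <- matrix(FALSE, 3, 2)
  prof <- tibble::tibble(block_id = rownames(atl$A),
                         n_U = c(100L, 1L, 0L),
                         n_total = c(1000L, 1L, 1000L))
  un <- deconvolve(atl, prof)$composition$coefficient
  we <- deconvolve(atl, prof, weighted = TRUE)$composition$coefficient
  expect_equal(un[2], 0.5, tolerance = 1e-9)
  expect_lt(we[2], 0.01)
})

test_that("compositions are non-negative and unit-sum or flagged", {
  atl <- tiny_atlas()
  prof <- tibble::tibble(block_id = rownames(atl$A),
                         n_U = c(0L, 0L), n_total = c(100L, 100L))
  comp <- deconvolve(atl, prof)
  expect_true(comp$degenerate)
  expect_true(all(is.na(comp$composition$fraction)))
  expect_true(all(comp$composition$coefficient >= 0))

  # uncovered markers are dropped; all-uncovered errors out
  prof$n_total <- c(100L, 0L)
  prof$n_U <- c(50L, 0L)
  comp2 <- suppressWarnings(deconvolve(atl, prof))
  expect_equal(comp2$dropped, rownames(atl$A)[2])
  prof$n_total <- c(0L, 0L)
  expect_error(deconvolve(atl, prof), "no signal")
})

test_that("atlas TSV round-trips", {
  atl <- tiny_atlas()
  p <- tempfile(fileext = ".tsv")
  write_atlas(atl, p)
  back <- read_atlas(p)
  expect_equal(back$A, atl$A)
  expect_equal(back$markers$block_id, atl$markers$block_id)
})

test_that("pure noise-free samples self-deconvolve to their own type", {
  atl <- tiny_atlas()
  samples <- list(
    pureA = dplyr::bind_rows(region_frags(1, "TTTT", 50),
                             region_frags(5, "CCCC", 50)),
    pureB = dplyr::bind_rows(region_frags(1, "CCCC", 50),
                             region_frags(5, "TTTT", 50)))
  groups <- tibble::tibble(sample_id = c("pureA", "pureB"),
                           group = c("typeA", "typeB"))
  rep_tbl <- self_deconvolution(atl, samples, groups)
  expect_equal(rep_tbl$expected_fraction, c(1, 1))
  expect_equal(rep_tbl$top_type, c("typeA", "typeB"))
})

test_that("composition tidiers report the fit", {
  atl <- tiny_atlas()
  prof <- tibble::tibble(block_id = rownames(atl$A),
                         n_U = c(30L, 10L), n_total = c(100L, 100L))
  comp <- deconvolve(atl, prof)
  td <- generics::tidy(comp)
  expect_named(td, c("cell_type", "coefficient", "fraction"))
  g <- generics::glance(comp)
  expect_equal(g$n_markers_used, 2L)
  expect_false(g$degenerate)
})
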