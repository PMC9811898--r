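#' Methylation blocks
#'
#' A block is a contiguous CpG-index interval with its genomic footprint:
#' 0-based half-open genomic interval `[start_bp, end_bp)` and 1-based
#' half-open CpG interval `[start_cpg, end_cpg)`. Blocks are plain tibbles
#' with columns `block_id`, `chrom`, `start_bp`, `end_bp`, `start_cpg`,
#' `end_cpg`, `n_cpgs`.
#'
#' @name blocks
NULL

#' Construct blocks from CpG-index ranges
#'
#' Computes the genomic footprint of half-open CpG ranges: `start_bp` is the
#' position of the first CpG and `end_bp` is the position of the last CpG
#' plus 2 (covering its G), so the interval contains exactly the CpGs of
#' `[start_cpg, end_cpg)`.
#'
#' @param index A [cpg_index_from_positions()] object.
#' @param start_cpg,end_cpg Integer vectors of half-open global CpG ranges.
#'   Each range must lie within one chromosome.
#' @return A block tibble.
#' @export
blocks_from_cpg_ranges <- function(index, start_cpg, end_cpg) {
  start_cpg <- as.integer(start_cpg); end_cpg <- as.integer(end_cpg)
  stopifnot(length(start_cpg) == length(end_cpg), all(end_cpg > start_cpg))
  first <- cpg_index_to_coord(index, start_cpg)
  last <- cpg_index_to_coord(index, end_cpg - 1L)
  if (any(first$chrom != last$chrom)) {
    abort("a block may not span chromosomes")
  }
  tibble(
    block_id = sprintf("%s:%d-%d", first$chrom, first$pos, last$pos + 2L),
    chrom = first$chrom,
    start_bp = first$pos,
    end_bp = last$pos + 2L,
    start_cpg = start_cpg,
    end_cpg = end_cpg,
    n_cpgs = end_cpg - start_cpg
  )
}

#' Read / write block files
#'
#' Blocks are stored as BED5-like tab-separated text without header:
#' chrom, start_bp, end_bp, start_cpg, end_cpg (genomic interval 0-based
#' half-open; CpG interval 1-based half-open).
#'
#' @param path File path (`.gz` allowed).
#' @return `read_blocks()` returns a block tibble; `write_blocks()` returns
#'   `path` invisibly.
#' @export
read_blocks <- function(path) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(blocks_empty())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5)) {
    stop_bad_line(path, which(nf < 5)[1], "expected >= 5 tab-separated fields")
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:5)), ncol = 5, byrow = TRUE)
  num <- suppressWarnings(matrix(as.integer(m[, 2:5]), ncol = 4))
  if (anyNA(num)) {
    stop_bad_line(path, which(rowSums(is.na(num)) > 0)[1],
                  "non-integer coordinate field")
  }
  out <- tibble(
    block_id = sprintf("%s:%d-%d", m[, 1], num[, 1], num[, 2]),
    chrom = m[, 1], start_bp = num[, 1], end_bp = num[, 2],
    start_cpg = num[, 3], end_cpg = num[, 4],
    n_cpgs = num[, 4] - num[, 3])
  bad <- which(out$end_bp <= out$start_bp | out$n_cpgs < 1)
  if (length(bad) > 0) {
    stop_bad_line(path, bad[1], "degenerate block interval")
  }
  out
}

blocks_empty <- function() {
  tibble(block_id = character(), chrom = character(),
         start_bp = integer(), end_bp = integer(),
         start_cpg = integer(), end_cpg = integer(), n_cpgs = integer())
}

#' @param blocks Block tibble.
#' @rdname read_blocks
#' @export
write_blocks <- function(blocks, path) {
  con <- open_text(path, "wt")
  on.exit(close(con))
  writeLines(paste(blocks$chrom, blocks$start_bp, blocks$end_bp,
                   blocks$start_cpg, blocks$end_cpg, sep = "\t"), con)
  invisible(path)
}

#' Keep blocks with a minimum number of CpGs
#'
#' @param blocks Block tibble.
#' @param min_cpgs Minimum `n_cpgs` to retain; order is preserved.
#' @return Filtered block tibble.
#' @export
filter_blocks <- function(blocks, min_cpgs) {
  dplyr::filter(blocks, .data$n_cpgs >= min_cpgs)
}

#' Block-by-sample methylation means
#'
#' For every block and sample, sums the methylated and unmethylated
#' observations over the block's CpG sites and returns the mean methylation
#' `n_meth / (n_meth + n_unmeth)` together with the number of observations
#' (`n_obs`, sequenced CpG calls). Blocks with zero observations get `NA`.
#'
#' @param counts A [site_counts()] object.
#' @param blocks Block tibble; every block must lie within the counts' CpG
#'   range.
#' @return A tibble (one row per block x sample): `block_id`, `sample`,
#'   `n_meth`, `n_unmeth`, `n_obs`, `mean`.
#' @export
block_means <- function(counts, blocks) {
  stopifnot(inherits(counts, "site_counts"))
  s0 <- counts$start_cpg
  nsite <- ncol(counts$meth)
  if (any(blocks$start_cpg < s0) || any(blocks$end_cpg > s0 + nsite)) {
    abort("block outside the CpG range of `counts`")
  }
  csC <- row_cumsum0(counts$meth)
  csT <- row_cumsum0(counts$unmeth)
  lo <- blocks$start_cpg - s0 + 1L
  hi <- blocks$end_cpg - s0 + 1L
  nm <- csC[, hi, drop = FALSE] - csC[, lo, drop = FALSE]
  nu <- csT[, hi, drop = FALSE] - csT[, lo, drop = FALSE]
  k <- nrow(nm)
  out <- tibble(
    block_id = rep(blocks$block_id, each = k),
    sample = rep(counts$samples, times = nrow(blocks)),
    n_meth = as.vector(nm), n_unmeth = as.vector(nu))
  out$n_obs <- out$n_meth + out$n_unmeth
  out$mean <- ifelse(out$n_obs > 0, out$n_meth / out$n_obs, NA_real_)
  out
}

#' Block-by-sample beta table from fragment files
#'
#' Convenience pipeline: tallies per-site counts for each sample over the
#' CpG range spanned by `blocks`, then computes [block_means()].
#'
#' @param samples Named list of fragment tibbles.
#' @param blocks Block tibble.
#' @return Long tibble: `block_id`, `sample`, `n_meth`, `n_unmeth`, `n_obs`,
#'   `mean`.
#' @export
beta_table <- function(samples, blocks) {
  rng <- c(min(blocks$start_cpg), max(blocks$end_cpg))
  block_means(counts_from_samples(samples, rng), blocks)
}

#' Read a BED interval file
#'
#' Minimal BED3+ reader: chrom, 0-based start, end; extra columns ignored;
#' optional `name` from column 4. Malformed lines raise an error with the
#' line number.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop_bad_line(path, which(nf < 3)[1], "expected >= 3 tab-separated fields")
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0) stop_bad_line(path, bad[1], "malformed interval")
  tibble(chrom = vapply(parts, `[`, "", 1), start = start, end = end,
         name = ifelse(nf >= 4, vapply(parts, function(p) p[4] %||% NA_character_, ""),
                       NA_character_))
}

#' Flag blocks overlapping annotation intervals
#'
#' In `"overlap"` mode a block is flagged when it shares at least 1 bp with
#' some annotation interval (both 0-based half-open). In `"near_start"` mode
#' a block is flagged when it lies within `max_dist` bp of an annotation
#' interval's start coordinate (e.g. TSS proximity).
#'
#' @param blocks Block tibble.
#' @param annotations Tibble with `chrom`, `start`, `end` (see [read_bed()]).
#' @param mode `"overlap"` or `"near_start"`.
#' @param max_dist Distance in bp for `"near_start"` mode (default 1000).
#' @return `blocks` with an added logical column `overlaps`.
#' @export
intersect_blocks <- function(blocks, annotations,
                             mode = c("overlap", "near_start"),
                             max_dist = 1000L) {
  mode <- match.arg(mode)
  ann <- annotations
  if (mode == "near_start") {
    ann <- tibble(chrom = ann$chrom,
                  start = as.integer(ann$start - max_dist),
                  end = as.integer(ann$start + max_dist + 1L))
  }
  flags <- logical(nrow(blocks))
  for (cm in unique(blocks$chrom)) {
    bi <- which(blocks$chrom == cm)
    a <- ann[ann$chrom == cm, , drop = FALSE]
    if (nrow(a) == 0) next
    o <- order(a$start)
    astart <- a$start[o]
    pmax_end <- cummax(a$end[o])
    # an overlap with [s, e) exists iff some annotation has start < e and
    # (prefix-max) end > s among those annotations
    k <- findInterval(blocks$end_bp[bi] - 1L, astart)
    flags[bi] <- k > 0 & ifelse(k > 0, pmax_end[pmax(k, 1)], 0L) > blocks$start_bp[bi]
  }
  blocks$overlaps <- flags
  blocks
}

#' Read a sample-to-group assignment table
#'
#' Tab-separated with header; columns `sample_id`, `group` and optionally
#' `supergroup` (a label shared by related groups). Every sample must have
#' exactly one group.
#'
#' @param path File path.
#' @return Tibble with `sample_id`, `group` and (possibly `NA`) `supergroup`.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    abort("group file must have columns `sample_id` and `group`")
  }
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample_id in group file")
  }
  if (!"supergroup" %in% names(df)) df$supergroup <- NA_character_
  as_tibble(df[, c("sample_id", "group", "supergroup")])
}
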