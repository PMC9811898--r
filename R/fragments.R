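#' Fragment-level methylation records (PAT format)
#'
#' Each record is one sequenced molecule: the chromosome, the 1-based global
#' CpG index of its first covered CpG, a pattern string over `C` (methylated
#' call), `T` (unmethylated call) and `.` (no call), and a positive
#' multiplicity (`count`) of molecules sharing that exact pattern. The first
#' and last pattern characters must be calls (no-call padding is trimmed),
#' and files are sorted by chromosome then `start_cpg`.
#'
#' @name fragments
#' @aliases FragmentRecord
NULL

validate_fragments <- function(fragments, check_sorted = TRUE) {
  need <- c("chrom", "start_cpg", "pattern", "count")
  if (!all(need %in% names(fragments))) {
    abort(sprintf("fragment table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  bad <- which(!grepl("^[CT]([CT.]*[CT])?$", fragments$pattern))
  if (length(bad) > 0) {
    abort(sprintf(
      "record %d: invalid pattern '%s' (allowed: C/T/., call at both ends)",
      bad[1], fragments$pattern[bad[1]]))
  }
  if (!is_count_vector(fragments$count) || any(fragments$count < 1)) {
    abort("`count` must be a positive integer for every record")
  }
  if (!is_count_vector(fragments$start_cpg) || any(fragments$start_cpg < 1)) {
    abort("`start_cpg` must be a positive integer for every record")
  }
  if (check_sorted) {
    r <- rle(fragments$chrom)
    if (anyDuplicated(r$values)) {
      abort("fragments unsorted: chromosome appears in multiple runs")
    }
    for (cm in r$values) {
      s <- fragments$start_cpg[fragments$chrom == cm]
      if (is.unsorted(s)) {
        abort(sprintf("fragments unsorted within chromosome %s", cm))
      }
    }
  }
  invisible(fragments)
}

#' Read a fragment (PAT) file
#'
#' Tab-separated text with four columns (chrom, start_cpg, pattern, count),
#' optionally gzip-compressed (`.gz`). Invariant violations are rejected with
#' the offending line number.
#'
#' @param path File path.
#' @param unsorted If `TRUE`, skip the sortedness check (records are returned
#'   as stored). By default unsorted input is an error.
#' @return A tibble with columns `chrom` (character), `start_cpg` (integer),
#'   `pattern` (character), `count` (integer).
#' @export
read_pat <- function(path, unsorted = FALSE) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start_cpg = integer(),
                  pattern = character(), count = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4)) {
    stop_bad_line(path, which(nf != 4)[1], "expected 4 tab-separated fields")
  }
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  start_cpg <- suppressWarnings(as.integer(m[, 2]))
  count <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(start_cpg) || any(start_cpg < 1)) {
    stop_bad_line(path, which(is.na(start_cpg) | start_cpg < 1)[1],
                  "start_cpg must be a positive integer")
  }
  if (anyNA(count) || any(count < 1)) {
    stop_bad_line(path, which(is.na(count) | count < 1)[1],
                  "count must be a positive integer")
  }
  ok <- grepl("^[CT]([CT.]*[CT])?$", m[, 3])
  if (!all(ok)) {
    stop_bad_line(path, which(!ok)[1], sprintf(
      "invalid pattern '%s' (C/T/. only, call at both ends)", m[!ok, 3][1]))
  }
  out <- tibble(chrom = m[, 1], start_cpg = start_cpg,
                pattern = m[, 3], count = count)
  validate_fragments(out, check_sorted = !unsorted)
  out
}

#' Write a fragment (PAT) file
#'
#' @param fragments Fragment tibble (see [read_pat()]).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_pat <- function(fragments, path) {
  validate_fragments(fragments, check_sorted = FALSE)
  con <- open_text(path, "wt")
  on.exit(close(con))
  writeLines(paste(fragments$chrom, fragments$start_cpg, fragments$pattern,
                   fragments$count, sep = "\t"), con)
  invisible(path)
}

#' Sort a fragment table
#'
#' Orders records by chromosome (order of first appearance or an explicit
#' level vector) then start CpG, then pattern, and merges duplicate records
#' by summing counts.
#'
#' @param fragments Fragment tibble.
#' @param chrom_levels Optional chromosome order.
#' @return Sorted fragment tibble.
#' @export
sort_fragments <- function(fragments, chrom_levels = NULL) {
  if (nrow(fragments) == 0) {
    return(tibble(chrom = character(), start_cpg = integer(),
                  pattern = character(), count = integer()))
  }
  key <- paste(fragments$chrom, fragments$start_cpg, fragments$pattern,
               sep = "\r")
  # rowsum with reorder = FALSE aggregates in order of first appearance,
  # aligning with !duplicated(key)
  agg <- rowsum(fragments$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- tibble(chrom = fragments$chrom[first],
                start_cpg = fragments$start_cpg[first],
                pattern = fragments$pattern[first],
                count = as.integer(agg[, 1]))
  lv <- chrom_levels %||% unique(out$chrom)
  out[order(match(out$chrom, lv), out$start_cpg, out$pattern), ]
}

#' Pool fragments from several samples
#'
#' Multiset union preserving multiplicities (counts of identical records are
#' summed), returned sorted. Used to merge all replicates of one cell type
#' before fragment-level classification.
#'
#' @param fragment_list List of fragment tibbles.
#' @param index Optional [cpg_index_from_positions()] object; when given,
#'   every record is checked to lie within its chromosome's CpG range, so
#'   that files from different genomes cannot be pooled silently.
#' @return A sorted fragment tibble.
#' @export
pool_fragments <- function(fragment_list, index = NULL) {
  stopifnot(is.list(fragment_list))
  fragment_list <- fragment_list[vapply(fragment_list, nrow, 1L) > 0]
  if (length(fragment_list) == 0) {
    return(tibble(chrom = character(), start_cpg = integer(),
                  pattern = character(), count = integer()))
  }
  all <- dplyr::bind_rows(fragment_list)
  if (!is.null(index)) {
    for (cm in unique(all$chrom)) {
      if (!cm %in% index$chroms) {
        abort(sprintf("fragments on chromosome %s absent from the CpG index", cm))
      }
      rng <- cpg_chrom_range(index, cm)
      sel <- all$chrom == cm
      ends <- all$start_cpg[sel] + nchar(all$pattern[sel])
      if (any(all$start_cpg[sel] < rng[1]) || any(ends > rng[2])) {
        abort(sprintf(
          "fragments on %s fall outside the CpG index range: mixed indices?", cm))
      }
    }
  }
  sort_fragments(all, chrom_levels = if (!is.null(index)) index$chroms)
}

#' Per-site methylation counts
#'
#' A `site_counts` object holds, for each sample and each CpG site of a
#' contiguous global CpG range, the number of methylated (`C`) and
#' unmethylated (`T`) observations. It is the input of segmentation and of
#' block-level averaging.
#'
#' @param meth,unmeth Integer matrices, samples x sites.
#' @param start_cpg 1-based global CpG index of the first column.
#' @param samples Character vector of sample ids (row names).
#' @return An object of class `site_counts`.
#' @export
site_counts <- function(meth, unmeth, start_cpg, samples) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  stopifnot(identical(dim(meth), dim(unmeth)),
            length(samples) == nrow(meth),
            all(meth >= 0), all(unmeth >= 0))
  rownames(meth) <- rownames(unmeth) <- samples
  structure(list(meth = meth, unmeth = unmeth,
                 start_cpg = as.integer(start_cpg),
                 samples = samples),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("<site_counts> %d sample(s) x %d CpG sites [%d, %d)\n",
              nrow(x$meth), ncol(x$meth), x$start_cpg,
              x$start_cpg + ncol(x$meth)))
  invisible(x)
}

#' Tally per-site counts from fragments
#'
#' Each pattern character `j` of a fragment contributes its record count to
#' site `start_cpg + j - 1`: `C` to the methylated tally, `T` to the
#' unmethylated tally, `.` to nothing. Sites outside `cpg_range` are ignored.
#'
#' @param fragments Fragment tibble (one sample).
#' @param cpg_range Half-open global CpG range `c(start, end)`.
#' @param sample_id Sample name for the resulting single row.
#' @return A one-sample [site_counts()] object.
#' @export
counts_from_fragments <- function(fragments, cpg_range,
                                  sample_id = "sample") {
  start <- as.integer(cpg_range[1]); end <- as.integer(cpg_range[2])
  stopifnot(end >= start)
  n <- end - start
  meth <- integer(n); unmeth <- integer(n)
  if (nrow(fragments) > 0 && n > 0) {
    lens <- nchar(fragments$pattern)
    sites <- rep(fragments$start_cpg, lens) + sequence(lens) - 1L
    chars <- unlist(strsplit(fragments$pattern, "", fixed = TRUE),
                    use.names = FALSE)
    wts <- rep(fragments$count, lens)
    keep <- sites >= start & sites < end & chars != "."
    sites <- sites[keep] - start + 1L
    chars <- chars[keep]
    wts <- wts[keep]
    add_to <- function(vec, sel) {
      if (any(sel)) {
        agg <- rowsum(wts[sel], group = sites[sel])
        vec[as.integer(rownames(agg))] <- vec[as.integer(rownames(agg))] +
          as.integer(agg[, 1])
      }
      vec
    }
    meth <- add_to(meth, chars == "C")
    unmeth <- add_to(unmeth, chars == "T")
  }
  site_counts(matrix(meth, nrow = 1), matrix(unmeth, nrow = 1),
              start, sample_id)
}

#' Stack per-sample counts into a multisample matrix
#'
#' @param counts_list List of [site_counts()] objects over the same CpG range.
#' @return A multisample `site_counts`.
#' @export
bind_site_counts <- function(counts_list) {
  stopifnot(length(counts_list) > 0)
  s0 <- counts_list[[1]]$start_cpg
  n0 <- ncol(counts_list[[1]]$meth)
  for (x in counts_list) {
    if (x$start_cpg != s0 || ncol(x$meth) != n0) {
      abort("all site_counts must cover the same CpG range")
    }
  }
  site_counts(do.call(rbind, lapply(counts_list, `[[`, "meth")),
              do.call(rbind, lapply(counts_list, `[[`, "unmeth")),
              s0, unlist(lapply(counts_list, `[[`, "samples")))
}

#' Tally counts for a set of samples
#'
#' @param samples Named list of fragment tibbles.
#' @param cpg_range Half-open global CpG range.
#' @return A multisample [site_counts()] object (one row per list element).
#' @export
counts_from_samples <- function(samples, cpg_range) {
  stopifnot(length(samples) > 0, !is.null(names(samples)))
  bind_site_counts(purrr::imap(samples, function(fr, nm) {
    counts_from_fragments(fr, cpg_range, sample_id = nm)
  }))
}
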