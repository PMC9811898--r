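#' Genome-wide CpG index
#'
#' A `cpg_index` is the coordinate system of the package: an ordered map
#' between genomic coordinates and a single 1-based running index over all
#' CpG (CG dinucleotide) sites of the genome. All fragment records, count
#' matrices and blocks address CpGs through this index, so per-site work is
#' independent of base-pair coordinates while every block can still be
#' reported as a genomic interval.
#'
#' Only forward-strand CG dinucleotides are indexed; reverse-strand calls are
#' assumed to have been collapsed onto the forward-strand CpG by the upstream
#' alignment pipeline. Soft-masked (lowercase) `cg` counts as a CpG; any `N`
#' interrupts a CpG.
#'
#' @param positions Named list of strictly increasing integer vectors: the
#'   0-based position of the C of each CpG, per chromosome. List order is the
#'   chromosome order of the global index.
#' @return An object of class `cpg_index`.
#' @seealso [build_cpg_index()] to scan a genome sequence.
#' @export
cpg_index_from_positions <- function(positions) {
  chroms <- names(positions)
  if (is.null(chroms) || any(chroms == "")) {
    abort("`positions` must be a fully named list (one element per chromosome)")
  }
  if (anyDuplicated(chroms)) {
    abort(sprintf("duplicate chromosome name: %s",
                  chroms[duplicated(chroms)][1]))
  }
  positions <- lapply(positions, function(p) {
    p <- as.integer(p)
    if (is.unsorted(p, strictly = TRUE)) {
      abort("CpG positions must be strictly increasing within a chromosome")
    }
    p
  })
  counts <- vapply(positions, length, integer(1))
  offsets <- c(0L, cumsum(counts))[seq_along(chroms)]
  names(offsets) <- chroms
  structure(
    list(chroms = chroms, positions = positions, offsets = offsets,
         n = sum(counts)),
    class = "cpg_index"
  )
}

#' Build a CpG index from genome sequence
#'
#' Scans forward-strand sequence for CG dinucleotides (case-insensitive) and
#' assigns a global 1-based running index following `chrom_order`.
#'
#' @param genome One of: a path to a FASTA file (read with
#'   [Biostrings::readDNAStringSet()]), a `DNAStringSet`, or a named
#'   character vector of sequences.
#' @param chrom_order Optional character vector fixing the chromosome order
#'   of the global index; defaults to the order of appearance. Every name
#'   must be present in the genome.
#' @return A [cpg_index_from_positions()] object.
#' @examples
#' idx <- build_cpg_index(c(chr1 = "ACGTCGCG"))
#' n_cpgs(idx)
#' @export
build_cpg_index <- function(genome, chrom_order = NULL) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome) && is.null(names(genome)) &&
             length(genome) == 1 && file.exists(genome)) {
    seqs <- as.character(Biostrings::readDNAStringSet(genome))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) {
      abort("`genome` must be named sequences, a DNAStringSet, or a FASTA path")
    }
    seqs <- genome
  } else {
    abort("unsupported `genome` type")
  }
  if (anyDuplicated(names(seqs))) {
    abort(sprintf("duplicate chromosome name: %s",
                  names(seqs)[duplicated(names(seqs))][1]))
  }
  if (!is.null(chrom_order)) {
    missing <- setdiff(chrom_order, names(seqs))
    if (length(missing) > 0) {
      abort(sprintf("chromosome in `chrom_order` absent from genome: %s",
                    missing[1]))
    }
    seqs <- seqs[chrom_order]
  }
  positions <- lapply(seqs, function(s) {
    hits <- gregexpr("CG", toupper(s), fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  })
  cpg_index_from_positions(positions)
}

#' Total number of CpG sites in an index
#' @param index A `cpg_index`.
#' @return Integer scalar.
#' @export
n_cpgs <- function(index) {
  stopifnot(inherits(index, "cpg_index"))
  index$n
}

#' @export
print.cpg_index <- function(x, ...) {
  cat(sprintf("<cpg_index> %d CpGs over %d chromosome(s): %s\n",
              x$n, length(x$chroms),
              paste(utils::head(x$chroms, 5), collapse = ", ")))
  invisible(x)
}

#' Convert genomic coordinates to global CpG indices
#'
#' @param index A `cpg_index`.
#' @param chrom,pos Vectors (recycled to common length) of chromosome names
#'   and 0-based positions of the C of a CpG.
#' @return Integer vector of 1-based global CpG indices; `NA` where the
#'   position is not an indexed CpG.
#' @export
cpg_coord_to_index <- function(index, chrom, pos) {
  stopifnot(inherits(index, "cpg_index"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  out <- integer(n)
  for (cm in unique(chrom)) {
    sel <- chrom == cm
    if (!cm %in% index$chroms) {
      out[sel] <- NA_integer_
      next
    }
    hit <- match(pos[sel], index$positions[[cm]])
    out[sel] <- ifelse(is.na(hit), NA_integer_, index$offsets[[cm]] + hit)
  }
  out
}

#' Convert global CpG indices to genomic coordinates
#'
#' @param index A `cpg_index`.
#' @param cpg Vector of 1-based global CpG indices in `[1, n_cpgs(index)]`.
#' @return A tibble with columns `cpg`, `chrom`, `pos` (0-based position of
#'   the C).
#' @export
cpg_index_to_coord <- function(index, cpg) {
  stopifnot(inherits(index, "cpg_index"))
  cpg <- as.integer(cpg)
  if (any(is.na(cpg)) || any(cpg < 1L) || any(cpg > index$n)) {
    abort("CpG index out of range")
  }
  bounds <- c(unname(index$offsets), index$n)
  ci <- findInterval(cpg - 1L, bounds, rightmost.closed = FALSE)
  chrom <- index$chroms[ci]
  pos <- integer(length(cpg))
  for (k in unique(ci)) {
    sel <- ci == k
    pos[sel] <- index$positions[[k]][cpg[sel] - index$offsets[[k]]]
  }
  tibble(cpg = cpg, chrom = chrom, pos = pos)
}

#' Global CpG-index range of one chromosome
#'
#' @param index A `cpg_index`.
#' @param chrom Chromosome name.
#' @return Half-open integer range `c(start_cpg, end_cpg)` of the
#'   chromosome's CpGs in the global index.
#' @export
cpg_chrom_range <- function(index, chrom) {
  stopifnot(inherits(index, "cpg_index"))
  if (!chrom %in% index$chroms) abort(sprintf("unknown chromosome: %s", chrom))
  off <- index$offsets[[chrom]]
  c(off + 1L, off + length(index$positions[[chrom]]) + 1L)
}
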