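#' Specification of a synthetic multi-cell-type methylome
#'
#' Describes the study conditions emulated by the generator: a set of cell
#' types with replicates, planted cell-type-specific marker regions
#' (unmethylated only in their own type, methylated in all others), shared
#' background regions (fully methylated, fully unmethylated or
#' intermediate), a CpG spacing model, sequencing depth, a fragment
#' CpG-count distribution, and a per-CpG flip-noise rate emulating imperfect
#' bisulfite conversion (~1%).
#'
#' Fragment methylation is region-state-driven: each fragment draws one
#' state from its region and then emits per-CpG calls Bernoulli(theta of
#' that state) flipped with probability `epsilon`, so the bimodal U/M
#' fragment structure that fragment-level deconvolution exploits is present.
#' `fragment_bimodality` optionally lets a fragment draw the region's
#' opposite state, injecting controlled cross-class contamination.
#'
#' @param n_types Number of cell types (default 10).
#' @param replicates Replicates per type (default 3).
#' @param markers_per_type Planted marker regions per type (default 25).
#' @param n_background_blocks Shared background regions (default 500).
#' @param region_cpgs_min,region_cpgs_mean Region CpG-count distribution:
#'   `min + Poisson(mean - min)` (defaults 4 and 8).
#' @param gap_within_bp,gap_between_bp Mean bp gap between CpGs within a
#'   region and between regions (defaults 30 and 600; within-region gaps are
#'   at least 2 bp).
#' @param depth Mean fragments per region per replicate (default 100).
#' @param frag_cpgs_mean Fragment CpG-call count distribution
#'   `1 + Poisson(frag_cpgs_mean - 1)` (default 6: most fragments cover >= 4
#'   CpGs, some fewer, exercising the eligibility rules).
#' @param theta_low,theta_high Per-CpG methylation probabilities of the
#'   unmethylated / methylated state (defaults 0.05, 0.95); intermediate
#'   background regions use 0.5.
#' @param epsilon Independent per-CpG flip noise (default 0.01).
#' @param fragment_bimodality Probability a fragment draws the region's
#'   minority state (default 0).
#' @param nocall_rate Per-internal-CpG no-call probability (default 0.01);
#'   pattern ends are always calls.
#' @param span_prob Probability a fragment is anchored without regard to the
#'   region end, so it may span into the next region (default 0.05).
#' @param background_state_probs Probabilities of low/intermediate/high
#'   state for background regions (default `c(0.3, 0.3, 0.4)`).
#' @param chrom Chromosome name (default "chr1").
#' @return A list of class `synthetic_atlas_spec`.
#' @export
synthetic_atlas_spec <- function(n_types = 10, replicates = 3,
                                 markers_per_type = 25,
                                 n_background_blocks = 500,
                                 region_cpgs_min = 4, region_cpgs_mean = 8,
                                 gap_within_bp = 30, gap_between_bp = 600,
                                 depth = 100, frag_cpgs_mean = 6,
                                 theta_low = 0.05, theta_high = 0.95,
                                 epsilon = 0.01, fragment_bimodality = 0,
                                 nocall_rate = 0.01, span_prob = 0.05,
                                 background_state_probs = c(0.3, 0.3, 0.4),
                                 chrom = "chr1") {
  stopifnot(n_types >= 2, replicates >= 1, depth > 0,
            theta_low >= 0, theta_low <= 1, theta_high >= 0, theta_high <= 1,
            epsilon >= 0, epsilon <= 1,
            fragment_bimodality >= 0, fragment_bimodality <= 1,
            region_cpgs_min >= 1, region_cpgs_mean >= region_cpgs_min,
            frag_cpgs_mean >= 1)
  structure(as.list(environment()), class = "synthetic_atlas_spec")
}

#' Generate a synthetic fragment-level reference
#'
#' Lays out marker and background regions along one chromosome, builds the
#' CpG index, and draws fragment files for every replicate of every cell
#' type according to the spec. All randomness flows from `seed`; the same
#' seed reproduces the data exactly.
#'
#' @param spec A [synthetic_atlas_spec()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_reference`: list with
#'   `cpg_index`, `samples` (named list of fragment tibbles), `groups`
#'   (tibble `sample_id`, `group`), `truth` (list: `blocks` -- the true
#'   region partition as a block tibble with `kind`, `marker_type`, `state`;
#'   `markers` -- tibble `block_id`, `type`; `theta` -- regions x types
#'   matrix of state methylation levels), `spec`, `seed`.
#' @export
generate_reference <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_atlas_spec"))
  if (spec$markers_per_type < 1) {
    abort("markers_per_type must be >= 1 for a marker-bearing reference")
  }
  with_seed(seed, {
    types <- sprintf("ct%02d", seq_len(spec$n_types))
    n_marker <- spec$n_types * spec$markers_per_type
    n_regions <- n_marker + spec$n_background_blocks
    kind <- sample(c(rep("marker", n_marker),
                     rep("background", spec$n_background_blocks)))
    marker_type <- rep(NA_character_, n_regions)
    marker_type[kind == "marker"] <-
      sample(rep(types, spec$markers_per_type))

    # region sizes and CpG positions
    n_cpg_region <- spec$region_cpgs_min +
      rpois(n_regions, spec$region_cpgs_mean - spec$region_cpgs_min)
    gaps <- lapply(n_cpg_region, function(n) {
      c(max(2, rpois(1, spec$gap_between_bp)),
        2 + rpois(n - 1, max(spec$gap_within_bp - 2, 0)))
    })
    pos <- cumsum(unlist(gaps)) + 100L
    index <- cpg_index_from_positions(setNames(list(as.integer(pos)),
                                               spec$chrom))
    region_end <- cumsum(n_cpg_region)
    region_start <- region_end - n_cpg_region + 1L
    blocks <- blocks_from_cpg_ranges(index, region_start, region_end + 1L)
    blocks$kind <- kind
    blocks$marker_type <- marker_type

    # per-region, per-type state methylation level
    state <- rep(NA_character_, n_regions)
    bg_states <- sample(c("low", "mid", "high"),
                        sum(kind == "background"), replace = TRUE,
                        prob = spec$background_state_probs)
    state[kind == "background"] <- bg_states
    blocks$state <- state
    theta_of <- c(low = spec$theta_low, mid = 0.5, high = spec$theta_high)
    theta <- matrix(NA_real_, n_regions, spec$n_types,
                    dimnames = list(blocks$block_id, types))
    for (j in seq_along(types)) {
      th <- ifelse(kind == "marker",
                   ifelse(marker_type == types[j],
                          spec$theta_low, spec$theta_high),
                   theta_of[state])
      theta[, j] <- th
    }

    groups <- tibble(
      sample_id = as.vector(outer(seq_len(spec$replicates), types,
                                  function(r, t) sprintf("%s.r%d", t, r))),
      group = rep(types, each = spec$replicates))
    # per-CpG theta lookup per type
    cpg_region <- rep(seq_len(n_regions), n_cpg_region)
    samples <- lapply(seq_len(nrow(groups)), function(si) {
      type_j <- match(groups$group[si], types)
      simulate_sample(spec, index, theta[, type_j], cpg_region,
                      region_start, n_cpg_region)
    })
    names(samples) <- groups$sample_id

    structure(
      list(cpg_index = index, samples = samples, groups = groups,
           truth = list(
             blocks = blocks,
             markers = tibble(block_id = blocks$block_id[kind == "marker"],
                              type = marker_type[kind == "marker"]),
             theta = theta),
           spec = spec, seed = seed),
      class = "synthetic_reference")
  })
}

# Draw one replicate's fragments. theta_type: per-region state theta for
# this cell type; cpg_region maps global CpG index -> region id.
simulate_sample <- function(spec, index, theta_type, cpg_region,
                            region_start, n_cpg_region) {
  n_regions <- length(region_start)
  n_frag <- rpois(n_regions, spec$depth)
  total <- sum(n_frag)
  if (total == 0) {
    return(tibble(chrom = character(), start_cpg = integer(),
                  pattern = character(), count = integer()))
  }
  region <- rep(seq_len(n_regions), n_frag)
  n_calls <- 1L + rpois(total, spec$frag_cpgs_mean - 1)
  spanning <- runif(total) < spec$span_prob
  max_off <- ifelse(spanning, n_cpg_region[region] - 1L,
                    pmax(n_cpg_region[region] - n_calls, 0L))
  off <- floor(runif(total) * (max_off + 1L))
  start <- region_start[region] + as.integer(off)
  end <- pmin(start + n_calls - 1L, index$n)
  n_calls <- end - start + 1L

  lens <- n_calls
  fid <- rep(seq_len(total), lens)
  site <- start[fid] + sequence(lens) - 1L
  th <- theta_type[cpg_region[site]]
  # fragment-level state: with prob fragment_bimodality use the region's
  # opposite state for the whole fragment
  flip_frag <- runif(total) < spec$fragment_bimodality
  th <- ifelse(flip_frag[fid], 1 - th, th)
  p_c <- th * (1 - spec$epsilon) + (1 - th) * spec$epsilon
  call <- ifelse(runif(length(site)) < p_c, "C", "T")
  # internal no-calls only (pattern ends must be calls)
  pos_in_frag <- sequence(lens)
  internal <- pos_in_frag > 1L & pos_in_frag < lens[fid]
  nocall <- internal & runif(length(site)) < spec$nocall_rate
  call[nocall] <- "."
  big <- paste(call, collapse = "")
  cs <- cumsum(lens)
  pattern <- substring(big, cs - lens + 1L, cs)
  fr <- tibble(chrom = spec$chrom, start_cpg = start,
               pattern = pattern, count = 1L)
  sort_fragments(fr, chrom_levels = spec$chrom)
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat(sprintf(
    "<synthetic_reference> %d types x %d replicates, %d regions (%d markers), %d CpGs\n",
    x$spec$n_types, x$spec$replicates, nrow(x$truth$blocks),
    nrow(x$truth$markers), x$cpg_index$n))
  invisible(x)
}

#' Mix fragments from several sources
#'
#' Draws `total_fragments` molecules, each from source `s` with probability
#' `proportions[s]`, sampling molecules uniformly with replacement within a
#' source (records are weighted by their multiplicity). The realized
#' per-source counts are recorded as the mixture truth.
#'
#' @param sources Named list of fragment tibbles.
#' @param proportions Non-negative vector summing to 1 (same length/names as
#'   `sources`).
#' @param total_fragments Number of molecules to draw.
#' @param seed Integer seed.
#' @return List of class `methylome_mixture`: `fragments` (sorted tibble)
#'   and `truth` (tibble `source`, `n`, `proportion`).
#' @export
generate_mixture <- function(sources, proportions, total_fragments,
                             seed = 1L) {
  stopifnot(length(sources) == length(proportions), all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-8) {
    abort("`proportions` must sum to 1")
  }
  empty <- vapply(sources, function(s) nrow(s) == 0 || sum(s$count) == 0,
                  logical(1))
  if (any(empty & proportions > 0)) {
    abort(sprintf("empty source with positive proportion: %s",
                  names(sources)[empty & proportions > 0][1]))
  }
  with_seed(seed, {
    n_per <- as.vector(rmultinom(1, total_fragments, proportions))
    parts <- purrr::map(seq_along(sources), function(s) {
      if (n_per[s] == 0) return(NULL)
      src <- sources[[s]]
      draws <- sample.int(nrow(src), n_per[s], replace = TRUE,
                          prob = src$count)
      times <- tabulate(draws, nbins = nrow(src))
      out <- src[times > 0, c("chrom", "start_cpg", "pattern"), drop = FALSE]
      out$count <- as.integer(times[times > 0])
      out
    })
    fragments <- sort_fragments(dplyr::bind_rows(parts))
    truth <- tibble(source = names(sources) %||% as.character(seq_along(sources)),
                    n = n_per, proportion = proportions)
    structure(list(fragments = fragments, truth = truth),
              class = "methylome_mixture")
  })
}

#' @export
print.methylome_mixture <- function(x, ...) {
  cat(sprintf("<methylome_mixture> %d fragments from %d sources\n",
              sum(x$fragments$count), nrow(x$truth)))
  invisible(x)
}
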