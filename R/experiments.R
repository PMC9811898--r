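#' In-silico deconvolution experiments
#'
#' End-to-end benchmarks of the fragment-level deconvolution pipeline on
#' synthetic data: leave-one-out spike-in series to measure the detection
#' limit of a rare cell type, and multi-way mixture recovery.
#'
#' @name experiments
NULL

#' Leave-one-out spike-in detection experiment
#'
#' Generates a synthetic reference, holds out one replicate of the target
#' cell type, re-derives the blocks and markers from the remaining samples
#' (segmentation and one-vs-all marker ranking are rerun without the
#' held-out sample), builds the reduced reference atlas, and mixes the
#' held-out sample's fragments into a leukocyte-like background pool (a
#' fixed-proportion mixture of background cell types) at each spike-in
#' concentration, `repetitions` times per concentration. Every mixture is
#' deconvolved with the fragment-level NNLS algorithm.
#'
#' @param spec A [synthetic_atlas_spec()]; needs at least 2 replicates of
#'   the target type.
#' @param target_type Target cell type (default the last type, which is
#'   never part of the default background pool).
#' @param concentrations Spike-in fractions (defaults to the series
#'   10, 3, 1, 0.3, 0.1, 0.03 and 0 percent, as fractions).
#' @param repetitions Mixtures per concentration (default 10).
#' @param seed Integer seed driving the whole experiment.
#' @param background_types Cell types forming the background pool (default:
#'   the first three non-target types).
#' @param background_props Their mixing proportions (default
#'   `c(0.6, 0.3, 0.1)`).
#' @param mixture_coverage Mean mixture fragments per region (default 800,
#'   emulating deeply sequenced plasma so that the sampling-noise floor at
#'   0% sits below the smallest nonzero concentration).
#' @param top_n Markers per cell type for the reduced atlas (default 25).
#' @param min_cpgs_deconv Minimum CpG calls per fragment in atlas and input
#'   profiles (default 3, the low-concentration setting).
#' @param marker_min_cpgs Minimum CpGs per block for marker candidacy
#'   (default 5).
#' @param marker_min_delta Minimum quantile-contrast delta a block must
#'   reach to enter the atlas (default 0.35). Without it, a cell type with
#'   fewer than `top_n` strong markers pads its set with non-specific
#'   blocks, which distort the fit at low spike-in concentrations.
#' @param segmentation_alpha Pseudocount used when re-segmenting (default 8).
#'   At WGBS-like per-site depth the plug-in likelihood gains about half a
#'   log-likelihood unit per sample for every extra block, so the
#'   pseudocounts must be large enough for a block's regularization cost to
#'   exceed that; 8 achieves this for per-site depths of 30-100 (see the
#'   methods vignette).
#' @param rerun_segmentation Re-segment with the remaining samples (default
#'   `TRUE`); otherwise the generator's true region partition is used.
#' @return Object of class `spike_experiment`: list with `estimates`
#'   (tibble `concentration`, `repetition`, `cell_type`, `fraction`),
#'   `target_type`, `markers`, `atlas`, `reference`.
#' @seealso [detection_limit()]
#' @export
loo_spike_experiment <- function(spec = synthetic_atlas_spec(),
                                 target_type = NULL,
                                 concentrations = c(0.1, 0.03, 0.01, 0.003,
                                                    0.001, 0.0003, 0),
                                 repetitions = 10, seed = 1L,
                                 background_types = NULL,
                                 background_props = c(0.6, 0.3, 0.1),
                                 mixture_coverage = 800,
                                 top_n = 25, min_cpgs_deconv = 3,
                                 marker_min_cpgs = 5, marker_min_delta = 0.35,
                                 segmentation_alpha = 8,
                                 rerun_segmentation = TRUE) {
  if (any(concentrations < 0 | concentrations > 1)) {
    abort("spike concentrations must lie in [0, 1]")
  }
  if (spec$replicates < 2) {
    abort("need >= 2 replicates of the target type (one to hold out)")
  }
  ref <- generate_reference(spec, seed = derive_seed(seed, 1))
  types <- unique(ref$groups$group)
  target_type <- target_type %||% types[length(types)]
  stopifnot(target_type %in% types)
  background_types <- background_types %||%
    utils::head(setdiff(types, target_type), length(background_props))
  stopifnot(length(background_types) == length(background_props),
            !target_type %in% background_types)

  held_id <- ref$groups$sample_id[ref$groups$group == target_type][1]
  remaining <- ref$groups[ref$groups$sample_id != held_id, , drop = FALSE]
  rem_samples <- ref$samples[remaining$sample_id]

  # re-derive blocks and markers without the held-out sample
  rng <- c(1L, ref$cpg_index$n + 1L)
  counts <- counts_from_samples(rem_samples, rng)
  blocks <- if (rerun_segmentation) {
    segment_blocks(counts, ref$cpg_index, alpha_c = segmentation_alpha,
                   alpha_t = segmentation_alpha)$blocks
  } else {
    ref$truth$blocks
  }
  beta <- block_means(counts, blocks)
  markers <- rank_markers(beta, blocks, remaining, direction = "U",
                          top_n = top_n, min_cpgs = marker_min_cpgs,
                          min_delta = marker_min_delta)
  group_frags <- lapply(split(remaining$sample_id, remaining$group),
                        function(ids) ref$samples[ids])
  atlas <- build_atlas(markers, group_frags, min_cpgs = min_cpgs_deconv,
                       index = ref$cpg_index)

  bg_pools <- lapply(background_types, function(t) {
    pool_fragments(ref$samples[ref$groups$sample_id[ref$groups$group == t]])
  })
  names(bg_pools) <- background_types
  held <- ref$samples[[held_id]]
  n_regions <- nrow(ref$truth$blocks)
  total_fragments <- round(mixture_coverage * n_regions)

  grid <- expand.grid(repetition = seq_len(repetitions),
                      concentration = concentrations)
  est <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    conc <- grid$concentration[i]
    rep_i <- grid$repetition[i]
    props <- c(conc, (1 - conc) * background_props)
    mix <- generate_mixture(c(list(target = held), bg_pools), props,
                            total_fragments,
                            seed = derive_seed(seed, 100 + i))
    prof <- uxm_profile(mix$fragments, atlas, min_cpgs = min_cpgs_deconv)
    comp <- deconvolve(atlas, prof)$composition
    tibble(concentration = conc, repetition = rep_i,
           cell_type = comp$cell_type, fraction = comp$fraction)
  })
  structure(
    list(estimates = est, target_type = target_type, markers = markers,
         atlas = atlas,
         params = list(concentrations = concentrations,
                       repetitions = repetitions,
                       background_types = background_types,
                       background_props = background_props,
                       mixture_coverage = mixture_coverage,
                       min_cpgs_deconv = min_cpgs_deconv, seed = seed)),
    class = "spike_experiment")
}

#' @export
print.spike_experiment <- function(x, ...) {
  cat(sprintf("<spike_experiment> target %s, %d concentrations x %d repetitions\n",
              x$target_type, length(x$params$concentrations),
              x$params$repetitions))
  invisible(x)
}

#' Detection limit of a spike-in series
#'
#' The smallest spike-in concentration at which the target's estimated
#' contribution exceeds the maximum of the zero-spike estimates in every
#' repetition.
#'
#' @param experiment A [loo_spike_experiment()] result (or its `estimates`
#'   tibble plus `target_type`).
#' @param target_type Target cell type (defaults to the experiment's).
#' @return List: `detection_limit` (fraction; `NA` if no concentration
#'   qualifies), `zero_max`, and the per-concentration summary tibble.
#' @export
detection_limit <- function(experiment, target_type = NULL) {
  est <- if (inherits(experiment, "spike_experiment")) experiment$estimates
         else experiment
  target_type <- target_type %||% experiment$target_type
  tgt <- est[est$cell_type == target_type, , drop = FALSE]
  tgt$fraction[is.na(tgt$fraction)] <- 0
  zero_max <- max(tgt$fraction[tgt$concentration == 0])
  summ <- dplyr::summarise(
    dplyr::group_by(tgt, .data$concentration),
    mean_estimate = mean(.data$fraction),
    min_estimate = min(.data$fraction),
    all_detected = all(.data$fraction > zero_max),
    .groups = "drop")
  cand <- summ$concentration[summ$concentration > 0 & summ$all_detected]
  list(detection_limit = if (length(cand) > 0) min(cand) else NA_real_,
       zero_max = zero_max, summary = dplyr::arrange(summ, .data$concentration))
}

#' Multi-way mixture recovery experiment
#'
#' Generates a synthetic reference, selects the top markers per type over
#' the generator's true region partition, builds the atlas, then repeatedly
#' draws mixtures of `k_components` cell types with Dirichlet-distributed
#' proportions and deconvolves them. Reports the mean absolute error between
#' the estimated and true composition over all cell types and replicates.
#'
#' @param spec A [synthetic_atlas_spec()].
#' @param n_mixtures Number of mixtures (default 20).
#' @param k_components Cell types per mixture (default 4).
#' @param mixture_coverage Mean mixture fragments per region (default 100).
#' @param dirichlet_alpha Symmetric Dirichlet concentration (default 1).
#' @param top_n Markers per type (default 25).
#' @param marker_min_delta Minimum marker delta (default 0.35).
#' @param min_cpgs Fragment CpG filter for atlas and profiles (default 4).
#' @param seed Integer seed.
#' @return List of class `mixture_recovery`: `estimates` (tibble
#'   `replicate`, `cell_type`, `true`, `estimated`), `mae` (mean absolute
#'   error, as a fraction), `atlas`.
#' @export
mixture_recovery_experiment <- function(spec = synthetic_atlas_spec(),
                                        n_mixtures = 20, k_components = 4,
                                        mixture_coverage = 100,
                                        dirichlet_alpha = 1, top_n = 25,
                                        marker_min_delta = 0.35,
                                        min_cpgs = 4, seed = 1L) {
  ref <- generate_reference(spec, seed = derive_seed(seed, 1))
  types <- unique(ref$groups$group)
  blocks <- ref$truth$blocks
  beta <- beta_table(ref$samples, blocks)
  markers <- rank_markers(beta, blocks, ref$groups, direction = "U",
                          top_n = top_n, min_delta = marker_min_delta)
  group_frags <- lapply(split(ref$groups$sample_id, ref$groups$group),
                        function(ids) ref$samples[ids])
  atlas <- build_atlas(markers, group_frags, min_cpgs = min_cpgs,
                       index = ref$cpg_index)
  pools <- lapply(group_frags, pool_fragments)
  total_fragments <- round(mixture_coverage * nrow(blocks))

  est <- with_seed(derive_seed(seed, 2), {
    purrr::map_dfr(seq_len(n_mixtures), function(r) {
      picked <- sample(types, k_components)
      w <- rgamma(k_components, shape = dirichlet_alpha)
      w <- w / sum(w)
      mix <- generate_mixture(pools[picked], w, total_fragments,
                              seed = derive_seed(seed, 200 + r))
      prof <- uxm_profile(mix$fragments, atlas, min_cpgs = min_cpgs)
      comp <- deconvolve(atlas, prof)$composition
      true <- setNames(rep(0, length(types)), types)
      true[picked] <- w
      tibble(replicate = r, cell_type = comp$cell_type,
             true = unname(true[comp$cell_type]),
             estimated = comp$fraction)
    })
  })
  structure(
    list(estimates = est,
         mae = mean(abs(est$estimated - est$true)),
         atlas = atlas,
         params = list(n_mixtures = n_mixtures, k_components = k_components,
                       mixture_coverage = mixture_coverage, seed = seed)),
    class = "mixture_recovery")
}

#' @export
print.mixture_recovery <- function(x, ...) {
  cat(sprintf("<mixture_recovery> %d mixtures, MAE %.3f%%\n",
              x$params$n_mixtures, 100 * x$mae))
  invisible(x)
}
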