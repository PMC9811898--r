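---
title: "Fragment-level methylome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-level methylome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmeth)
```

fragmeth analyses whole-genome bisulfite sequencing (WGBS) data at the level
of individual sequenced molecules. Each fragment carries the joint
methylation state of the CpG sites it covers, which a site-wise average
throws away. The package covers four connected tasks: segmenting the genome
into blocks of homogeneous methylation, selecting cell-type-specific marker
blocks, classifying fragments as mostly unmethylated (U), mixed (X) or
mostly methylated (M), and inferring the cell-type composition of a mixed
methylome — such as circulating cell-free DNA (cfDNA) — by non-negative
least squares over a U-proportion reference atlas. A synthetic-data
generator ties the pieces together so every claim in this vignette is
reproducible without controlled-access data.

## Coordinates and data structures

All per-site work uses a genome-wide 1-based CpG index (`build_cpg_index()`):
only forward-strand CG dinucleotides are indexed, on the assumption that the
upstream alignment pipeline collapsed reverse-strand calls onto the forward
CpG. Genomic intervals are 0-based half-open (BED convention); CpG-index
intervals are 1-based half-open. Fragments are PAT-style records — a start
CpG index, a pattern over `C`/`T`/`.`, and a multiplicity — with no-call
padding trimmed from pattern ends. No-call characters never count as
observations.

## The segmentation model

A block *i* induces, per sample *k*, a Bernoulli distribution with
parameter θᵢᵏ; every sequenced CpG observation in the block is an i.i.d.
draw from it. With Nᶜ methylated and Nᵀ unmethylated observations, the
plug-in estimate is regularized by pseudocounts:

θ̂ᵢᵏ = (Nᶜ + α_C) / (Nᶜ + Nᵀ + α_C + α_T)

and a block's score is the summed log-likelihood
Σₖ (Nᶜ log θ̂ᵢᵏ + Nᵀ log(1 − θ̂ᵢᵏ)). A dynamic program over table
T[i] = max over i′ of T[i′] + score(block[i′+1..i]) finds the optimal
partition of each chromosome, subject to a maximal genomic block span
(default 5,000 bp, measured first-CpG to last-CpG inclusive). Distance
between consecutive CpGs is otherwise ignored. A single-CpG block is always
admissible, so a feasible segmentation always exists. Ties (within
`tie_tolerance`, default 1e−9) prefer the longest last block, which
canonically minimizes the number of blocks on degenerate all-zero input.
`brute_force_segment()` provides an exhaustive oracle for small instances;
the test suite checks exact score agreement on hundreds of random cases.

### Choosing the pseudocounts

The pseudocounts are the only regularization in the model, and their scale
matters more than is obvious. Splitting a block adds one free parameter per
sample, and on pure noise the maximized log-likelihood gains about 0.5 per
added parameter (the usual χ²/2 argument) — about K/2 per extra block for K
samples. The pseudocount cost of a block per sample is approximately

n α² (1 − 2p)² / (2 p (1 − p) (n + 2α)²)

for per-site depth n and methylation level p, which vanishes for large n
and for p near 0.5. With α = 1 (Laplace smoothing, the package default and
a neutral choice for low-coverage data) and per-site depths of 30–100, the
optimum therefore shatters into single-CpG blocks. The in-silico
experiments (`loo_spike_experiment()`) re-segment deeply covered synthetic
references and use `segmentation_alpha = 8`, the smallest round value whose
per-block cost exceeds K/2 across depths 30–100 at the methylation levels
the generator plants (0.05/0.95 with 1% flip noise). Segmentation of
near-0.5 (intermediate) regions stays fine-grained under any α; such blocks
are simply never competitive as markers. Users segmenting their own deep
multi-sample data should scale α accordingly rather than keep the Laplace
default.

## Marker selection

Markers are discovered one-vs-all per cell-type group on a block-by-sample
table of mean methylation. Entries backed by fewer than `min_obs = 25`
observations (where the standard error of the mean is roughly 10%) are
replaced by the neutral value 0.5, shrinking their contrast and demoting
them. For unmethylated markers the ranking delta is the background's 2.5th
percentile minus the target's 75th percentile — tolerating about one target
outlier and a few background outliers — and symmetrically (25th vs 97.5th)
for methylated markers. Quantiles use linear interpolation between order
statistics (R type 7), stated explicitly so results are bit-reproducible.
Candidate blocks need ≥ 5 CpGs and a genomic length of 10–1,500 bp. Ties in
delta break by CpG count (descending) then genomic position, making marker
tables byte-identical across runs. `two_set_markers()` exposes the same
machinery for an explicit pair of sample sets with symmetric 10th/90th
percentile quantiles and a 0.4 delta floor — the configuration used for
epithelial/endoderm-wide contrasts. When basic groups and supergroups are
ranked together, `dedup_markers()` attributes a doubly selected block to
the more specific group.

## Fragment classification and the reference atlas

A fragment with c methylated and t unmethylated calls (n = c + t ≥
`min_cpgs`) is U when c/n ≤ `u_threshold`, M when c/n ≥ `m_threshold`, X
otherwise; both comparisons are inclusive, so at the default 0.25/0.75 a
4-CpG fragment is U with at most one methylated call. Fragments spanning a
region boundary are clipped, not discarded — marker regions are short and
discarding spanning molecules would waste most of the coverage; `min_cpgs`
counts the calls remaining after clipping. The stricter 0.15/0.85
thresholds with ≥ 4-CpG fragments and an 85% U-fraction floor define the
genome-wide unmethylated-region catalogue of a cell type
(`unmethylated_catalogue()`).

The reference atlas A holds, per marker × cell type, the U proportion of
the type's pooled replicates. Cells with no eligible fragment are imputed
(own-group prior at the marker's source type — 1 for U markers, 0 for M
markers — otherwise the column mean) and flagged; markers uncovered in more
than 20% of types are dropped. The original formulation leaves this case
unspecified; imputation keeps the design matrix complete for the solver
while recording unreliability.

## Deconvolution

Given an input profile b of per-marker U proportions, `deconvolve()` solves
min ‖A x − b‖₂ subject to x ≥ 0 (Lawson–Hanson active set via
`pracma::lsqnonneg`) and normalizes x to fractions. The coverage-weighted
variant sets bᵢ to the U count and scales row i of A by the marker's total
fragment count Cᵢ, i.e. min ‖diag(C) A x − b‖₂, so poorly covered markers
lose influence; both variants coincide when coverage is uniform, which the
tests assert. Markers uncovered in the input are dropped from the fit —
exactly the Cᵢ = 0 limit of the weighted form. An all-zero solution is
reported as an explicitly flagged degenerate composition rather than NaNs.
Tests check the solver against an independent projected-gradient oracle to
1e−6, including active-constraint cases where the unconstrained optimum is
negative.

## Sample-level analyses

`pairwise_dissimilarity()` quantifies interindividual variation as the
fraction of blocks (≥ 3 CpGs, ≥ 10 observations in both samples) whose mean
methylation differs by ≥ 0.5. `select_variable_blocks()` retains blocks of
≥ 4 CpGs covered by ≥ 10 observations in at least two-thirds of samples and
keeps the top 1% by across-sample variance. `cluster_samples()` marks
low-coverage entries missing, imputes them by k-nearest-neighbour averaging
over samples (L1 distance, k = 5 — both unstated in the original
description; k = 5 is the common KNN-imputer default) and clusters samples
agglomeratively on L1 distance. The linkage method is configurable and
defaults to "average"; the original description pins down only the metric
and the agglomerative scheme. Trees export to newick via ape.

`marker_gene_tiers()` grades marker–gene–condition associations: expression
is standardized per gene across conditions, then per condition across
genes, and the tier rules (1: ≤ 5 kb, ≥ 10 TPM, z ≥ 1.5; 2: as 1 but
≤ 50 kb; 3: ≤ 750 kb, ≥ 25 TPM, z ≥ 5; 4: as 3 with z ≥ 3.5) use the final,
column-standardized z — the interpretation that matches "highlighting the
most overexpressed genes per condition". Candidate genes are gathered
within 750 kb, the largest tier distance, resolving the tension with the
shorter 500 kb gathering radius mentioned elsewhere in the original text in
favour of not losing tier-3/4 candidates.

## The synthetic generator

`synthetic_atlas_spec()` describes a study: cell types with replicates,
planted marker regions (unmethylated only in their own type, methylated in
the rest), shared background regions (fully methylated, fully unmethylated
or intermediate in every type), a CpG spacing model, per-region sequencing
depth, a fragment CpG-count distribution (1 + Poisson, mean 6 — most
fragments cover ≥ 4 CpGs, some fewer, so eligibility rules are exercised),
and two noise knobs: a per-CpG flip probability ε (default 0.01, emulating
~1% bisulfite conversion error) and an optional fragment-level state-swap
probability (`fragment_bimodality`, default 0) emulating sorting impurity.
Fragment methylation is region-state-driven — a fragment draws one state
and then emits per-CpG calls — so the bimodal U/M fragment structure that
fragment-level deconvolution exploits is present by construction; per-CpG
independent mixing would destroy it. Internal no-calls occur at rate 1%;
5% of fragments are anchored so they may span a region boundary. All
randomness flows from one seed; identical seeds give byte-identical data.

What the generator does not emulate: genomic correlation in CpG density,
read-length and GC biases, copy-number variation, partially methylated
domains, or biological within-type heterogeneity beyond the two noise
knobs. Passing tests therefore demonstrate the correctness and statistical
behaviour of the algorithms under the stated model, not performance on real
tissue.

## The in-silico spike-in benchmark

`loo_spike_experiment()` reproduces the leave-one-out design at desk scale:
a reference of 10 types × 3 replicates, 25 planted markers per type, 500
background regions, and per-region coverage of about 100 fragments per
replicate. One replicate of the target type is held out; segmentation and
marker selection are rerun on the remaining 29 samples; the reduced atlas
(top 25 markers per type, delta ≥ 0.35, fragments with ≥ 3 CpG calls) is
rebuilt; and the held-out fragments are mixed into a leukocyte-like
background pool (three types at 60/30/10%) at 10, 3, 1, 0.3, 0.1, 0.03 and
0%, ten repetitions each. The detection limit is the smallest concentration
whose ten estimates all exceed the maximum of the ten zero-spike estimates.

Two sizing choices deserve explanation. First, the marker-delta floor of
0.35: when a type has fewer than 25 strong markers surviving the size
filters (a planted region can fall below 5 CpGs, or two adjacent same-type
markers merge into one over-long block), an unfiltered top-25 pads the set
with non-specific blocks whose U proportion is high in every type; a single
such block visibly distorts the fit at the 0.1% scale, occasionally zeroing
the target's coefficient outright. Second, the mixture sequencing depth
(default 800 fragments per region, the analogue of deeply sequenced
plasma): with 25 markers per type, ε = 0.01 and ≥ 3-CpG fragments, the
background generates spurious U fragments at a rate of roughly
1–3 × 10⁻⁴ per fragment, so the zero-spike estimates of an absent type sit
near zero with binomial scatter that shrinks as the square root of the
mixture depth; the depth is set so a 0.1% spike (about 20 target-derived U
fragments across the 25 markers) clears that scatter under the strict
all-exceed-the-maximum rule — the analogue of deciding how deeply one must
sequence plasma to resolve a 1-in-1000 contribution.
`mixture_recovery_experiment()` runs the complementary
four-way Dirichlet mixture benchmark at a conventional coverage of 100
fragments per region, where mean absolute composition error is the metric.

## Numerical conventions

Natural logarithms throughout; scores are only compared, never
interpreted, so the base is immaterial but fixed. Zero observations give a
block log-likelihood of exactly 0 and a missing block mean. Quantiles are R
type 7 everywhere. The DP stores the exact maximum at every prefix, so tie
tolerance affects traceback only. Compositions are normalized by the
coefficient sum; a zero sum is flagged, never divided through. Problem
sizes in the tests (random-instance counts, region counts, depths,
repetition numbers) are chosen so the full suite and the benchmark scripts
run comfortably on a single CPU; they are stated in each test and are the
package's own scaling decisions.

## Known limitations

The segmentation is exact but O(N × W × K) in time for window size W; the
pure-R implementation targets desk-scale studies (10⁴–10⁵ CpGs), not the
3 × 10⁷ CpGs of a full genome. Reverse-strand collapsing, alignment and
PAT conversion are out of scope. The marker-gene association uses a single
TSS per gene. KNN imputation recomputes sample distances on the observed
entries only, which is quadratic in samples. The generator's leukocyte
stand-in is a fixed mixture of synthetic types, not a measured leukocyte
methylome.
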