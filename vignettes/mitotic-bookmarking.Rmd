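---
title: "Methods: quantifying mitotic bookmarking with mitobook"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mitotic bookmarking with mitobook}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each module, the
parameter defaults and why they were chosen, what the synthetic-data
generator does and does not emulate, and the numerical conventions that
affect results. It is a methods reference; for runnable examples with
output see the README and `scripts/acceptance.R`.

## 1. Coordinates and data structures

All interval files follow the BED convention: 0-based, half-open. In
memory, peak sets are standard Bioconductor `GRanges` (1-based, closed)
on a `GenomeInfoDb::Seqinfo` genome; `read_narrowpeak()` and
`write_bed()` perform the conversion, and
`read_narrowpeak(write_bed(x))` is the identity. Peak summits are
stored as 0-based offsets from the interval start (narrowPeak column
10); the absolute 1-based summit is `start(gr) + summit`. When a file
carries no summit (plain BED, or narrowPeak with column 10 = −1) the
interval midpoint, rounded down, is substituted.

`merge_intervals(max_gap)` follows bedtools `merge` semantics: two
intervals separated by at most `max_gap` bp join, and book-ended
intervals join at the default `max_gap = 0`. This is implemented as
`GenomicRanges::reduce(min.gapwidth = max_gap + 1)`.

## 2. Bookmark classification

A mitotic peak is *bookmarked* when it overlaps at least one
asynchronous peak by `min_overlap` bp (default 1, the bedtools
`intersect` default); the asynchronous side is classified symmetrically.
Counts are per-condition peak counts: one broad mitotic peak spanning
two asynchronous peaks counts once on the mitotic side, while both
asynchronous peaks count as bookmarked. Classification refuses to
compare peak sets whose `Seqinfo` seqlengths differ.

Gene assignment uses the nearest transcription start site to the peak
summit, with ties broken towards the lexicographically smaller gene id
so the assignment is deterministic. A peak is a *promoter* peak when
its summit lies within `[TSS − 2000, TSS + 500]` in the gene's strand
orientation — a conventional promoter window — and peaks farther than
`max_distance = 1e5` bp from every TSS stay unassigned. The headline
gene-level statistic is the percentage of asynchronous-target genes
with at least one bookmarked asynchronous peak; genes targeted only by
mitotic-unique peaks are reported separately and excluded from the
denominator, because they are not part of the interphase target set
whose persistence is being measured.

## 3. Summit-centred signal matrices and clustering

`build_matrix()` computes a reference-point matrix: for each peak, the
signal track (bedGraph, materialised as a coverage `Rle`) is read in a
window of `flank` bp (default 2000) on each side of the summit and
averaged in consecutive `binsize`-bp bins (default 50, so 80 columns).
Positions without coverage or outside chromosome bounds contribute 0.
The ±2 kb / 50 bp defaults are the common choice for ChIP-seq profile
heatmaps; a narrower ±500 bp window suits accessibility tracks.

`kmeans_cluster()` is `stats::kmeans` with Lloyd's algorithm and
`nstart = 10` random starts, seeded reproducibly (the caller's RNG
state is saved and restored). Clusters are relabelled in order of
decreasing cluster mean so that **cluster 1 is always the strongest**;
raw k-means labels are arbitrary and this convention makes cluster
composition statements stable across runs. The between-condition
*difference score* is the sum over bins of (mean profile of set A −
mean profile of set B); it is signed (antisymmetric in A and B), and an
`absolute` option sums |differences| instead. The sign convention is
recorded as an attribute of the result.

## 4. Motif scanning with exact p-values

A `PWM` is built from base counts or probabilities with pseudocount 0.1
folded in as `(p + 0.1·bg) / (1 + 0.1)` against a background `bg`
(default uniform). Scanning scores each window by the log2 odds of the
PWM versus the background, on both strands (the reverse strand is
scanned with the reverse-complement PWM); windows containing `N` are
skipped.

P-values are exact, not sampled. Per-position scores are discretised to
a grid of `granularity` bits (default 1e-3), and the null score
distribution under the background model is computed by dynamic
programming (convolution across positions) — the same algorithm FIMO
uses. Window scores are accumulated as integers on the identical grid,
so the p-value of an observed score is an exact tail sum of the DP
distribution with no discretisation inconsistency. The score threshold
is the smallest grid score whose tail probability is ≤ `p_threshold`
(default 1e-4, FIMO's default). Granularity 1e-3 keeps the DP table
small (≈ tens of thousands of cells for a 10-bp motif) while making
discretisation error orders of magnitude smaller than any p-value of
interest; the test suite verifies the DP distribution against
exhaustive enumeration of all 4^L words for L up to 8.

Per-peak motif-count distributions of two peak classes are compared two
ways. First, *matched subsampling*: the larger class is subsampled
without replacement to the smaller class's size, `n_rep = 1000` times,
and the count histograms averaged — this removes the visual effect of
unequal sample sizes. Second, a two-sample Kolmogorov–Smirnov test on
the raw counts: D is the exact sup-difference of the two empirical
CDFs, and the p-value uses the asymptotic Kolmogorov series with
effective sample size `na·nb/(na+nb)`. The KS statistic is computed
in-package because `stats::ks.test` warns on the heavily tied integer
counts; the suite cross-checks both D and p against `ks.test` and a
brute-force oracle. With counts this discrete the KS p-value is
conservative; it is reported as computed, without correction.

## 5. Chromatin-state enrichment

`overlap_enrichment()` follows the ChromHMM OverlapEnrichment
convention. In the default `"bases"` mode, the enrichment of state *s*
is `(overlap bp in s / total peak bp) / (genome bp in s / genome bp)` —
the fold over what uniform placement would give; `"peaks"` mode counts
peaks by summit instead. Rows are ordered by the sorted state
catalogue. Enrichment vectors are min-max normalised before
between-condition comparison: values are shifted to start at 0 and
divided by the range. A `legacy_divisor` flag reproduces the
divide-by-max variant some pipelines use; the two agree when the
minimum is 0. A constant vector normalises to all zeros with a warning.
The per-state fold change between conditions is the ratio of normalised
values, reported as `NA` (never `Inf`) where the denominator is 0.

## 6. Imaging: chromatin retention

For each cell, the DNA channel is thresholded — either at a fixed value
or by Otsu's method on a 256-level histogram of intensities inside the
cell mask — to partition the cell into a chromatin ROI and a cytoplasm
ROI. Otsu's between-class variance is flat across an empty histogram
valley; the implementation takes the midpoint of the maximal plateau
rather than its left edge, the symmetric choice among equally optimal
thresholds. The retention measure per cell is mean TF-channel intensity
over chromatin divided by mean over cytoplasm, and its log2; a zero
cytoplasm mean yields `NA`, never `Inf`. `compare_groups()` runs
one-way ANOVA on per-cell log2 ratios across conditions followed by
pairwise Welch t-tests with Bonferroni correction.

## 7. The synthetic-data generator

`generate_dataset(sim_config(...))` produces every input the analyses
need — genome, two peak sets, per-peak DNA sequences, a PWM, a signal
track, a chromatin segmentation, a gene table — plus a manifest of all
planted truths. Defaults (see `?sim_config`):

| Parameter | Default | Rationale |
|---|---|---|
| `n_chroms`, `chrom_length` | 3 × 1 Mb | desk scale: seconds, not minutes |
| `n_async_peaks` | 500 | enough for stable fractions |
| `bookmark_fraction` | 0.32 | a typical bookmarked share for a mitotically retained factor |
| `n_mitotic_unique` | 13 | small mitotic-only class, as observed for bookmarking factors |
| `peak_width` | 200–600 bp | typical TF peak widths |
| `motif_lambda` | 3 vs 1.5 | bookmarked peaks carry roughly twice the motif density |
| `tier_means`, `tier_noise_sd` | 10 / 3 / 0.5, sd 0.1 | three well-separated intensity tiers |
| `tier_probs_bookmarked` | 0.70 / 0.25 / 0.05 | bookmarked sites concentrate in the strongest tier |
| `tier_probs_other` | 0.10 / 0.45 / 0.45 | the rest skew weak |
| `state_fractions` | TssA .04, Enh .10, EnhWk .12, EnhBiv .06, Tx .28, Quies .40 | plausible genome composition |
| `state_preference` | 20 / 8 / 8 / 8 / 1 / 0.05 | peaks prefer promoters and enhancers |
| `state_avoidance` | EnhWk 1.8, EnhBiv 2.2, rest 1 | bookmarking is depleted at weak and bivalent enhancers by these factors |
| `n_cells`, `cell_enrichment`, `cell_noise_sd` | 50, 2.5, 0.05 | planted log2 retention ratio of log2(2.5) ≈ 1.32 |

Construction details that matter for recoverability:

- **Slot-grid placement.** Peaks occupy a grid with pitch
  `max(peak_width) + 2400` bp, so any two summits are more than 2.25 kb
  apart. This guarantees that (a) asynchronous/mitotic overlap is
  unambiguous — a mitotic partner overlaps only its own asynchronous
  peak — and (b) each ±2 kb matrix window contains only its own peak's
  signal, so tier recovery by k-means is not confounded by neighbours.
  Slots are assigned to chromatin states in 2-kb blocks and sampled
  with probability proportional to `state_preference`.
- **Bookmark selection.** Exactly `round(bookmark_fraction ·
  n_async_peaks)` asynchronous peaks are chosen, with per-peak weight
  `1 / state_avoidance[state]`, so the normalised state enrichment of
  bookmarked peaks falls below the asynchronous enrichment by
  approximately the avoidance factors. Each bookmarked peak gets a
  mitotic partner shifted by ±width/4, keeping ≥ 75% reciprocal
  overlap.
- **Motif planting.** Each peak draws a Poisson number of consensus
  copies of the generator PWM (`sim_pwm()`, a 10-bp GATA-like motif
  with 0.94 consensus-base probability), overwritten into a random
  background sequence at non-overlapping offsets. The sequence is
  redrawn until the package's own scanner recovers exactly the planted
  count, so "planted" and "recoverable" coincide by construction.
- **Signal track.** Each peak contributes its tier mean (with Gaussian
  noise, in 50-bp chunks) over summit ± 250 bp; elsewhere the track
  is 0.
- **Seeding.** Every component draws from an independent sub-stream
  (`sub_seed(seed, k)`), and all generator entry points save and
  restore `.Random.seed`, so adding one component never shifts
  another's draws and library code cannot leak RNG state.
- **Images.** Each synthetic cell is a disk on a 64×64 grid with a
  chromatin blob; the TF channel is baseline 100 inside the cell and
  `100 × cell_enrichment` on chromatin, with multiplicative Gaussian
  noise; the DNA channel is 200 on chromatin vs 20 elsewhere, so both
  fixed (100) and Otsu thresholds separate the compartments.

### What the generator does *not* emulate

Read-level realism: there are no reads, no fragment-length effects, no
mappability or GC bias, no input/background track, and no peak-calling
noise — peak calls are taken as given, which is the level at which all
the package's analyses operate. Sequence background is i.i.d. uniform,
so motif counts in unplanted background are governed purely by the
scanner's p-value threshold. The segmentation is block-structured
rather than learned from marks. Cells are circular with a single
chromatin blob; no z-stacks, bleaching or segmentation errors. Effect
sizes are planted as constants, not drawn from biological
distributions.

### Recovery precision at desk scale

Counts planted exactly (bookmarked peaks, motif copies, tier
membership) are recovered exactly; the acceptance suite checks this.
Statistical estimands vary: with ~35–70 asynchronous peaks per enhancer
state, the estimated state fold decreases have a coefficient of
variation of roughly 15–30% around the planted 1.8/2.2, and the mean
log2 retention ratio lands within a few hundredths of log2(2.5) with 50
cells at 5% noise. `scripts/acceptance.R` reports these estimates as
computed.

## 8. Testing strategy

Every non-trivial algorithm is checked against an independent
brute-force oracle at small scale: quadratic all-pairs interval
overlap, naive window-by-window motif scanning, exhaustive 4^L
enumeration for the PWM null distribution, the ECDF sup-difference for
KS D, a contingency-table adjusted Rand index for clustering recovery,
and hypergeometric expectations for matched subsampling. End-to-end
tests run the full pipeline on generated datasets and compare against
the manifest's planted truth. The suite uses no skips and no network or
file fixtures; every input is generated from a seed.

## 9. Limitations

- The KS p-value is asymptotic and conservative on heavily tied integer
  counts; for very small peak classes a permutation test would be
  preferable.
- Gene assignment is nearest-TSS only; no 3D contact or
  enhancer–promoter mapping.
- `overlap_enrichment` treats the segmentation as exhaustive ground
  truth; unsegmented gaps are excluded from the genome denominator.
- Otsu thresholding assumes a bimodal DNA histogram inside the cell
  mask; cells without a clear chromatin compartment should use a fixed
  threshold or be excluded via the `chromatin_empty` /
  `cytoplasm_empty` flags.
- The pipeline runner validates inputs and parameter shapes but does
  not attempt peak calling, alignment or image segmentation — it starts
  from peak calls, tracks and masks.
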