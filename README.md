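# mitobook

Quantitative analysis of **mitotic bookmarking** by a transcription
factor from ChIP-seq peak calls, signal tracks, motif models, chromatin
segmentations and fluorescence images.

During mitosis most transcription factors are evicted from the condensed
chromosomes, but some remain bound at a subset of their interphase sites
— they "bookmark" those sites for rapid reactivation after division.
Given peak calls from an asynchronous (mostly interphase) population and
from a mitotic-arrested population, the core questions are:

- **Which sites are bookmarked?** A mitotic peak overlapping an
  asynchronous peak is a bookmarked site; mitotic peaks with no
  interphase counterpart are mitotic-unique.
- **What fraction of target genes retain a mark through mitosis?**
  Peaks are assigned to genes by nearest transcription start site.
- **Are bookmarked sites the strongest sites?** Summit-centred signal
  matrices are clustered by k-means and cluster membership is crossed
  with bookmarking status.
- **Do bookmarked sites have more binding-motif copies?** Peak sequences
  are scanned with a position weight matrix using exact log-odds
  p-values; per-peak count distributions are compared with matched
  subsampling and a Kolmogorov–Smirnov test.
- **Which chromatin states lose binding in mitosis?** Base-pair overlap
  enrichment per chromatin state, min-max normalised, compared between
  conditions as fold changes.
- **Is the protein retained on mitotic chromatin in single cells?**
  Chromatin/cytoplasm intensity ratios from two-channel images, with
  Otsu or fixed thresholding of the DNA channel.

Every analysis has a seeded synthetic-data generator counterpart
(`generate_dataset()`, `generate_images()`) that plants known truth —
which peaks are bookmarked, how many motif copies each sequence carries,
which signal tier each peak belongs to, the per-cell chromatin
enrichment — so the whole pipeline can be validated end to end.

## Worked example

Generate a complete synthetic study at seed 42 and run the main
analyses. All numbers below are the actual output of this code.

```r
library(mitobook)

cfg <- sim_config(seed = 42)   # defaults are the study conditions
d   <- generate_dataset(cfg)   # peaks, track, sequences, PWM, states, genes

## 1. Bookmark classification
cls <- classify_peaks(d$async, d$mitotic)
cls
#> Bookmark classification (min_overlap = 1 bp)
#> bookmarked_mitotic     mitotic_unique   bookmarked_async         async_only
#>                160                 13                160                340

## 2. Gene-level bookmarking
gbf <- gene_bookmark_fraction(cls, d$genes)
gbf$bookmarked_fraction     # 32.0 (% of 500 asynchronous target genes)

## 3. Signal matrix, k-means, cluster composition
mat <- build_matrix(d$track, d$async, flank = 2000, binsize = 50)
cl  <- kmeans_cluster(mat, k = 3, seed = 42)   # cluster 1 = strongest
cluster_overlap_fractions(cls, cl)$pct_of_bookmarked
#> [1] 68.8 28.1  3.1

## 4. Motif counts and distribution comparison
seqs <- d$sequences
co <- count_motifs(cls$async_only,
                   seqs[S4Vectors::mcols(cls$async_only)$name], d$pwm)
cb <- count_motifs(cls$bookmarked_mitotic,
                   seqs[S4Vectors::mcols(cls$bookmarked_mitotic)$name], d$pwm)
c(bookmarked = mean(cb$counts), async_only = mean(co$counts))
#> bookmarked async_only
#>       2.94       1.46
ks_compare(co$counts, cb$counts)
#> D = 0.414, p = 1.19e-16

## 5. Chromatin-state fold decrease in mitosis
sfc <- state_fold_change(overlap_enrichment(d$async, d$segmentation),
                         overlap_enrichment(cls$bookmarked_mitotic,
                                            d$segmentation))
sfc[sfc$state %in% c("EnhWk", "EnhBiv"), c("state", "fold_change")]
#>    state fold_change
#>   EnhBiv        1.86
#>    EnhWk        1.64

## 6. Imaging: chromatin retention
imgs <- generate_images(cfg)
logr <- vapply(imgs$cells, function(cell) {
  mk <- make_masks(cell$dna, cell$cell_mask, threshold = 100)
  retention_ratio(cell$intensity, mk$chromatin, mk$cytoplasm)$log2_ratio
}, numeric(1))
mean(logr)                  # 1.322; planted log2(2.5) = 1.322
```

The generator plants 160 bookmarked peaks (32% of 500) and this run
recovers exactly 160. The planted chromatin-state avoidance factors are
1.8 (EnhWk) and 2.2 (EnhBiv); at this scale the estimates (1.64, 1.86
above) scatter around those values with a coefficient of variation of
roughly 15–30%, as expected from the ~35–70 peaks per state.

## File-based workflow

`generate_dataset(cfg, dir = "study/")` writes chrom.sizes, narrowPeak
files, FASTA sequences, a MEME motif file, a bedGraph track, a
segmentation BED, a gene table and a JSON manifest. `run_pipeline()`
then drives the full analysis from a YAML config (or an R list) and
writes `report.json` plus BED/TSV artifacts:

```r
run_pipeline("config.yaml", out_dir = "results/")
```

See `default_pipeline_params()` for the tunable knobs.

## Documentation

The methods vignette (`vignettes/mitotic-bookmarking.Rmd`) describes
the statistical model behind each module, every generator parameter and
its default, the numerical conventions (coordinate systems, exact PWM
p-values, Otsu tie-breaking, min-max normalisation variants) and the
known limitations of the synthetic data. Function-level documentation
is in the roxygen comments of the `R/` sources.
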