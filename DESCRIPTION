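Package: mitobook
Title: Mitotic Bookmarking Analysis of Transcription-Factor ChIP-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify mitotic bookmarking by a transcription factor
    from ChIP-seq peak calls and signal tracks. Classifies peaks into
    bookmarked, interphase-only and mitotic-unique sets; assigns peaks to
    genes by nearest transcription start site; builds summit-centred signal
    matrices, clusters them by k-means and scores between-condition signal
    differences; scans peak sequences with position weight matrices using
    exact log-odds p-values and compares per-peak motif-count distributions
    with matched subsampling and a Kolmogorov-Smirnov test; computes
    chromatin-state overlap enrichment with min-max normalisation and
    between-condition fold changes; and quantifies mitotic chromatin
    retention from fluorescence images as chromatin/cytoplasm intensity
    ratios. A seeded synthetic-data generator produces all inputs with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
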