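#' Read a chromatin-state segmentation from BED
#'
#' Four-column BED with the state label in column 4 (ChromHMM dense-bed
#' dialect; extra columns ignored). Intervals must be non-overlapping
#' within each chromosome.
#'
#' @param path Path to the segmentation BED file.
#' @param genome A `Seqinfo` object.
#' @return A `GRanges` with a `state` column; `metadata(x)$states` holds
#'   the state catalogue.
#' @export
read_segmentation <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          fill = TRUE)
  if (ncol(df) < 4L) stop("segmentation BED needs at least 4 columns")
  seg <- segmentation(genome, df[[1]], df[[2]], df[[3]], df[[4]])
  seg
}

#' @rdname read_segmentation
#' @param chrom,start,end BED-style (0-based half-open) coordinates.
#' @param state State labels.
#' @export
segmentation <- function(genome, chrom, start, end, state) {
  known <- chrom %in% GenomeInfoDb::seqnames(genome)
  if (any(!known)) {
    warning(sum(!known), " segment(s) on unknown chromosomes skipped")
    chrom <- chrom[known]; start <- start[known]
    end <- end[known]; state <- state[known]
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               state = as.character(state),
                               seqinfo = genome)
  gr <- GenomicRanges::sort(gr)
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(self)) stop("overlapping segmentation intervals")
  S4Vectors::metadata(gr)$states <- sort(unique(as.character(state)))
  gr
}

#' Chromatin-state overlap enrichment of a peak set
#'
#' For every state: the fraction of peak bases falling in the state, the
#' fraction of the genome the state occupies, and their ratio (fold
#' enrichment), following ChromHMM OverlapEnrichment semantics
#' (base-pair overlap). A peak-count mode reports instead the percentage
#' of peaks overlapping each state by at least 1 bp.
#'
#' @param peaks A peak set.
#' @param seg A segmentation from [read_segmentation()].
#' @param mode `"bases"` (default, ChromHMM semantics) or `"peaks"`
#'   (percentage of peaks overlapping each state).
#' @return A `data.frame` of class `enrichment_table` with columns
#'   `state`, `peak_fraction` (percent), `genome_fraction` (percent),
#'   `fold_enrichment` (`NA` when the state is absent from the genome).
#' @export
overlap_enrichment <- function(peaks, seg, mode = c("bases", "peaks")) {
  validate_peakset(peaks)
  mode <- match.arg(mode)
  if (length(peaks) == 0L) stop("empty peak set")
  states <- S4Vectors::metadata(seg)$states
  if (is.null(states)) states <- sort(unique(S4Vectors::mcols(seg)$state))
  peaks_red <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
  total_peak_bases <- sum(as.numeric(GenomicRanges::width(peaks_red)))
  gsize <- genome_size(GenomeInfoDb::seqinfo(peaks))
  rows <- lapply(states, function(s) {
    sgr <- seg[S4Vectors::mcols(seg)$state == s]
    state_bases <- sum(as.numeric(GenomicRanges::width(sgr)))
    genome_fraction <- 100 * state_bases / gsize
    if (mode == "bases") {
      ov <- GenomicRanges::intersect(peaks_red, sgr, ignore.strand = TRUE)
      peak_fraction <- 100 *
        sum(as.numeric(GenomicRanges::width(ov))) / total_peak_bases
    } else {
      peak_fraction <- 100 *
        sum(GenomicRanges::countOverlaps(peaks, sgr,
                                         ignore.strand = TRUE) > 0) /
        length(peaks)
    }
    fold <- if (state_bases == 0) NA_real_ else
      peak_fraction / genome_fraction
    data.frame(state = s, peak_fraction = peak_fraction,
               genome_fraction = genome_fraction,
               fold_enrichment = fold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_table", class(out))
  attr(out, "mode") <- mode
  out
}

#' Min-max normalisation of per-state values
#'
#' Subtracts the minimum and divides by the shifted maximum, so that a
#' non-constant vector spans exactly `[0, 1]`. With
#' `legacy_divisor = TRUE` the division uses the original (unshifted)
#' maximum instead. A constant vector returns all zeros with a warning.
#'
#' @param values Numeric vector (length >= 2) of per-state values.
#' @param legacy_divisor Divide by the unshifted maximum.
#' @return Numeric vector on `[0, 1]` (names preserved).
#' @export
minmax_normalise <- function(values, legacy_divisor = FALSE) {
  if (length(values) < 2L) stop("need at least 2 states")
  mn <- min(values)
  mx <- max(values)
  if (mx == mn) {
    warning("constant vector: min-max normalisation returns zeros")
    return(values * 0)
  }
  shifted <- values - mn
  if (legacy_divisor) shifted / mx else shifted / (mx - mn)
}

#' Per-state fold change between two enrichment tables
#'
#' Min-max normalises each table's fold enrichments and reports, per
#' state, `A / B` on the normalised scale. With the asynchronous
#' condition as A and the mitotic as B, values above 1 indicate binding
#' loss in mitosis. Zero denominators give `NA`, never infinity.
#'
#' @param tableA,tableB `enrichment_table` objects on the same state
#'   catalogue.
#' @param legacy_divisor Passed to [minmax_normalise()].
#' @return A `data.frame` with columns `state`, `normalised_A`,
#'   `normalised_B`, `fold_change`; attribute `sign_convention` is
#'   `"A_over_B"`.
#' @export
state_fold_change <- function(tableA, tableB, legacy_divisor = FALSE) {
  if (!identical(tableA$state, tableB$state)) {
    stop("state catalogues differ between the two tables")
  }
  na <- minmax_normalise(tableA$fold_enrichment,
                         legacy_divisor = legacy_divisor)
  nb <- minmax_normalise(tableB$fold_enrichment,
                         legacy_divisor = legacy_divisor)
  fc <- ifelse(nb == 0, NA_real_, na / nb)
  out <- data.frame(state = tableA$state, normalised_A = na,
                    normalised_B = nb, fold_change = fc,
                    stringsAsFactors = FALSE)
  attr(out, "sign_convention") <- "A_over_B"
  out
}
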