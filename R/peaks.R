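#' Construct a peak set
#'
#' A peak set is a [GenomicRanges::GRanges] carrying one metadata column per
#' narrowPeak-style field: `name`, `score` and `summit` (the summit offset
#' from the interval start, 0-based). File coordinates follow the BED
#' convention (0-based, half-open); in memory they are held as standard
#' 1-based closed `GRanges`, and the readers/writers do the conversion. The
#' condition tag (e.g. "async", "mitotic") is stored in
#' `metadata(x)$label`.
#'
#' @param genome A `Seqinfo` object (see [Genome()]).
#' @param chrom,start,end Vectors of chromosome, 0-based start and
#'   exclusive end (BED convention).
#' @param name Peak identifiers; autogenerated when `NULL`.
#' @param score Numeric scores (default 0).
#' @param summit Summit offsets from `start` in bp, or `NA` to use the
#'   interval midpoint (rounded down).
#' @param label Condition tag.
#' @return A sorted `GRanges` with the peak-set metadata columns.
#' @examples
#' gn <- Genome(c(chr1 = 1000))
#' ps <- PeakSet(gn, "chr1", 100, 200, label = "async")
#' peak_summits(ps)  # midpoint by default
#' @export
PeakSet <- function(genome, chrom, start, end, name = NULL, score = 0,
                    summit = NA, label = "peaks") {
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0L) n <- 0L
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  score <- rep_len(score, n)
  summit <- rep_len(summit, n)
  if (any(start < 0) || any(start >= end)) {
    stop("invalid interval: need 0 <= start < end")
  }
  width <- end - start
  mid <- floor(width / 2)
  summit <- ifelse(is.na(summit) | summit < 0, mid, summit)
  if (any(summit >= width)) stop("summit offset outside interval")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    name = as.character(name),
    score = as.numeric(score),
    summit = as.integer(summit),
    seqinfo = genome
  )
  bounds <- GenomeInfoDb::seqlengths(genome)[as.character(
    GenomicRanges::seqnames(gr))]
  if (any(GenomicRanges::end(gr) > bounds)) {
    stop("interval exceeds chromosome bounds")
  }
  gr <- GenomicRanges::sort(gr)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' @rdname PeakSet
#' @param x Object to test.
#' @export
is_peakset <- function(x) {
  methods::is(x, "GRanges") &&
    all(c("name", "score", "summit") %in% names(S4Vectors::mcols(x)))
}

validate_peakset <- function(x, arg = deparse(substitute(x))) {
  if (!is_peakset(x)) {
    stop(arg, " is not a peak set (GRanges with name/score/summit columns)")
  }
  invisible(x)
}

#' Condition label of a peak set
#' @param x A peak set.
#' @return Character scalar.
#' @export
peak_label <- function(x) {
  lb <- S4Vectors::metadata(x)$label
  if (is.null(lb)) "peaks" else lb
}

#' Absolute summit positions of a peak set
#'
#' @param peaks A peak set.
#' @param as_granges If `TRUE`, return width-1 `GRanges` at the summits;
#'   otherwise a 1-based integer vector of positions.
#' @return Integer vector or `GRanges`.
#' @export
peak_summits <- function(peaks, as_granges = FALSE) {
  validate_peakset(peaks)
  pos <- GenomicRanges::start(peaks) + S4Vectors::mcols(peaks)$summit
  if (!as_granges) return(pos)
  GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                         IRanges::IRanges(pos, pos),
                         name = S4Vectors::mcols(peaks)$name,
                         seqinfo = GenomeInfoDb::seqinfo(peaks))
}

#' Read peaks from narrowPeak or BED
#'
#' Accepts ENCODE narrowPeak (BED6+4), plain BED3/BED6, and the package's
#' own BED6+summit output. The summit offset is taken from narrowPeak
#' column 10 when it is >= 0; otherwise (and for BED inputs without a
#' summit column) the interval midpoint is used. Peaks on chromosomes not
#' present in `genome` are skipped with a warning; peaks extending past
#' chromosome ends are clipped with a warning.
#'
#' @param path Path to the peak file.
#' @param genome A `Seqinfo` object.
#' @param label Condition tag stored on the result.
#' @return A sorted peak set (`GRanges`), see [PeakSet()].
#' @export
read_narrowpeak <- function(path, genome, label = "peaks") {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(PeakSet(genome, character(), integer(), integer(), label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # fall back to whitespace splitting for space-separated files
  one_col <- vapply(fields, length, 1L) == 1L
  fields[one_col] <- strsplit(trimws(lines[one_col]), "\\s+")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) {
    stop("malformed peak line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 fields")
  }
  getcol <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  chrom <- getcol(1L)
  start <- suppressWarnings(as.numeric(getcol(2L)))
  end <- suppressWarnings(as.numeric(getcol(3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start >= end | start < 0)
  if (length(bad)) {
    stop("malformed peak line ", lineno[bad[1L]],
         ": invalid coordinates '", lines[bad[1L]], "'")
  }
  name <- getcol(4L)
  name[is.na(name) | name == "."] <- NA
  if (anyNA(name)) {
    auto <- sprintf("peak_%d", seq_along(chrom))
    name[is.na(name)] <- auto[is.na(name)]
  }
  score <- suppressWarnings(as.numeric(getcol(5L)))
  score[is.na(score)] <- 0
  # summit offset: narrowPeak column 10, or our own column 7 for BED6+summit
  summit <- rep(NA_real_, length(chrom))
  if (max(nf) >= 10L) {
    s10 <- suppressWarnings(as.numeric(getcol(10L)))
    summit <- ifelse(!is.na(s10) & s10 >= 0, s10, NA_real_)
  } else if (max(nf) == 7L) {
    s7 <- suppressWarnings(as.numeric(getcol(7L)))
    summit <- ifelse(!is.na(s7) & s7 >= 0, s7, NA_real_)
  }
  known <- chrom %in% GenomeInfoDb::seqnames(genome)
  if (any(!known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from genome ",
            "were skipped")
  }
  chrom <- chrom[known]; start <- start[known]; end <- end[known]
  name <- name[known]; score <- score[known]; summit <- summit[known]
  bound <- as.numeric(
    GenomeInfoDb::seqlengths(genome)[chrom])
  over <- end > bound
  if (any(over)) {
    warning(sum(over), " peak(s) clipped to chromosome bounds")
    end[over] <- bound[over]
    summit[over & !is.na(summit) & summit >= end - start] <- NA
  }
  PeakSet(genome, chrom, start, end, name = name, score = score,
          summit = summit, label = label)
}

#' Write a peak set as BED
#'
#' Emits tab-separated BED6 plus a seventh column with the summit offset,
#' sorted, 0-based half-open. `read_narrowpeak(write_bed(x))` is the
#' identity on valid peak sets.
#'
#' @param peaks A peak set.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(peaks, path) {
  validate_peakset(peaks)
  peaks <- GenomicRanges::sort(peaks)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = S4Vectors::mcols(peaks)$name,
    score = S4Vectors::mcols(peaks)$score,
    strand = rep(".", length(peaks)),
    summit = S4Vectors::mcols(peaks)$summit
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge nearby intervals (bedtools merge semantics)
#'
#' Any two intervals whose gap is at most `max_gap` bp end up in one output
#' interval; book-ended intervals (gap 0) merge at the default. Output is
#' sorted and non-overlapping; merged regions get fresh names, score 0 and
#' midpoint summits.
#'
#' @param peaks A peak set.
#' @param max_gap Maximum gap in bp (default 0, the bedtools default).
#' @return A merged peak set.
#' @export
merge_intervals <- function(peaks, max_gap = 0) {
  validate_peakset(peaks)
  if (max_gap < 0) stop("max_gap must be >= 0")
  red <- GenomicRanges::reduce(peaks, min.gapwidth = max_gap + 1L)
  PeakSet(GenomeInfoDb::seqinfo(peaks),
          as.character(GenomicRanges::seqnames(red)),
          GenomicRanges::start(red) - 1L,
          GenomicRanges::end(red),
          name = sprintf("region_%d", seq_along(red)),
          label = peak_label(peaks))
}

#' Remove peaks overlapping an exclusion list
#'
#' Drops every peak that overlaps any interval of `exclude` by at least 1
#' bp, the conventional treatment of assay blacklists. No blacklist is
#' bundled; supply one as a BED file via [read_narrowpeak()].
#'
#' @param peaks A peak set.
#' @param exclude A peak set (or any `GRanges`) of regions to exclude.
#' @return The filtered peak set.
#' @export
exclude_regions <- function(peaks, exclude) {
  validate_peakset(peaks)
  hit <- GenomicRanges::countOverlaps(peaks, exclude,
                                      ignore.strand = TRUE) > 0
  peaks[!hit]
}
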