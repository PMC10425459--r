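#' Classify peaks into bookmarked and condition-unique sets
#'
#' A mitotic peak is "bookmarked" when it overlaps at least one
#' asynchronous (interphase) peak by `min_overlap` bp or more; the
#' asynchronous side is classified symmetrically. Counts are per-condition
#' peak counts, so one mitotic peak spanning two asynchronous peaks counts
#' once on the mitotic side while both asynchronous peaks count as
#' bookmarked.
#'
#' @param async Peak set for the asynchronous condition.
#' @param mitotic Peak set for the mitotic condition.
#' @param min_overlap Minimum overlap in bp (default 1, the bedtools
#'   intersect default).
#' @return An object of class `bookmark_classification`: a list with the
#'   four peak sets (`bookmarked_mitotic`, `mitotic_unique`,
#'   `bookmarked_async`, `async_only`) and their `counts`.
#' @export
classify_peaks <- function(async, mitotic, min_overlap = 1L) {
  validate_peakset(async)
  validate_peakset(mitotic)
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  gA <- GenomeInfoDb::seqinfo(async)
  gM <- GenomeInfoDb::seqinfo(mitotic)
  if (!identical(GenomeInfoDb::seqlengths(gA), GenomeInfoDb::seqlengths(gM))) {
    stop("async and mitotic peak sets are on different genomes")
  }
  mit_hit <- GenomicRanges::countOverlaps(
    mitotic, async, minoverlap = min_overlap, ignore.strand = TRUE) > 0
  asy_hit <- GenomicRanges::countOverlaps(
    async, mitotic, minoverlap = min_overlap, ignore.strand = TRUE) > 0
  res <- list(
    bookmarked_mitotic = mitotic[mit_hit],
    mitotic_unique = mitotic[!mit_hit],
    bookmarked_async = async[asy_hit],
    async_only = async[!asy_hit],
    min_overlap = as.integer(min_overlap)
  )
  res$counts <- c(
    bookmarked_mitotic = sum(mit_hit),
    mitotic_unique = sum(!mit_hit),
    bookmarked_async = sum(asy_hit),
    async_only = sum(!asy_hit)
  )
  class(res) <- "bookmark_classification"
  res
}

#' @export
print.bookmark_classification <- function(x, ...) {
  cat("Bookmark classification (min_overlap =", x$min_overlap, "bp)\n")
  print(x$counts)
  invisible(x)
}

#' Percentage of query peaks overlapping a subject peak set
#'
#' @param query,subject Peak sets on the same genome.
#' @param min_overlap Minimum overlap in bp.
#' @return Percentage in `[0, 100]`.
#' @export
overlap_fraction <- function(query, subject, min_overlap = 1L) {
  validate_peakset(query)
  if (length(query) == 0L) stop("overlap percentage undefined: empty query")
  hit <- GenomicRanges::countOverlaps(
    query, subject, minoverlap = min_overlap, ignore.strand = TRUE) > 0
  100 * sum(hit) / length(query)
}

#' Read a gene annotation table
#'
#' Tab-separated columns `gene_id`, `chrom`, `strand`, `tss` (0-based TSS
#' position, matching the package's BED coordinate convention). A header
#' line is optional.
#'
#' @param path Path to the TSV file.
#' @param genome A `Seqinfo` object for bounds checking.
#' @return A `data.frame` with those four columns.
#' @export
read_gene_annotation <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("gene_id", "chrom", "strand", "tss"),
                          colClasses = c("character", "character",
                                         "character", "numeric"))
  if (nrow(df) && identical(df$gene_id[1], "gene_id")) df <- df[-1L, ]
  validate_gene_annotation(df, genome)
}

validate_gene_annotation <- function(genes, genome = NULL) {
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(genes))) {
    stop("gene annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!is.null(genome)) {
    len <- GenomeInfoDb::seqlengths(genome)[genes$chrom]
    if (anyNA(len) || any(genes$tss < 0) || any(genes$tss >= len)) {
      stop("TSS outside genome bounds")
    }
  }
  genes
}

#' Assign peaks to genes by nearest TSS
#'
#' Each peak is assigned to the gene whose TSS is nearest to the peak
#' summit. The assignment is reported as category "promoter" when the
#' summit lies within `[tss - promoter_up, tss + promoter_down]` in the
#' gene's strand orientation, "distal" otherwise, and peaks farther than
#' `max_distance` from every TSS are left unassigned. Distance ties are
#' broken towards the lexicographically smaller `gene_id`.
#'
#' @param peaks A peak set.
#' @param genes Gene annotation `data.frame` (see [read_gene_annotation()]).
#' @param promoter_up,promoter_down Promoter window upstream/downstream of
#'   the TSS in bp (defaults 2000 / 500).
#' @param max_distance Maximum summit-to-TSS distance in bp (default 1e5).
#' @return A `data.frame` with one row per peak: `peak`, `gene_id`,
#'   `distance` (bp, `NA` when unassigned) and `category` in
#'   `{"promoter", "distal", "unassigned"}`.
#' @export
assign_genes <- function(peaks, genes, promoter_up = 2000,
                         promoter_down = 500, max_distance = 1e5) {
  validate_peakset(peaks)
  n <- length(peaks)
  out <- data.frame(peak = S4Vectors::mcols(peaks)$name,
                    gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    category = rep("unassigned", n),
                    stringsAsFactors = FALSE)
  if (is.null(genes) || nrow(genes) == 0L) {
    warning("empty gene annotation: all peaks unassigned")
    return(out)
  }
  genes <- validate_gene_annotation(genes)
  sm_chr <- as.character(GenomicRanges::seqnames(peaks))
  sm_pos <- peak_summits(peaks) - 1L  # 0-based, same convention as tss
  for (i in seq_along(peaks)) {
    on_chr <- genes$chrom == sm_chr[i]
    if (!any(on_chr)) next
    g <- genes[on_chr, , drop = FALSE]
    d <- abs(g$tss - sm_pos[i])
    dmin <- min(d)
    if (dmin > max_distance) next
    cand <- g[d == dmin, , drop = FALSE]
    pick <- cand[order(cand$gene_id)[1L], ]
    # signed offset in the gene's strand orientation: + downstream of TSS
    delta <- sm_pos[i] - pick$tss
    if (pick$strand == "-") delta <- -delta
    out$gene_id[i] <- pick$gene_id
    out$distance[i] <- dmin
    out$category[i] <- if (delta >= -promoter_up && delta <= promoter_down) {
      "promoter"
    } else "distal"
  }
  out
}

#' Gene-level bookmarking table and fraction
#'
#' Flags each annotated gene for carrying at least one asynchronous peak,
#' at least one mitotic peak, and for being bookmarked (at least one
#' bookmarked asynchronous peak). The headline fraction is the percentage
#' of asynchronous-target genes that are bookmarked; genes targeted only
#' by mitotic-unique peaks are reported separately and excluded from the
#' denominator.
#'
#' @param cls A `bookmark_classification` from [classify_peaks()].
#' @param genes Gene annotation `data.frame`.
#' @inheritParams assign_genes
#' @return A list with `table` (per-gene flags), `bookmarked_fraction`
#'   (percentage), and the counts behind it.
#' @export
gene_bookmark_fraction <- function(cls, genes, promoter_up = 2000,
                                   promoter_down = 500, max_distance = 1e5) {
  stopifnot(inherits(cls, "bookmark_classification"))
  assign1 <- function(ps) {
    a <- assign_genes(ps, genes, promoter_up, promoter_down, max_distance)
    unique(a$gene_id[!is.na(a$gene_id)])
  }
  async_all <- c(cls$bookmarked_async, cls$async_only)
  g_async <- assign1(async_all)
  g_book <- assign1(cls$bookmarked_async)
  g_mit <- assign1(c(cls$bookmarked_mitotic, cls$mitotic_unique))
  g_mit_unique <- setdiff(assign1(cls$mitotic_unique), g_async)
  if (length(g_async) == 0L) stop("no genes assigned to asynchronous peaks")
  tab <- data.frame(
    gene_id = sort(unique(c(g_async, g_mit))),
    stringsAsFactors = FALSE
  )
  tab$has_async_peak <- tab$gene_id %in% g_async
  tab$has_mitotic_peak <- tab$gene_id %in% g_mit
  tab$is_bookmarked <- tab$gene_id %in% g_book
  list(
    table = tab,
    bookmarked_fraction = 100 * length(intersect(g_book, g_async)) /
      length(g_async),
    n_async_genes = length(g_async),
    n_bookmarked_genes = length(intersect(g_book, g_async)),
    mitotic_unique_genes = g_mit_unique
  )
}

#' Associate differentially expressed genes with bookmarked motifs
#'
#' For each expression direction and each motif, counts differentially
#' expressed genes that are bookmarked and whose bookmarked peak(s)
#' contain the motif.
#'
#' @param de_genes `data.frame` with columns `gene_id` and `direction`
#'   (`"up"` or `"down"`).
#' @param table Per-gene table from [gene_bookmark_fraction()] (the
#'   `table` element).
#' @param motif_presence Logical matrix, genes x motifs: whether each
#'   gene's bookmarked peaks contain each motif. Row names are gene ids.
#' @return A `data.frame` of counts with columns `direction`, `motif`,
#'   `count`.
#' @export
de_gene_association <- function(de_genes, table, motif_presence) {
  stopifnot(is.data.frame(de_genes),
            all(c("gene_id", "direction") %in% names(de_genes)))
  unknown <- setdiff(de_genes$gene_id, table$gene_id)
  if (length(unknown)) {
    warning(length(unknown), " DE gene id(s) not in the gene table, ignored")
    de_genes <- de_genes[de_genes$gene_id %in% table$gene_id, , drop = FALSE]
  }
  book <- table$gene_id[table$is_bookmarked]
  motifs <- colnames(motif_presence)
  dirs <- c("up", "down")
  out <- expand.grid(direction = dirs, motif = motifs,
                     stringsAsFactors = FALSE)
  out$count <- 0L
  for (r in seq_len(nrow(out))) {
    ids <- de_genes$gene_id[de_genes$direction == out$direction[r]]
    ids <- intersect(ids, book)
    ids <- ids[ids %in% rownames(motif_presence)]
    out$count[r] <- sum(motif_presence[ids, out$motif[r]])
  }
  out
}
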