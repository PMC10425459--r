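#' Read a bedGraph signal track
#'
#' bedGraph semantics: sorted, non-overlapping (interval, value) pairs per
#' chromosome, with uncovered positions implicitly 0. Returned as a
#' `GRanges` with a `score` column and the genome as seqinfo.
#'
#' @param path Path to a bedGraph file.
#' @param genome A `Seqinfo` object.
#' @return A `GRanges` signal track.
#' @export
read_bedgraph <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  known <- df$chrom %in% GenomeInfoDb::seqnames(genome)
  if (any(!known)) {
    warning(sum(!known), " bedGraph line(s) on unknown chromosomes skipped")
    df <- df[known, , drop = FALSE]
  }
  if (any(!is.finite(df$value))) stop("non-finite bedGraph values")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               score = df$value, seqinfo = genome)
  gr <- GenomicRanges::sort(gr)
  if (any(S4Vectors::queryHits(GenomicRanges::findOverlaps(
    gr, drop.self = TRUE)))) {
    stop("overlapping bedGraph intervals")
  }
  gr
}

#' Write a signal track as bedGraph
#' @param track A `GRanges` with a `score` column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(track)),
                   GenomicRanges::start(track) - 1L,
                   GenomicRanges::end(track),
                   S4Vectors::mcols(track)$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a summit-centred signal matrix
#'
#' For each peak, the window `[summit - flank, summit + flank)` is tiled
#' into bins of `binsize` bp and each bin is filled with the mean track
#' value over its bases, counting uncovered bases (and bases beyond the
#' chromosome ends) as 0. This reproduces reference-point signal matrices
#' as produced by deepTools computeMatrix with the default mean statistic.
#'
#' @param track A `GRanges` signal track (see [read_bedgraph()]).
#' @param peaks A peak set with summits.
#' @param flank Half-window in bp (default 2000).
#' @param binsize Bin width in bp (default 50); must divide `2 * flank`.
#' @return A numeric matrix, peaks x bins, with rownames the peak names
#'   and attributes `flank` and `binsize`; class `signal_matrix`.
#' @export
build_matrix <- function(track, peaks, flank = 2000, binsize = 50) {
  validate_peakset(peaks)
  if ((2 * flank) %% binsize != 0) stop("binsize must divide 2*flank")
  nbins <- as.integer(2 * flank / binsize)
  cov <- GenomicRanges::coverage(track, weight = "score")
  sm_chr <- as.character(GenomicRanges::seqnames(peaks))
  sm0 <- peak_summits(peaks) - 1L          # 0-based summit
  win_start0 <- sm0 - flank                 # 0-based window start
  vals <- matrix(0, nrow = length(peaks), ncol = nbins,
                 dimnames = list(S4Vectors::mcols(peaks)$name, NULL))
  chrlens <- GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(peaks))
  wlen <- 2L * as.integer(flank)
  for (i in seq_along(peaks)) {
    rle <- cov[[sm_chr[i]]]
    clen <- chrlens[[sm_chr[i]]]
    v <- numeric(wlen)
    lo0 <- max(win_start0[i], 0L)
    hi0 <- min(win_start0[i] + wlen, clen)  # exclusive
    if (hi0 > lo0) {
      seg <- as.numeric(S4Vectors::window(rle, lo0 + 1L, hi0))
      v[(lo0 - win_start0[i] + 1L):(hi0 - win_start0[i])] <- seg
    }
    vals[i, ] <- colMeans(matrix(v, nrow = binsize))
  }
  attr(vals, "flank") <- flank
  attr(vals, "binsize") <- binsize
  class(vals) <- c("signal_matrix", class(vals))
  vals
}

#' K-means clustering of a signal matrix
#'
#' Lloyd's algorithm on the matrix rows with Euclidean distance, taking
#' the best of `n_init` seeded initialisations by total within-cluster sum
#' of squares. Clusters are relabelled in descending order of cluster mean
#' signal, so cluster 1 always has the strongest mean signal and labels
#' are stable across runs.
#'
#' @param matrix A `signal_matrix` (or plain numeric matrix with
#'   rownames).
#' @param k Number of clusters.
#' @param seed RNG seed (default 1234).
#' @param n_init Number of random initialisations (default 10).
#' @return A list of class `cluster_result`: `k`, `labels` (named integer
#'   vector in 1..k), `sizes`, `cluster_means`, `seed`, `inertia`.
#' @export
kmeans_cluster <- function(matrix, k, seed = 1234, n_init = 10) {
  x <- unclass(matrix)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x)) stop("k exceeds the number of features")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_init,
                  algorithm = "Lloyd", iter.max = 200))
  raw <- fit$cluster
  means <- vapply(seq_len(k), function(c) mean(x[raw == c, , drop = FALSE]),
                  numeric(1))
  relabel <- order(means, decreasing = TRUE)      # relabel[new] = old
  newlab <- match(raw, relabel)
  names(newlab) <- rownames(x)
  structure(list(
    k = k,
    labels = newlab,
    sizes = tabulate(newlab, nbins = k),
    cluster_means = sort(means, decreasing = TRUE),
    seed = seed,
    inertia = fit$tot.withinss
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("K-means result: k =", x$k, " inertia =", signif(x$inertia, 6), "\n")
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Distribution of bookmarked peaks across signal clusters
#'
#' Given a clustering of the asynchronous peaks, reports per cluster the
#' percentage of all bookmarked asynchronous peaks falling in that
#' cluster, and the percentage of that cluster's peaks that are
#' bookmarked.
#'
#' @param cls A `bookmark_classification` from [classify_peaks()].
#' @param cluster A `cluster_result` computed on the full asynchronous
#'   peak set (labels named by peak name).
#' @return A `data.frame` with columns `cluster`, `n_peaks`,
#'   `n_bookmarked`, `pct_of_bookmarked`, `pct_bookmarked_in_cluster`.
#' @export
cluster_overlap_fractions <- function(cls, cluster) {
  stopifnot(inherits(cls, "bookmark_classification"),
            inherits(cluster, "cluster_result"))
  book <- S4Vectors::mcols(cls$bookmarked_async)$name
  if (length(book) == 0L) stop("no bookmarked peaks")
  missing <- setdiff(book, names(cluster$labels))
  if (length(missing)) {
    stop("bookmarked peaks absent from the clustering: ", missing[1L], " ...")
  }
  out <- data.frame(cluster = seq_len(cluster$k),
                    n_peaks = cluster$sizes)
  out$n_bookmarked <- vapply(seq_len(cluster$k), function(c) {
    sum(cluster$labels[book] == c)
  }, integer(1))
  out$pct_of_bookmarked <- 100 * out$n_bookmarked / length(book)
  out$pct_bookmarked_in_cluster <- ifelse(
    out$n_peaks > 0, 100 * out$n_bookmarked / out$n_peaks, NA_real_)
  out
}

#' Mean signal profile over a subset of features
#'
#' @param matrix A `signal_matrix`.
#' @param subset Character vector of feature ids (rownames); `NULL` for
#'   all rows.
#' @return Numeric vector of per-bin means.
#' @export
mean_profile <- function(matrix, subset = NULL) {
  x <- unclass(matrix)
  if (!is.null(subset)) {
    if (length(subset) == 0L) stop("empty feature subset")
    bad <- setdiff(subset, rownames(x))
    if (length(bad)) stop("unknown feature id: ", bad[1L])
    x <- x[subset, , drop = FALSE]
  }
  colMeans(x)
}

#' Bin-summed signal difference between two peak groups
#'
#' The score sums, over all bins, the difference between the mean profile
#' of group A and that of group B. The sign convention is A minus B; a
#' positive score means more signal in group A. With `absolute = TRUE`
#' the absolute per-bin differences are summed instead.
#'
#' @param matrix A `signal_matrix`.
#' @param groupA,groupB Character vectors of feature ids.
#' @param absolute Sum absolute differences instead of signed ones.
#' @return Numeric scalar with attribute `sign_convention`.
#' @export
signal_difference_score <- function(matrix, groupA, groupB,
                                    absolute = FALSE) {
  pa <- mean_profile(matrix, groupA)
  pb <- mean_profile(matrix, groupB)
  d <- pa - pb
  s <- if (absolute) sum(abs(d)) else sum(d)
  attr(s, "sign_convention") <- "A_minus_B"
  s
}
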