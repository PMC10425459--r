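DNA_ALPHABET <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Per-position nucleotide probabilities with a background model. A
#' pseudocount proportional to the background is folded in so that all
#' probabilities are strictly positive and log-odds scores stay finite.
#'
#' @param motif_id Motif identifier.
#' @param probs 4 x L numeric matrix of probabilities, rows A, C, G, T;
#'   each column must sum to 1 (tolerance 1e-6 before pseudocount).
#' @param background Background probabilities over A, C, G, T (default
#'   uniform).
#' @param pseudocount Pseudocount fraction (default 0.1, folded in as
#'   `(p + pc * bg) / (1 + pc)`).
#' @return An object of class `pwm`.
#' @export
PWM <- function(motif_id, probs, background = rep(0.25, 4),
                pseudocount = 0.1) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A, C, G, T)")
  if (any(abs(colSums(probs) - 1) > 1e-6)) {
    stop("PWM columns must each sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  if (any(background <= 0)) stop("background probabilities must be > 0")
  adj <- (probs + pseudocount * background) / (1 + pseudocount)
  rownames(adj) <- DNA_ALPHABET
  structure(list(motif_id = motif_id, probs = adj,
                 background = stats::setNames(background, DNA_ALPHABET),
                 pseudocount = pseudocount, length = ncol(adj)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "length", x$length, "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Log-odds score matrix of a PWM
#'
#' @param pwm A `pwm` object.
#' @return 4 x L matrix of `log2(p / background)` scores in bits.
#' @export
pwm_log_odds <- function(pwm) {
  log2(pwm$probs / pwm$background)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param pwm A `pwm` object.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_ALPHABET[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm A `pwm` object.
#' @return A `pwm` scoring the reverse strand.
#' @keywords internal
pwm_revcomp <- function(pwm) {
  p2 <- pwm
  p2$probs <- pwm$probs[4:1, rev(seq_len(pwm$length)), drop = FALSE]
  rownames(p2$probs) <- DNA_ALPHABET
  p2$background <- stats::setNames(pwm$background[4:1], DNA_ALPHABET)
  p2
}

#' Read PWMs from a MEME minimal motif file
#'
#' Parses the MEME minimal format: optional background letter
#' frequencies, then one or more `MOTIF` blocks with
#' `letter-probability matrix` sections. When no background is given a
#' uniform one is used.
#'
#' @param path Path to the MEME file.
#' @param pseudocount Passed to [PWM()].
#' @return A named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  i <- 1L
  n <- length(lines)
  while (i <= n && !grepl("^Background letter frequencies", lines[i]) &&
         !grepl("^MOTIF", lines[i])) i <- i + 1L
  if (i <= n && grepl("^Background letter frequencies", lines[i])) {
    toks <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    lets <- toks[seq(1, length(toks), 2)]
    vals <- as.numeric(toks[seq(2, length(toks), 2)])
    if (!setequal(lets, DNA_ALPHABET)) stop("unsupported alphabet: ",
                                            paste(lets, collapse = ""))
    bg <- vals[match(DNA_ALPHABET, lets)]
    i <- i + 2L
  }
  out <- list()
  while (i <= n) {
    if (grepl("^MOTIF", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= n && !grepl("^letter-probability matrix", lines[j])) {
        if (grepl("^MOTIF", lines[j])) stop("MOTIF ", id, " has no matrix")
        j <- j + 1L
      }
      if (j > n) stop("MOTIF ", id, " has no matrix")
      w <- suppressWarnings(as.integer(
        sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
      rows <- list()
      j <- j + 1L
      while (j <= n && length(rows) < w) {
        if (nzchar(trimws(lines[j]))) {
          vals <- as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]])
          if (length(vals) != 4L || anyNA(vals)) {
            stop("malformed matrix row in motif ", id)
          }
          rows[[length(rows) + 1L]] <- vals
        }
        j <- j + 1L
      }
      if (length(rows) != w) stop("motif ", id, ": expected ", w, " rows")
      probs <- t(do.call(rbind, rows))
      if (any(abs(colSums(probs) - 1) > 1e-4)) {
        stop("motif ", id, ": rows do not sum to 1")
      }
      probs <- sweep(probs, 2, colSums(probs), "/")
      out[[id]] <- PWM(id, probs, background = bg,
                       pseudocount = pseudocount)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) stop("no motifs found in ", path)
  out
}

#' Write PWMs to a MEME minimal motif file
#'
#' Writes the raw (pre-pseudocount is not recoverable, so the adjusted)
#' probabilities; a write/read round trip preserves probabilities to
#' numerical precision when `pseudocount = 0` is used on re-read.
#'
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_ALPHABET, bg), collapse = " "),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      p$length), con)
    for (j in seq_len(p$length)) {
      writeLines(paste(sprintf("%.6f", p$probs[, j]), collapse = "  "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Exact null score distribution of a PWM
#'
#' Discretises the per-position log-odds scores on a fixed grid and
#' convolves the per-position distributions under the background model,
#' giving the exact distribution of the score of a random background
#' window. Window scores are discretised on the same grid (sums of
#' per-position rounded scores), so p-values from this distribution are
#' exact for the discretised score.
#'
#' @param pwm A `pwm` object.
#' @param granularity Grid step in bits (default 1e-3).
#' @return A list: `grid` (integer score support, units of
#'   `granularity`), `prob` (probabilities), `tail` (P(score >= grid)),
#'   `granularity`, and `int_scores` (4 x L integer per-position scores).
#' @export
pwm_score_distribution <- function(pwm, granularity = 1e-3) {
  lo <- pwm_log_odds(pwm)
  ints <- round(lo / granularity)
  storage.mode(ints) <- "integer"
  bg <- pwm$background
  # convolution over positions; dist is a named-by-offset prob vector
  offset <- 0L
  prob <- 1
  for (j in seq_len(ncol(ints))) {
    s <- ints[, j]
    new_lo <- offset + min(s)
    new_hi <- offset + length(prob) - 1L + max(s)
    np <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- offset + s[b] - new_lo
      idx <- seq_along(prob) + sh
      np[idx] <- np[idx] + prob * bg[b]
    }
    prob <- np
    offset <- new_lo
  }
  grid <- seq.int(offset, offset + length(prob) - 1L)
  tail <- rev(cumsum(rev(prob)))
  list(grid = grid, prob = prob, tail = tail,
       granularity = granularity, int_scores = ints)
}

#' P-value of a discretised PWM score
#' @param dist Result of [pwm_score_distribution()].
#' @param int_score Integer score (units of the grid step).
#' @return P(null score >= int_score).
#' @keywords internal
pwm_score_pvalue <- function(dist, int_score) {
  ifelse(int_score <= dist$grid[1L], 1,
         ifelse(int_score > dist$grid[length(dist$grid)], 0,
                dist$tail[int_score - dist$grid[1L] + 1L]))
}

#' Score threshold for a target p-value
#'
#' The smallest grid score whose exact null p-value is at most
#' `p_threshold`; `Inf` when no score is significant at that level.
#'
#' @param pwm A `pwm` object.
#' @param p_threshold Target p-value.
#' @param granularity Grid step in bits.
#' @return Integer threshold on the grid scale (attribute `bits` gives
#'   the value in bits).
#' @export
pwm_score_threshold <- function(pwm, p_threshold = 1e-4,
                                granularity = 1e-3) {
  dist <- pwm_score_distribution(pwm, granularity)
  ok <- which(dist$tail <= p_threshold)
  if (length(ok) == 0L) {
    thr <- Inf
  } else {
    thr <- dist$grid[ok[1L]]
  }
  attr(thr, "bits") <- thr * granularity
  thr
}

scan_one_strand <- function(codes, ints, dist, p_threshold, granularity) {
  L <- ncol(ints)
  n <- length(codes)
  if (L > n) return(NULL)
  nwin <- n - L + 1L
  # window integer scores via per-position lookup; NA codes poison windows
  smat <- matrix(0L, nrow = nwin, ncol = L)
  bad <- rep(FALSE, nwin)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + nwin - 1L)]
    bad <- bad | is.na(cj)
    smat[, j] <- ifelse(is.na(cj), 0L, ints[ifelse(is.na(cj), 1L, cj), j])
  }
  tot <- rowSums(smat)
  pv <- pwm_score_pvalue(dist, tot)
  hit <- !bad & pv <= p_threshold
  if (!any(hit)) return(NULL)
  data.frame(offset = which(hit) - 1L,
             score = tot[hit] * granularity,
             p_value = pv[hit])
}

#' Scan a DNA sequence with a PWM
#'
#' Scores every window of length L on both strands with the log-odds
#' score and reports windows whose exact null p-value (from
#' [pwm_score_distribution()]) is at most `p_threshold`. Windows
#' containing N are skipped; hits may overlap.
#'
#' @param seq DNA string over A, C, G, T, N (case-insensitive).
#' @param pwm A `pwm` object.
#' @param p_threshold P-value threshold (default 1e-4).
#' @param granularity Score grid step in bits.
#' @param dists Optional precomputed pair of score distributions
#'   (`list(fwd =, rev =)` from [pwm_score_distribution()] on the PWM
#'   and its reverse complement), to amortise the DP over many
#'   sequences.
#' @return A `data.frame` with columns `offset` (0-based, leftmost
#'   position of the window on the forward sequence), `strand`, `score`
#'   (bits) and `p_value`, sorted by offset.
#' @export
scan_sequence <- function(seq, pwm, p_threshold = 1e-4,
                          granularity = 1e-3, dists = NULL) {
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% c(DNA_ALPHABET, "N"))) {
    stop("invalid DNA character in sequence")
  }
  codes <- match(chars, DNA_ALPHABET)  # NA for N
  if (is.null(dists)) {
    dists <- list(fwd = pwm_score_distribution(pwm, granularity),
                  rev = pwm_score_distribution(pwm_revcomp(pwm),
                                               granularity))
  }
  dist <- dists$fwd
  fwd <- scan_one_strand(codes, dist$int_scores, dist, p_threshold,
                         granularity)
  rdist <- dists$rev
  rev_hits <- scan_one_strand(codes, rdist$int_scores, rdist, p_threshold,
                              granularity)
  out <- data.frame(offset = integer(), strand = character(),
                    score = numeric(), p_value = numeric())
  if (!is.null(fwd)) {
    fwd$strand <- "+"
    out <- rbind(out, fwd[, c("offset", "strand", "score", "p_value")])
  }
  if (!is.null(rev_hits)) {
    rev_hits$strand <- "-"
    out <- rbind(out,
                 rev_hits[, c("offset", "strand", "score", "p_value")])
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Per-peak motif counts
#'
#' Scans each peak's sequence with [scan_sequence()] and counts hits.
#' With `non_overlapping = TRUE`, overlapping hits are resolved greedily
#' by score.
#'
#' @param peaks A peak set.
#' @param sequences Named character vector (or `DNAStringSet`) of peak
#'   sequences keyed by peak name.
#' @param pwm A `pwm` object.
#' @param p_threshold P-value threshold.
#' @param non_overlapping Resolve overlapping hits greedily by score.
#' @return An object of class `count_distribution`: list with `counts`
#'   (named integer vector) and `histogram` (table over 0..max).
#' @export
count_motifs <- function(peaks, sequences, pwm, p_threshold = 1e-4,
                         non_overlapping = FALSE) {
  validate_peakset(peaks)
  sequences <- vapply(as.list(sequences), as.character, "")
  nm <- S4Vectors::mcols(peaks)$name
  missing <- setdiff(nm, names(sequences))
  if (length(missing)) stop("no sequence for peak ", missing[1L])
  dists <- list(fwd = pwm_score_distribution(pwm),
                rev = pwm_score_distribution(pwm_revcomp(pwm)))
  counts <- vapply(nm, function(p) {
    hits <- scan_sequence(sequences[[p]], pwm, p_threshold,
                          dists = dists)
    if (nrow(hits) && non_overlapping) {
      hits <- hits[order(-hits$score), ]
      taken <- logical(0)
      keep <- logical(nrow(hits))
      used <- integer(0)
      for (i in seq_len(nrow(hits))) {
        span <- hits$offset[i] + seq_len(pwm$length) - 1L
        if (!any(span %in% used)) {
          keep[i] <- TRUE
          used <- c(used, span)
        }
      }
      hits <- hits[keep, ]
    }
    nrow(hits)
  }, integer(1))
  count_distribution(counts)
}

#' @rdname count_motifs
#' @param counts Named non-negative integer vector of per-peak counts.
#' @export
count_distribution <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  hist <- tabulate(counts + 1L, nbins = max(counts, 0) + 1L)
  names(hist) <- as.character(seq_along(hist) - 1L)
  structure(list(counts = counts, histogram = hist),
            class = "count_distribution")
}

#' Size-matched subsampled count histogram
#'
#' Draws `n_rep` subsamples of `n_target` peaks without replacement and
#' averages the per-draw count histograms, the standard correction for
#' comparing motif-count distributions between peak sets of unequal
#' size. The averaged histogram has total mass `n_target`.
#'
#' @param dist A `count_distribution`.
#' @param n_target Subsample size (at most the population size).
#' @param n_rep Number of draws (default 1000).
#' @param seed RNG seed.
#' @return Named numeric vector: average number of peaks per motif-count
#'   bin (bins 0..max observed count).
#' @export
subsample_matched <- function(dist, n_target, n_rep = 1000, seed = 1) {
  stopifnot(inherits(dist, "count_distribution"))
  counts <- dist$counts
  if (n_target > length(counts)) stop("n_target exceeds population size")
  if (n_rep < 1) stop("n_rep must be >= 1")
  nb <- max(counts) + 1L
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  acc <- numeric(nb)
  for (r in seq_len(n_rep)) {
    draw <- sample(counts, n_target, replace = FALSE)
    acc <- acc + tabulate(draw + 1L, nbins = nb)
  }
  stats::setNames(acc / n_rep, as.character(0:(nb - 1L)))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum difference between the two empirical CDFs; the
#' two-sided p-value uses the asymptotic Kolmogorov distribution with
#' effective sample size `n_a * n_b / (n_a + n_b)`. Suitable for tied,
#' discrete data such as motif counts (ties make the p-value
#' conservative, as with any KS test on counts).
#'
#' @param a,b Numeric samples.
#' @return List with `D` and `p_value`.
#' @export
ks_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  support <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(support)
  Fb <- stats::ecdf(b)(support)
  D <- max(abs(Fa - Fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  t <- sqrt(n_eff) * D
  if (t < 1e-12) {
    p <- 1
  } else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
    p <- min(max(p, 0), 1)
  }
  list(D = D, p_value = p)
}

#' Motif co-occurrence at anchor-motif peaks
#'
#' Restricted to peaks carrying at least one anchor motif, reports for
#' each other motif the percentage of those peaks that also carry it.
#'
#' @param anchor_counts Named per-peak counts for the anchor motif.
#' @param other Named list of per-peak count vectors (one per motif),
#'   aligned to the same peaks.
#' @return Named numeric vector of percentages.
#' @export
co_occurrence <- function(anchor_counts, other) {
  anchor <- anchor_counts >= 1
  if (!any(anchor)) stop("no peaks contain the anchor motif")
  vapply(other, function(cnt) {
    if (length(cnt) != length(anchor_counts)) {
      stop("count vectors must align to the same peaks")
    }
    100 * sum(anchor & cnt >= 1) / sum(anchor)
  }, numeric(1))
}

#' Extract peak sequences from chromosome sequences
#'
#' @param peaks A peak set.
#' @param chrom_seqs Named `DNAStringSet` (or character vector) of
#'   chromosome sequences.
#' @return Named character vector of peak sequences.
#' @export
peak_sequences <- function(peaks, chrom_seqs) {
  validate_peakset(peaks)
  seqs <- vapply(as.list(chrom_seqs), as.character, "")
  chr <- as.character(GenomicRanges::seqnames(peaks))
  bad <- setdiff(unique(chr), names(seqs))
  if (length(bad)) stop("no sequence for chromosome ", bad[1L])
  out <- substring(seqs[chr], GenomicRanges::start(peaks),
                   GenomicRanges::end(peaks))
  stats::setNames(out, S4Vectors::mcols(peaks)$name)
}
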