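# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (quadratic loops, per-base
# counting, exhaustive enumeration) and share no code with the package
# internals they check.

toy_genome <- function(sizes = c(chrA = 10000, chrB = 8000)) {
  Genome(sizes)
}

random_peakset <- function(genome, n, label = "peaks",
                           max_width = 300) {
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)
  chrom <- sample(chroms, n, replace = TRUE)
  width <- sample(20:max_width, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(lens[[chrom[i]]] - width[i], 1L) - 1L
  }, numeric(1))
  PeakSet(genome, chrom, start, start + width,
          name = sprintf("%s_%04d", label, seq_len(n)), label = label)
}

# quadratic all-pairs overlap oracle on BED coordinates
brute_overlap_flags <- function(query, subject, min_overlap = 1L) {
  qc <- as.character(GenomicRanges::seqnames(query))
  qs <- GenomicRanges::start(query) - 1L
  qe <- GenomicRanges::end(query)
  sc <- as.character(GenomicRanges::seqnames(subject))
  ss <- GenomicRanges::start(subject) - 1L
  se <- GenomicRanges::end(subject)
  vapply(seq_along(query), function(i) {
    any(vapply(seq_along(subject), function(j) {
      qc[i] == sc[j] &&
        min(qe[i], se[j]) - max(qs[i], ss[j]) >= min_overlap
    }, logical(1)))
  }, logical(1))
}

# union-find merge oracle over pairwise gap tests
brute_merge <- function(peaks, max_gap = 0) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  s <- GenomicRanges::start(peaks) - 1L
  e <- GenomicRanges::end(peaks)
  n <- length(s)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] &&
        max(s[i], s[j]) - min(e[i], e[j]) <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(idx) {
    data.frame(chrom = chrom[idx[1]], start = min(s[idx]),
               end = max(e[idx]), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# naive per-window PWM scan: score every window on both strands with
# plain arithmetic, threshold from the package DP (the DP itself is
# checked against exhaustive word enumeration elsewhere)
brute_scan <- function(seq, pwm, p_threshold = 1e-4,
                       granularity = 1e-3) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
          collapse = "")
  }
  lo <- pwm_log_odds(pwm)
  ints <- round(lo / granularity)
  score_window <- function(w) {
    ch <- strsplit(w, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_integer_)
    idx <- match(ch, c("A", "C", "G", "T"))
    sum(ints[cbind(idx, seq_along(idx))])
  }
  dist <- pwm_score_distribution(pwm, granularity)
  L <- pwm$length
  n <- nchar(seq)
  hits <- list()
  for (off in 0:(n - L)) {
    w <- substr(seq, off + 1, off + L)
    for (strand in c("+", "-")) {
      ww <- if (strand == "+") w else revcomp(w)
      sc <- score_window(ww)
      if (is.na(sc)) next
      p <- sum(dist$prob[dist$grid >= sc])
      if (p <= p_threshold) {
        hits[[length(hits) + 1L]] <- data.frame(
          offset = off, strand = strand, int_score = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(offset = integer(), strand = character(),
                      int_score = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# exhaustive null distribution: every word of length L weighted by the
# background model
brute_null_tail <- function(pwm, granularity = 1e-3) {
  L <- pwm$length
  ints <- round(pwm_log_odds(pwm) / granularity)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- integer(nrow(words))
  pr <- numeric(nrow(words))
  bg <- pwm$background
  sc <- rowSums(matrix(ints[cbind(as.vector(words),
                                  rep(seq_len(L), each = nrow(words)))],
                       nrow = nrow(words)))
  pr <- apply(words, 1, function(w) prod(bg[w]))
  list(scores = sc, probs = pr)
}

brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}

random_pwm <- function(L, alpha = 0.5, motif_id = "rand") {
  probs <- matrix(0, 4, L)
  for (j in seq_len(L)) {
    p <- stats::rgamma(4, alpha)
    probs[, j] <- p / sum(p)
  }
  PWM(motif_id, probs)
}

# adjusted Rand index between two labelings (contingency-table form)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
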