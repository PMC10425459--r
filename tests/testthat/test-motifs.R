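test_that("MEME minimal format reads and writes PWMs with background handling", {
  f <- withr::local_tempfile()
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF toy",
               "letter-probability matrix: alength= 4 w= 2",
               "0.7 0.1 0.1 0.1",
               "0.1 0.1 0.1 0.7"), f)
  pwms <- read_meme(f)
  expect_length(pwms, 1L)
  expect_equal(pwms$toy$length, 2L)
  # no background lines -> uniform default
  expect_equal(unname(pwms$toy$background), rep(0.25, 4))
  # explicit background is honoured
  writeLines(c("MEME version 4", "",
               "Background letter frequencies",
               "A 0.3 C 0.2 G 0.2 T 0.3", "",
               "MOTIF toy2",
               "letter-probability matrix: alength= 4 w= 1",
               "0.25 0.25 0.25 0.25"), f)
  p2 <- read_meme(f)
  expect_equal(unname(p2$toy2$background), c(0.3, 0.2, 0.2, 0.3))
  # bad rows error
  writeLines(c("MOTIF bad",
               "letter-probability matrix: alength= 4 w= 1",
               "0.9 0.9 0.9 0.9"), f)
  expect_error(read_meme(f), "sum")
  # round trip preserves probabilities
  pwm <- sim_pwm()
  write_meme(pwm, f)
  back <- read_meme(f, pseudocount = 0)[[1]]
  expect_equal(back$probs, pwm$probs, tolerance = 1e-5)
})

test_that("scanning finds sharp consensus sites and ignores uninformative motifs", {
  pwm <- sim_pwm()
  hits <- scan_sequence(pwm_consensus(pwm), pwm)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$offset[1], 0L)
  expect_equal(hits$strand[1], "+")
  # motif identical to background scores 0 everywhere: no hits at 1e-4
  flat <- PWM("flat", matrix(0.25, 4, 6), pseudocount = 0)
  expect_equal(nrow(scan_sequence(strrep("A", 30), flat, 1e-4)), 0L)
  # windows containing N are skipped
  seqN <- paste0("AA", substr(pwm_consensus(pwm), 1, 9), "N")
  expect_equal(nrow(scan_sequence(seqN, pwm)), 0L)
  expect_error(scan_sequence("ACGTX", pwm), "invalid")
  # motif longer than the sequence yields no hits
  expect_equal(nrow(scan_sequence("ACG", pwm)), 0L)
})

test_that("hit sets equal exhaustive window enumeration on random inputs", {
  set.seed(17)
  for (rep in 1:10) {
    L <- sample(3:6, 1)
    pwm <- random_pwm(L)
    seq <- random_dna_str(40)
    got <- scan_sequence(seq, pwm, p_threshold = 0.01)
    want <- brute_scan(seq, pwm, p_threshold = 0.01)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(round(got$score / 1e-3), want$int_score)
  }
})

test_that("reverse-complement scanning mirrors hits with flipped strands", {
  set.seed(19)
  pwm <- random_pwm(5)
  seq <- random_dna_str(60)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  h1 <- scan_sequence(seq, pwm, p_threshold = 0.02)
  h2 <- scan_sequence(rc, pwm, p_threshold = 0.02)
  expect_equal(nrow(h1), nrow(h2))
  # offsets mirror: offset' = len - L - offset, strands flip
  mirrored <- data.frame(offset = nchar(seq) - pwm$length - h2$offset,
                         strand = ifelse(h2$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$offset, d$strand))
  expect_equal(key(h1[, c("offset", "strand")]), key(mirrored))
})

test_that("the DP null distribution matches exhaustive word enumeration", {
  set.seed(29)
  for (L in c(3, 5, 8)) {
    pwm <- random_pwm(L)
    dist <- pwm_score_distribution(pwm)
    brute <- brute_null_tail(pwm)
    # total mass 1 and identical tail probabilities on the brute support
    expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
    for (q in stats::quantile(brute$scores, c(0.1, 0.5, 0.9, 1))) {
      expect_equal(sum(dist$prob[dist$grid >= q]),
                   sum(brute$probs[brute$scores >= q]),
                   tolerance = 1e-12)
    }
    # tail p is non-increasing in score
    expect_true(all(diff(dist$tail) <= 1e-15))
    # threshold from DP equals brute-force threshold
    thr <- pwm_score_threshold(pwm, 1e-3)
    cand <- sort(unique(brute$scores))
    tails <- vapply(cand, function(s) sum(brute$probs[brute$scores >= s]),
                    numeric(1))
    ok <- cand[tails <= 1e-3]
    grid_ok <- dist$grid[dist$tail <= 1e-3]
    if (length(grid_ok)) {
      expect_equal(as.numeric(thr), grid_ok[1])
      # no achievable word score below the DP threshold is significant
      if (length(ok)) expect_gte(min(ok), as.numeric(thr))
    } else {
      expect_equal(as.numeric(thr), Inf)
    }
  }
})

test_that("count_motifs counts planted copies exactly and errors on missing sequences", {
  gn <- Genome(c(chrA = 10000))
  pwm <- sim_pwm()
  cons <- pwm_consensus(pwm)
  peaks <- PeakSet(gn, rep("chrA", 3), c(0, 1000, 2000),
                   c(60, 1060, 2060), name = c("p1", "p2", "p3"))
  seqs <- c(
    p1 = strrep("C", 60),
    p2 = paste0(cons, "CCCC", cons, "CCCC", cons,
                strrep("C", 60 - 3 * nchar(cons) - 8)),
    p3 = paste0("CC", cons, strrep("C", 48))
  )
  cd <- count_motifs(peaks, seqs, pwm)
  expect_equal(unname(cd$counts), c(0L, 3L, 1L))
  expect_equal(sum(cd$histogram), 3)
  expect_error(count_motifs(peaks, seqs[1:2], pwm), "p3")
})

test_that("matched subsampling reproduces the full histogram and the hypergeometric mean", {
  counts <- c(rep(0L, 40), rep(1L, 30), rep(2L, 20), rep(5L, 10))
  names(counts) <- sprintf("p%03d", seq_along(counts))
  cd <- count_distribution(counts)
  # n_target = population size -> exact histogram every draw
  full <- subsample_matched(cd, 100, n_rep = 5, seed = 3)
  expect_equal(unname(full[c("0", "1", "2", "5")]), c(40, 30, 20, 10))
  # determinism
  expect_identical(subsample_matched(cd, 30, 50, seed = 8),
                   subsample_matched(cd, 30, 50, seed = 8))
  # hypergeometric expectation: E[bin b] = n_target * N_b / N
  avg <- subsample_matched(cd, 30, n_rep = 2000, seed = 4)
  expect_equal(sum(avg), 30, tolerance = 1e-9)
  for (b in c("0", "1", "2", "5")) {
    Nb <- sum(counts == as.integer(b))
    expected <- 30 * Nb / 100
    se <- sqrt(30 * (Nb / 100) * (1 - Nb / 100)) / sqrt(2000)
    expect_lt(abs(avg[[b]] - expected), 3 * se + 1e-9)
  }
  expect_error(subsample_matched(cd, 200, 10, 1), "exceeds")
})

test_that("KS statistic equals the ECDF sup-difference oracle with sane p-values", {
  expect_equal(ks_compare(1:5, 1:5)$D, 0)
  expect_equal(ks_compare(1:5, 1:5)$p_value, 1)
  expect_equal(ks_compare(rep(0, 10), rep(10, 12))$D, 1)
  r <- ks_compare(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$D, brute_ks_D(c(1, 2, 3), c(2, 3, 4)))
  set.seed(37)
  for (rep in 1:20) {
    a <- rpois(sample(5:60, 1), sample(1:4, 1))
    b <- rpois(sample(5:60, 1), sample(1:4, 1))
    got <- ks_compare(a, b)
    expect_equal(got$D, brute_ks_D(a, b))
    expect_gte(got$p_value, 0)
    expect_lte(got$p_value, 1)
  }
  # agrees with the classical asymptotic test on tie-free data
  set.seed(41)
  a <- rnorm(80); b <- rnorm(70, 0.5)
  got <- ks_compare(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(got$D, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  expect_error(ks_compare(numeric(), 1:3), "empty")
})

test_that("co-occurrence percentages follow the planted pattern", {
  anchor <- c(p1 = 2L, p2 = 0L, p3 = 1L, p4 = 3L, p5 = 0L)
  everywhere <- c(p1 = 1L, p2 = 1L, p3 = 2L, p4 = 1L, p5 = 1L)
  nowhere <- c(p1 = 0L, p2 = 0L, p3 = 0L, p4 = 0L, p5 = 0L)
  partial <- c(p1 = 1L, p2 = 5L, p3 = 0L, p4 = 2L, p5 = 0L)
  out <- co_occurrence(anchor, list(A = everywhere, B = nowhere,
                                    C = partial))
  expect_equal(unname(out["A"]), 100)
  expect_equal(unname(out["B"]), 0)
  # anchor peaks: p1, p3, p4; C present in p1, p4 -> 2/3
  expect_equal(unname(out["C"]), 100 * 2 / 3)
  expect_error(co_occurrence(nowhere, list(A = everywhere)), "anchor")
  expect_error(co_occurrence(anchor, list(A = everywhere[1:3])), "align")
})
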