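make_track <- function(genome, chrom, start, end, value) {
  GenomicRanges::sort(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start + 1L, end), score = value,
    seqinfo = genome))
}

test_that("build_matrix bins summit-centred windows as base-wise means", {
  gn <- Genome(c(chrA = 10000))
  p <- PeakSet(gn, "chrA", 900, 1100, summit = 100)  # summit abs 1000
  # constant track over everything the window can see
  tr <- make_track(gn, "chrA", 0, 10000, 3.5)
  m <- build_matrix(tr, p, flank = 100, binsize = 20)
  expect_equal(ncol(m), 10L)
  expect_true(all(abs(m - 3.5) < 1e-12))
  # methods-default shape: flank 2000, binsize 50 -> 80 bins
  m80 <- build_matrix(tr, p, flank = 2000, binsize = 50)
  expect_equal(ncol(m80), 80L)

  # single covered interval vs per-base oracle
  tr2 <- make_track(gn, "chrA", 990, 1010, 4)
  m2 <- build_matrix(tr2, p, flank = 100, binsize = 20)
  base_vals <- numeric(200)                  # window [900, 1100)
  base_vals[(990 - 900 + 1):(1010 - 900)] <- 4
  oracle <- vapply(seq_len(10), function(j) {
    mean(base_vals[((j - 1) * 20 + 1):(j * 20)])
  }, numeric(1))
  expect_equal(as.numeric(m2[1, ]), oracle)
  # binsize 1 equals base-wise values exactly
  m1 <- build_matrix(tr2, p, flank = 100, binsize = 1)
  expect_equal(as.numeric(m1[1, ]), base_vals)
})

test_that("windows beyond chromosome ends are zero-padded", {
  gn <- Genome(c(chrA = 1000))
  p <- PeakSet(gn, "chrA", 0, 100, summit = 10)  # summit abs 10
  tr <- make_track(gn, "chrA", 0, 1000, 2)
  m <- build_matrix(tr, p, flank = 100, binsize = 10)
  # first 90 bp of the window fall before the chromosome start
  expect_equal(as.numeric(m[1, 1:9]), rep(0, 9))
  expect_equal(as.numeric(m[1, 11:20]), rep(2, 10))
})

test_that("build_matrix requires compatible binning", {
  gn <- Genome(c(chrA = 1000))
  p <- PeakSet(gn, "chrA", 100, 200)
  tr <- make_track(gn, "chrA", 0, 1000, 1)
  expect_error(build_matrix(tr, p, flank = 100, binsize = 30), "divide")
})

test_that("k-means recovers planted tiers, orders clusters by mean, and is reproducible", {
  sim <- simulate_signal_matrix(n_per_tier = c(40, 40, 40), seed = 5)
  cl <- kmeans_cluster(sim$matrix, k = 3, seed = 99)
  expect_equal(adjusted_rand_index(cl$labels, sim$tier), 1.0)
  # cluster 1 is the strongest tier
  expect_true(all(cl$labels[sim$tier == 1] == 1))
  expect_true(all(diff(cl$cluster_means) < 0))
  # reproducibility under a fixed seed
  cl2 <- kmeans_cluster(sim$matrix, k = 3, seed = 99)
  expect_identical(cl$labels, cl2$labels)
  # k = 1 trivially labels everything 1; k > n errors
  expect_true(all(kmeans_cluster(sim$matrix, 1, seed = 1)$labels == 1))
  expect_error(kmeans_cluster(sim$matrix[1:2, ], 5, seed = 1), "exceeds")
  # duplicated rows land in the same cluster
  dup <- sim$matrix[c(1, 1, 50, 50, 100, 100), ]
  rownames(dup) <- paste0("r", 1:6)
  cld <- kmeans_cluster(dup, 3, seed = 1)
  expect_equal(cld$labels[c(1, 3, 5)], cld$labels[c(2, 4, 6)],
               ignore_attr = TRUE)
})

test_that("bookmarked-per-cluster fractions match a hand-built split", {
  gn <- Genome(c(chrC = 100000))
  centres <- seq(3000, by = 3000, length.out = 30)
  async <- PeakSet(gn, rep("chrC", 30), centres - 100, centres + 100,
                   name = sprintf("p%02d", 1:30), label = "async")
  # bookmark peaks 1:10 (which we will force into cluster 1)
  mit <- PeakSet(gn, rep("chrC", 10), centres[1:10] - 80,
                 centres[1:10] + 80, label = "mitotic")
  cls <- classify_peaks(async, mit)
  m <- matrix(rep(rep(c(10, 3, 0.5), each = 10), 8), ncol = 8)
  rownames(m) <- sprintf("p%02d", 1:30)
  cl <- kmeans_cluster(m, 3, seed = 1)
  cf <- cluster_overlap_fractions(cls, cl)
  expect_equal(cf$pct_of_bookmarked, c(100, 0, 0))
  expect_equal(cf$pct_bookmarked_in_cluster, c(100, 0, 0))
  # zero bookmarked peaks is an error
  cls0 <- classify_peaks(async, mit[0])
  expect_error(cluster_overlap_fractions(cls0, cl), "no bookmarked")
})

test_that("mean_profile equals naive column averaging", {
  set.seed(31)
  m <- matrix(rnorm(10 * 8), nrow = 10,
              dimnames = list(sprintf("f%d", 1:10), NULL))
  class(m) <- c("signal_matrix", class(m))
  expect_equal(mean_profile(m, "f3"), unclass(m)["f3", ],
               ignore_attr = TRUE)
  two <- mean_profile(m, c("f1", "f2"))
  expect_equal(two, (unclass(m)["f1", ] + unclass(m)["f2", ]) / 2)
  sub <- sprintf("f%d", c(2, 5, 9))
  naive <- numeric(8)
  for (j in 1:8) naive[j] <- mean(unclass(m)[sub, j])
  expect_equal(unname(mean_profile(m, sub)), naive)
  expect_error(mean_profile(m, character()), "empty")
  expect_error(mean_profile(m, "nope"), "unknown")
})

test_that("difference score is antisymmetric, linear in offsets, and matches the loop oracle", {
  set.seed(13)
  m <- matrix(rnorm(6 * 8), nrow = 6,
              dimnames = list(sprintf("f%d", 1:6), NULL))
  class(m) <- c("signal_matrix", class(m))
  A <- c("f1", "f2"); B <- c("f4", "f5", "f6")
  s <- signal_difference_score(m, A, B)
  expect_equal(as.numeric(signal_difference_score(m, B, A)),
               -as.numeric(s))
  expect_equal(as.numeric(signal_difference_score(m, A, A)), 0)
  # constant offset c over n bins scores n*c
  m2 <- m
  m2[A, ] <- matrix(rep(unclass(m)["f4", ], each = 2), nrow = 2) + 0.7
  m2[B[1], ] <- unclass(m)["f4", ]
  m2[B[2], ] <- unclass(m)["f4", ]
  m2[B[3], ] <- unclass(m)["f4", ]
  expect_equal(as.numeric(signal_difference_score(m2, A, B)), 8 * 0.7)
  # double-loop oracle
  oracle <- 0
  for (j in 1:8) {
    oracle <- oracle + mean(unclass(m)[A, j]) - mean(unclass(m)[B, j])
  }
  expect_equal(as.numeric(s), oracle)
  # absolute mode
  expect_gte(as.numeric(signal_difference_score(m, A, B, absolute = TRUE)),
             abs(as.numeric(s)))
})
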