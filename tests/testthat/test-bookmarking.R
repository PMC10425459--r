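test_that("classify_peaks handles identical, disjoint and asymmetric sets", {
  gn <- toy_genome()
  a <- PeakSet(gn, "chrA", 100, 200, label = "async")
  m <- PeakSet(gn, "chrA", 100, 200, label = "mitotic")
  cls <- classify_peaks(a, m)
  expect_equal(unname(cls$counts),
               c(1L, 0L, 1L, 0L))

  m2 <- PeakSet(gn, "chrA", 300, 400)
  cls2 <- classify_peaks(a, m2)
  expect_equal(unname(cls2$counts), c(0L, 1L, 0L, 1L))

  # one mitotic peak spanning two async peaks counts once on the
  # mitotic side, both async peaks count as bookmarked
  a3 <- PeakSet(toy_genome(c(chr1 = 1000, chr2 = 1000, chr3 = 1000)),
                c("chr1", "chr1", "chr2"), c(100, 150, 0),
                c(200, 260, 50))
  m3 <- PeakSet(toy_genome(c(chr1 = 1000, chr2 = 1000, chr3 = 1000)),
                c("chr1", "chr3"), c(190, 5), c(250, 10))
  cls3 <- classify_peaks(a3, m3, min_overlap = 1)
  expect_equal(unname(cls3$counts), c(1L, 1L, 2L, 1L))
})

test_that("classification errors on mismatched genomes and partitions exactly", {
  a <- PeakSet(toy_genome(), "chrA", 100, 200)
  m <- PeakSet(toy_genome(c(chrA = 5000)), "chrA", 100, 200)
  expect_error(classify_peaks(a, m), "different genomes")

  set.seed(11)
  gn <- toy_genome()
  for (rep in 1:5) {
    a <- random_peakset(gn, 60, "a")
    m <- random_peakset(gn, 40, "m")
    cls <- classify_peaks(a, m)
    expect_equal(length(cls$bookmarked_mitotic) +
                   length(cls$mitotic_unique), length(m))
    expect_equal(length(cls$bookmarked_async) +
                   length(cls$async_only), length(a))
    # disjointness by name
    expect_length(intersect(S4Vectors::mcols(cls$bookmarked_async)$name,
                            S4Vectors::mcols(cls$async_only)$name), 0L)
  }
})

test_that("bookmarked counts agree with the quadratic oracle and are monotone in min_overlap", {
  set.seed(23)
  gn <- toy_genome()
  prev <- Inf
  a <- random_peakset(gn, 80, "a")
  m <- random_peakset(gn, 60, "m")
  for (mo in c(1, 20, 100)) {
    cls <- classify_peaks(a, m, min_overlap = mo)
    want <- sum(brute_overlap_flags(m, a, mo))
    expect_equal(unname(cls$counts[["bookmarked_mitotic"]]), want)
    expect_lte(cls$counts[["bookmarked_mitotic"]], prev)
    prev <- cls$counts[["bookmarked_mitotic"]]
  }
})

test_that("overlap_fraction computes percentages and rejects empty queries", {
  gn <- toy_genome()
  a <- PeakSet(gn, c("chrA", "chrA", "chrB"), c(0, 300, 100),
               c(100, 400, 200))
  expect_equal(overlap_fraction(a, a), 100)
  b <- PeakSet(gn, "chrB", 5000, 5100)
  expect_equal(overlap_fraction(a, b), 0)
  c2 <- PeakSet(gn, c("chrA", "chrA"), c(50, 390), c(60, 395))
  expect_equal(overlap_fraction(a, c2), 100 * 2 / 3, tolerance = 1e-12)
  expect_error(overlap_fraction(a[0], b), "empty query")
})

test_that("assign_genes picks the nearest TSS with promoter categories and distance cap", {
  gn <- toy_genome()
  genes <- data.frame(gene_id = c("g1", "g2"),
                      chrom = "chrA", strand = c("+", "+"),
                      tss = c(500, 2000), stringsAsFactors = FALSE)
  # summit exactly at a TSS
  p <- PeakSet(gn, "chrA", 400, 601, summit = 100)  # summit abs 500
  asn <- assign_genes(p, genes)
  expect_equal(asn$gene_id, "g1")
  expect_equal(asn$distance, 0)
  expect_equal(asn$category, "promoter")
  # summit 1200: distance 700 to g1 beats 800 to g2
  p2 <- PeakSet(gn, "chrA", 1100, 1301, summit = 100)
  asn2 <- assign_genes(p2, genes)
  expect_equal(asn2$gene_id, "g1")
  expect_equal(asn2$distance, 700)
  expect_equal(asn2$category, "distal")
  # farther than max_distance: unassigned
  asn3 <- assign_genes(p2, genes, max_distance = 500)
  expect_equal(asn3$category, "unassigned")
  expect_true(is.na(asn3$gene_id))
  # strand awareness: a - strand gene's promoter window flips
  genes_m <- data.frame(gene_id = "gm", chrom = "chrA", strand = "-",
                        tss = 5000, stringsAsFactors = FALSE)
  up <- PeakSet(gn, "chrA", 5200, 5401, summit = 100)  # 300 bp 5' of TSS
  expect_equal(assign_genes(up, genes_m)$category, "promoter")
  down <- PeakSet(gn, "chrA", 4200, 4401, summit = 100) # 700 bp 3' of TSS
  expect_equal(assign_genes(down, genes_m)$category, "distal")
  # ties break to the lexicographically smaller gene_id
  tie <- data.frame(gene_id = c("gB", "gA"), chrom = "chrA",
                    strand = "+", tss = c(900, 1100),
                    stringsAsFactors = FALSE)
  pt <- PeakSet(gn, "chrA", 900, 1101, summit = 100)   # summit 1000
  expect_equal(assign_genes(pt, tie)$gene_id, "gA")
  # empty annotation warns, all unassigned
  expect_warning(asn4 <- assign_genes(p, genes[0, ]), "empty")
  expect_equal(asn4$category, "unassigned")
})

test_that("gene bookmark fraction recovers a hand-planted 6-of-40 design", {
  # 40 genes, one async peak each, 6 carrying a mitotic partner -> 15%
  gn <- Genome(c(chrT = 400000))
  centres <- seq(5000, by = 5000, length.out = 40)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40), chrom = "chrT",
                      strand = "+", tss = centres,
                      stringsAsFactors = FALSE)
  async <- PeakSet(gn, rep("chrT", 40), centres - 150, centres + 150,
                   name = sprintf("a%02d", 1:40), label = "async")
  book <- c(3, 9, 14, 22, 30, 38)
  mit <- PeakSet(gn, rep("chrT", 6), centres[book] - 100,
                 centres[book] + 100,
                 name = sprintf("m%02d", 1:6), label = "mitotic")
  cls <- classify_peaks(async, mit)
  gbf <- gene_bookmark_fraction(cls, genes)
  expect_equal(gbf$bookmarked_fraction, 15)
  expect_equal(gbf$n_async_genes, 40)
  expect_equal(gbf$n_bookmarked_genes, 6)
  expect_true(all(gbf$table$is_bookmarked[gbf$table$gene_id %in%
                                            sprintf("g%02d", book)]))
  # all-bookmarked and no-mitotic edge cases
  cls_all <- classify_peaks(async, async)
  expect_equal(gene_bookmark_fraction(cls_all, genes)$bookmarked_fraction,
               100)
  cls_none <- classify_peaks(async, mit[0])
  expect_equal(gene_bookmark_fraction(cls_none, genes)$bookmarked_fraction,
               0)
})

test_that("DE-gene association counts bookmarked genes with each motif", {
  tab <- data.frame(gene_id = sprintf("g%d", 1:10),
                    has_async_peak = TRUE,
                    has_mitotic_peak = rep(c(TRUE, FALSE), 5),
                    is_bookmarked = rep(c(TRUE, FALSE), 5),
                    stringsAsFactors = FALSE)
  mp <- matrix(c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)), ncol = 2,
               dimnames = list(tab$gene_id, c("MOT_A", "MOT_B")))
  de <- data.frame(gene_id = sprintf("g%d", 1:6),
                   direction = rep(c("up", "down"), 3),
                   stringsAsFactors = FALSE)
  out <- de_gene_association(de, tab, mp)
  # manual tally: up DE = g1,g3,g5 (all bookmarked, odd), down = g2,g4,g6
  # (none bookmarked); MOT_B present on odd genes only
  expect_equal(out$count[out$direction == "up" & out$motif == "MOT_A"], 3L)
  expect_equal(out$count[out$direction == "up" & out$motif == "MOT_B"], 3L)
  expect_equal(out$count[out$direction == "down" & out$motif == "MOT_A"], 0L)
  # empty DE list gives zeros
  out0 <- de_gene_association(de[0, ], tab, mp)
  expect_true(all(out0$count == 0))
  # unknown ids are warned and ignored
  de_bad <- rbind(de, data.frame(gene_id = "gX", direction = "up"))
  expect_warning(out2 <- de_gene_association(de_bad, tab, mp), "ignored")
  expect_equal(out2$count, out$count)
})
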