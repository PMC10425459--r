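#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the statistical structure of a mitotic-bookmarking
#' ChIP-seq experiment at desk scale: two peak sets with a planted
#' overlap fraction, per-peak motif counts higher in bookmarked peaks,
#' three signal-intensity tiers with bookmarked peaks concentrated in
#' the strongest tier, a chromatin-state segmentation in which mitotic
#' peaks avoid weak/bivalent enhancer states, and synthetic mitotic
#' cells with a planted chromatin/cytoplasm enrichment.
#'
#' @param seed RNG seed driving every draw (sub-streams per component).
#' @param n_chroms,chrom_length Number and length (bp) of synthetic
#'   chromosomes.
#' @param n_async_peaks Number of asynchronous (interphase) peaks.
#' @param bookmark_fraction Fraction of asynchronous peaks with a
#'   mitotic partner overlapping at least 50 percent.
#' @param n_mitotic_unique Number of mitotic-only peaks.
#' @param peak_width Length-2 vector, min and max peak width in bp.
#' @param motif_lambda Named vector `c(bookmarked=, other=)`: Poisson
#'   mean of planted motif copies per peak, per class.
#' @param tier_means Three descending positive tier mean intensities.
#' @param tier_noise_sd Within-tier signal noise SD.
#' @param tier_probs_bookmarked,tier_probs_other Tier assignment
#'   probabilities (strong, mid, weak) for bookmarked and other peaks.
#' @param state_fractions Named vector of per-state genome fractions
#'   (sum at most 1).
#' @param state_preference Named vector of relative per-bp peak
#'   placement propensities per state.
#' @param state_avoidance Named vector: factor by which the bookmark
#'   probability is divided for peaks in each state (1 = no avoidance).
#' @param n_cells,cell_enrichment,cell_noise_sd Imaging component:
#'   number of synthetic cells, planted chromatin/cytoplasm ratio, and
#'   multiplicative Gaussian noise SD as a fraction of signal.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 3,
                       chrom_length = 1e6,
                       n_async_peaks = 500,
                       bookmark_fraction = 0.32,
                       n_mitotic_unique = 13,
                       peak_width = c(200, 600),
                       motif_lambda = c(bookmarked = 3, other = 1.5),
                       tier_means = c(10, 3, 0.5),
                       tier_noise_sd = 0.1,
                       tier_probs_bookmarked = c(0.70, 0.25, 0.05),
                       tier_probs_other = c(0.10, 0.45, 0.45),
                       state_fractions = c(TssA = 0.04, Enh = 0.10,
                                           EnhWk = 0.12, EnhBiv = 0.06,
                                           Tx = 0.28, Quies = 0.40),
                       state_preference = c(TssA = 20, Enh = 8,
                                            EnhWk = 8, EnhBiv = 8,
                                            Tx = 1, Quies = 0.05),
                       state_avoidance = c(TssA = 1, Enh = 1,
                                           EnhWk = 1.8, EnhBiv = 2.2,
                                           Tx = 1, Quies = 1),
                       n_cells = 50,
                       cell_enrichment = 2.5,
                       cell_noise_sd = 0.05) {
  cfg <- list(seed = seed, n_chroms = n_chroms,
              chrom_length = chrom_length,
              n_async_peaks = n_async_peaks,
              bookmark_fraction = bookmark_fraction,
              n_mitotic_unique = n_mitotic_unique,
              peak_width = peak_width, motif_lambda = motif_lambda,
              tier_means = tier_means, tier_noise_sd = tier_noise_sd,
              tier_probs_bookmarked = tier_probs_bookmarked,
              tier_probs_other = tier_probs_other,
              state_fractions = state_fractions,
              state_preference = state_preference,
              state_avoidance = state_avoidance,
              n_cells = n_cells, cell_enrichment = cell_enrichment,
              cell_noise_sd = cell_noise_sd)
  if (bookmark_fraction < 0 || bookmark_fraction > 1) {
    stop("bookmark_fraction must be in [0, 1]")
  }
  if (any(diff(tier_means) >= 0) || any(tier_means <= 0)) {
    stop("tier_means must be positive and strictly decreasing")
  }
  if (sum(state_fractions) > 1 + 1e-9) {
    stop("state fractions must sum to at most 1")
  }
  if (!setequal(names(state_fractions), names(state_preference)) ||
      !setequal(names(state_fractions), names(state_avoidance))) {
    stop("state vectors must share the same names")
  }
  class(cfg) <- "sim_config"
  cfg
}

# sub-stream seeding: independent seeds per component so that adding
# one component does not shift another's draws
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 10000L + k
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' A sharp GATA-like PWM used by the generator
#'
#' Ten positions around an AGATAA core with 0.94 probability on the
#' consensus base, giving planted consensus copies log-odds scores far
#' above the default scanning threshold.
#'
#' @param motif_id Identifier.
#' @return A `pwm` object.
#' @export
sim_pwm <- function(motif_id = "GATA_synth") {
  consensus <- c("C", "T", "A", "G", "A", "T", "A", "A", "G", "A")
  probs <- matrix(0.02, nrow = 4, ncol = length(consensus),
                  dimnames = list(DNA_ALPHABET, NULL))
  for (j in seq_along(consensus)) probs[consensus[j], j] <- 0.94
  PWM(motif_id, probs)
}

random_dna <- function(n, bg = rep(0.25, 4)) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE, prob = bg), collapse = "")
}

plant_motifs <- function(width, n_copies, motif, bg, p_threshold,
                         max_tries = 60) {
  L <- nchar(motif)
  pwm <- NULL
  for (try in seq_len(max_tries)) {
    seq <- random_dna(width, bg)
    if (n_copies > 0) {
      # non-overlapping offsets
      slots <- floor(width / (L + 2))
      if (n_copies > slots) n_copies <- slots
      pick <- sort(sample.int(slots, n_copies))
      for (s in pick) {
        at <- (s - 1L) * (L + 2L) + 1L
        substr(seq, at, at + L - 1L) <- motif
      }
    }
    attr(seq, "planted") <- n_copies
    return(seq)
  }
}

#' Generate a complete synthetic bookmarking dataset
#'
#' Produces every input the pipeline consumes, with a ground-truth
#' manifest: genome, gene table, asynchronous and mitotic peak sets,
#' per-peak sequences with planted motif copies, the planting PWM, a
#' signal track with three intensity tiers, and a chromatin-state
#' segmentation with planted per-state bookmark avoidance. Peaks are
#' placed on a slot grid that guarantees more than 1 kb spacing between
#' distinct sites, so the planted overlap structure is unambiguous:
#' exactly `round(bookmark_fraction * n_async_peaks)` asynchronous
#' peaks have a mitotic partner overlapping at least 50 percent.
#' Planted motif counts are verified by re-scanning and background
#' collisions resolved by re-draw, so per-peak counts are exact.
#' Identical configurations give identical outputs.
#'
#' @param cfg A `sim_config`.
#' @param dir Optional directory; when given, all inputs are written as
#'   plain-text files (chrom.sizes, narrowPeak, FASTA, MEME, bedGraph,
#'   BED segmentation, genes TSV, manifest JSON).
#' @return A list with elements `genome`, `genes`, `async`, `mitotic`,
#'   `sequences`, `pwm`, `track`, `segmentation`, `manifest` and (when
#'   `dir` is given) `paths`.
#' @export
generate_dataset <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  chroms <- sprintf("chrS%d", seq_len(cfg$n_chroms))
  genome <- Genome(stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                   chroms))
  states <- names(cfg$state_fractions)

  # --- segmentation: tile the genome in 2 kb blocks, sample states ---
  block <- 2000L
  seg <- with_seed(sub_seed(cfg$seed, 1L), {
    fr <- cfg$state_fractions
    rows <- lapply(chroms, function(ch) {
      nb <- cfg$chrom_length %/% block
      lab <- sample(states, nb, replace = TRUE, prob = fr / sum(fr))
      data.frame(chrom = ch, start = (seq_len(nb) - 1L) * block,
                 end = seq_len(nb) * block, state = lab,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  seg_gr <- segmentation(genome, seg$chrom, seg$start, seg$end, seg$state)

  # --- peak placement on a slot grid ---
  # pitch keeps neighbouring summits > 2.25 kb apart, so peaks never
  # collide by chance and +/- 2 kb signal windows stay uncontaminated
  slot <- max(cfg$peak_width) + 2400L
  slots <- do.call(rbind, lapply(chroms, function(ch) {
    ns <- cfg$chrom_length %/% slot
    data.frame(chrom = ch, centre = (seq_len(ns) - 1L) * slot + slot %/% 2L,
               stringsAsFactors = FALSE)
  }))
  n_total <- cfg$n_async_peaks + cfg$n_mitotic_unique
  if (n_total > nrow(slots)) {
    stop("infeasible packing: ", n_total, " peaks but only ",
         nrow(slots), " slots; enlarge the genome")
  }
  # state at each slot centre (block index)
  slot_state <- seg$state[match(
    paste(slots$chrom, (slots$centre %/% block) * block),
    paste(seg$chrom, seg$start))]
  slot_state[is.na(slot_state)] <- states[length(states)]

  placement <- with_seed(sub_seed(cfg$seed, 2L), {
    w <- cfg$state_preference[slot_state]
    pick <- sample.int(nrow(slots), n_total, prob = w)
    widths <- sample(seq(cfg$peak_width[1], cfg$peak_width[2]),
                     n_total, replace = TRUE)
    list(idx = pick, widths = widths)
  })
  pk <- slots[placement$idx, , drop = FALSE]
  pk$width <- placement$widths
  pk$start <- pk$centre - pk$width %/% 2L
  pk$end <- pk$start + pk$width
  pk$state <- slot_state[placement$idx]
  is_async <- seq_len(n_total) <= cfg$n_async_peaks
  async_pk <- pk[is_async, , drop = FALSE]
  unique_pk <- pk[!is_async, , drop = FALSE]

  # --- bookmark selection with planted per-state avoidance ---
  n_book <- round(cfg$bookmark_fraction * cfg$n_async_peaks)
  book_sel <- with_seed(sub_seed(cfg$seed, 3L), {
    w <- 1 / cfg$state_avoidance[async_pk$state]
    sort(sample.int(cfg$n_async_peaks, n_book, prob = w))
  })
  async_names <- sprintf("async_%04d", seq_len(cfg$n_async_peaks))
  bookmarked_async_names <- async_names[book_sel]

  # --- mitotic partners: shifted copies with >= 50 percent overlap ---
  mit <- with_seed(sub_seed(cfg$seed, 4L), {
    b <- async_pk[book_sel, , drop = FALSE]
    shift <- round(stats::runif(nrow(b), -0.25, 0.25) * b$width)
    b$start <- b$start + shift
    b$end <- b$start + b$width
    b
  })
  mit_names <- c(sprintf("mit_%04d", seq_len(n_book)),
                 sprintf("mitu_%04d", seq_len(cfg$n_mitotic_unique)))
  mit_all <- rbind(mit, unique_pk)

  async <- PeakSet(genome, async_pk$chrom, async_pk$start, async_pk$end,
                   name = async_names, label = "async")
  mitotic <- PeakSet(genome, mit_all$chrom, mit_all$start, mit_all$end,
                     name = mit_names, label = "mitotic")

  # --- genes: one TSS per asynchronous peak, near its summit ---
  genes <- with_seed(sub_seed(cfg$seed, 5L), {
    off <- sample(-200:200, cfg$n_async_peaks, replace = TRUE)
    data.frame(gene_id = sprintf("gene_%04d", seq_len(cfg$n_async_peaks)),
               chrom = async_pk$chrom,
               strand = sample(c("+", "-"), cfg$n_async_peaks,
                               replace = TRUE),
               tss = pmax(0, async_pk$centre + off),
               stringsAsFactors = FALSE)
  })

  # --- sequences with planted motif copies ---
  pwm <- sim_pwm()
  consensus <- pwm_consensus(pwm)
  bg <- rep(0.25, 4)
  is_book_class <- c(seq_len(cfg$n_async_peaks) %in% book_sel,
                     c(rep(TRUE, n_book),
                       rep(FALSE, cfg$n_mitotic_unique)))
  all_names <- c(async_names, mit_names)
  all_widths <- c(async_pk$width, mit_all$width)
  scan_dists <- list(fwd = pwm_score_distribution(pwm),
                     rev = pwm_score_distribution(pwm_revcomp(pwm)))
  seq_truth <- with_seed(sub_seed(cfg$seed, 6L), {
    lam <- ifelse(is_book_class, cfg$motif_lambda[["bookmarked"]],
                  cfg$motif_lambda[["other"]])
    n_copies <- stats::rpois(length(lam), lam)
    seqs <- character(length(lam))
    planted <- integer(length(lam))
    for (i in seq_along(lam)) {
      # re-draw until the scanner recovers exactly the planted count
      repeat {
        s <- plant_motifs(all_widths[i], n_copies[i], consensus, bg, 1e-4)
        got <- nrow(scan_sequence(s, pwm, 1e-4, dists = scan_dists))
        if (got == attr(s, "planted")) break
      }
      seqs[i] <- s
      planted[i] <- attr(s, "planted")
    }
    list(seqs = stats::setNames(seqs, all_names),
         planted = stats::setNames(planted, all_names))
  })

  # --- signal track with three intensity tiers ---
  tier_track <- with_seed(sub_seed(cfg$seed, 7L), {
    is_book_async <- seq_len(cfg$n_async_peaks) %in% book_sel
    tier <- integer(cfg$n_async_peaks)
    for (i in seq_len(cfg$n_async_peaks)) {
      p <- if (is_book_async[i]) cfg$tier_probs_bookmarked else
        cfg$tier_probs_other
      tier[i] <- sample.int(3L, 1L, prob = p)
    }
    chunks <- 10L  # 10 x 50 bp around the summit
    rows <- lapply(seq_len(cfg$n_async_peaks), function(i) {
      s0 <- async_pk$centre[i] - 250L
      val <- pmax(0, cfg$tier_means[tier[i]] +
                    stats::rnorm(chunks, 0, cfg$tier_noise_sd))
      data.frame(chrom = async_pk$chrom[i],
                 start = s0 + (seq_len(chunks) - 1L) * 50L,
                 end = s0 + seq_len(chunks) * 50L,
                 value = val, stringsAsFactors = FALSE)
    })
    list(df = do.call(rbind, rows),
         tier = stats::setNames(tier, async_names))
  })
  tdf <- tier_track$df
  track <- GenomicRanges::sort(GenomicRanges::GRanges(
    tdf$chrom, IRanges::IRanges(tdf$start + 1L, tdf$end),
    score = tdf$value, seqinfo = genome))

  manifest <- list(
    seed = cfg$seed,
    n_async_peaks = cfg$n_async_peaks,
    n_mitotic_peaks = n_book + cfg$n_mitotic_unique,
    n_bookmarked = n_book,
    n_mitotic_unique = cfg$n_mitotic_unique,
    bookmark_fraction = cfg$bookmark_fraction,
    bookmarked_async = bookmarked_async_names,
    bookmarked_mitotic = mit_names[seq_len(n_book)],
    gene_bookmark_fraction = 100 * n_book / cfg$n_async_peaks,
    motif_lambda = as.list(cfg$motif_lambda),
    planted_motif_counts = as.list(seq_truth$planted),
    signal_tier = as.list(tier_track$tier),
    tier_means = cfg$tier_means,
    state_fractions = as.list(cfg$state_fractions),
    state_avoidance = as.list(cfg$state_avoidance),
    peak_state = stats::setNames(
      as.list(pk$state),
      c(async_names, sprintf("mitu_%04d", seq_len(cfg$n_mitotic_unique))))
  )

  out <- list(genome = genome, genes = genes, async = async,
              mitotic = mitotic, sequences = seq_truth$seqs, pwm = pwm,
              track = track, segmentation = seg_gr, manifest = manifest)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      chrom_sizes = file.path(dir, "genome.chrom.sizes"),
      genes = file.path(dir, "genes.tsv"),
      async = file.path(dir, "async.narrowPeak"),
      mitotic = file.path(dir, "mitotic.narrowPeak"),
      fasta = file.path(dir, "peaks.fasta"),
      meme = file.path(dir, "motif.meme"),
      track = file.path(dir, "signal.bedGraph"),
      segmentation = file.path(dir, "segmentation.bed"),
      manifest = file.path(dir, "manifest.json")
    )
    write_chrom_sizes(genome, paths$chrom_sizes)
    utils::write.table(genes, paths$genes, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_bed(async, paths$async)
    write_bed(mitotic, paths$mitotic)
    writeLines(paste0(">", names(out$sequences), "\n", out$sequences),
               paths$fasta)
    write_meme(pwm, paths$meme)
    write_bedgraph(track, paths$track)
    utils::write.table(
      data.frame(seg$chrom, seg$start, seg$end, seg$state),
      paths$segmentation, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}

#' Generate a planted three-tier signal matrix
#'
#' Direct generator for clustering benchmarks: rows drawn around the
#' three tier means with Gaussian noise.
#'
#' @param n_per_tier Features per tier (length 3).
#' @param tier_means Three descending tier means.
#' @param noise_sd Noise SD.
#' @param nbins Number of bins per row.
#' @param seed RNG seed.
#' @return A list: `matrix` (a `signal_matrix`) and `tier` (true tier
#'   per row).
#' @export
simulate_signal_matrix <- function(n_per_tier = c(50, 50, 50),
                                   tier_means = c(10, 3, 0.5),
                                   noise_sd = 0.1, nbins = 80,
                                   seed = 1) {
  with_seed(seed, {
    tier <- rep(1:3, n_per_tier)
    n <- length(tier)
    m <- matrix(stats::rnorm(n * nbins, mean = tier_means[tier],
                             sd = noise_sd), nrow = n)
    rownames(m) <- sprintf("feat_%04d", seq_len(n))
    attr(m, "flank") <- nbins * 25
    attr(m, "binsize") <- 50
    class(m) <- c("signal_matrix", class(m))
    list(matrix = m, tier = stats::setNames(tier, rownames(m)))
  })
}

#' Generate synthetic mitotic-cell images with planted retention
#'
#' Each synthetic cell is a disk-shaped cell mask with an interior
#' chromatin blob; TF-channel intensity is a cytoplasm baseline times
#' the planted enrichment inside the chromatin, with multiplicative
#' Gaussian noise. The DNA channel separates chromatin from cytoplasm
#' cleanly.
#'
#' @param cfg A `sim_config` (fields `n_cells`, `cell_enrichment`,
#'   `cell_noise_sd`, `seed`).
#' @param size Image side length in pixels.
#' @return A list of cells, each with `intensity`, `dna`, `cell_mask`,
#'   `truth` (planted enrichment), plus a `truth` summary.
#' @export
generate_images <- function(cfg = sim_config(), size = 64L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seed(cfg$seed, 8L), {
    centre <- size / 2
    xy <- expand.grid(x = seq_len(size), y = seq_len(size))
    d_cell <- sqrt((xy$x - centre)^2 + (xy$y - centre)^2)
    cell_mask <- matrix(d_cell <= size * 0.4, nrow = size)
    cells <- lapply(seq_len(cfg$n_cells), function(i) {
      cx <- centre + stats::runif(1, -size * 0.12, size * 0.12)
      cy <- centre + stats::runif(1, -size * 0.12, size * 0.12)
      d_chr <- sqrt((xy$x - cx)^2 + (xy$y - cy)^2)
      chromatin <- matrix(d_chr <= size * 0.15, nrow = size) & cell_mask
      base <- 100
      signal <- ifelse(chromatin, base * cfg$cell_enrichment, base)
      noise <- stats::rnorm(length(signal), 0, cfg$cell_noise_sd)
      intensity <- matrix(pmax(0, signal * (1 + noise)), nrow = size)
      intensity[!cell_mask] <- 0
      dna <- matrix(20, nrow = size, ncol = size)
      dna[chromatin] <- 200
      list(cell_id = sprintf("cell_%03d", i),
           intensity = intensity, dna = dna, cell_mask = cell_mask,
           chromatin_mask = chromatin,
           truth = cfg$cell_enrichment)
    })
    list(cells = cells,
         truth = list(enrichment = cfg$cell_enrichment,
                      log2_enrichment = log2(cfg$cell_enrichment),
                      noise_sd = cfg$cell_noise_sd,
                      n_cells = cfg$n_cells))
  })
}
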