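#' Default pipeline parameters
#' @keywords internal
default_pipeline_params <- function() {
  list(min_overlap = 1L, flank = 2000, binsize = 50, k = 3,
       seed = 1234, n_init = 10, p_threshold = 1e-4, n_rep = 1000,
       promoter_up = 2000, promoter_down = 500, max_distance = 1e5,
       state_mode = "bases", legacy_divisor = FALSE)
}

#' Run the full bookmarking analysis end to end
#'
#' Thin, logged composition of the package's stage functions: peak
#' classification, gene assignment and bookmarking fraction,
#' summit-centred signal matrix with k-means clustering and per-cluster
#' bookmarked fractions, motif counting with matched subsampling and a
#' KS comparison (plus co-occurrence when several motifs are supplied),
#' chromatin-state enrichment with min-max normalisation and
#' between-condition fold change, and the bin-summed signal difference
#' score. No analysis logic lives in the orchestrator.
#'
#' @param config Either a list or the path of a YAML file with entries
#'   `inputs` (paths: `chrom_sizes`, `async`, `mitotic`, `genes`,
#'   `track`, `segmentation`, `fasta`, `meme`) and optional `params`
#'   overriding [default_pipeline_params()]. Alternatively pass the
#'   in-memory bundle from [generate_dataset()] via `bundle`.
#' @param bundle Optional in-memory dataset (as from
#'   [generate_dataset()]); when given, `config` may omit `inputs`.
#' @param out_dir Optional output directory for the JSON report and
#'   intermediate BED/TSV artifacts.
#' @return The report: a named list of headline statistics.
#' @export
run_pipeline <- function(config = list(), bundle = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  if (is.null(bundle)) {
    inp <- config$inputs
    need <- c("chrom_sizes", "async", "mitotic", "genes", "track",
              "segmentation", "fasta", "meme")
    missing <- setdiff(need, names(inp))
    if (length(missing)) {
      stop("pipeline config missing inputs: ",
           paste(missing, collapse = ", "))
    }
    absent <- unlist(inp[need])[!file.exists(unlist(inp[need]))]
    if (length(absent)) stop("input file not found: ", absent[1L])
    genome <- read_chrom_sizes(inp$chrom_sizes)
    bundle <- list(
      genome = genome,
      async = read_narrowpeak(inp$async, genome, label = "async"),
      mitotic = read_narrowpeak(inp$mitotic, genome, label = "mitotic"),
      genes = read_gene_annotation(inp$genes, genome),
      track = read_bedgraph(inp$track, genome),
      segmentation = read_segmentation(inp$segmentation, genome),
      sequences = read_fasta(inp$fasta),
      pwm = read_meme(inp$meme)
    )
  }
  pwms <- bundle$pwm
  if (inherits(pwms, "pwm")) pwms <- list(pwms)

  stage <- function(name) message("[mitobook] stage: ", name)

  stage("classify")
  cls <- classify_peaks(bundle$async, bundle$mitotic,
                        min_overlap = params$min_overlap)

  stage("annotate")
  gbf <- gene_bookmark_fraction(cls, bundle$genes,
                                promoter_up = params$promoter_up,
                                promoter_down = params$promoter_down,
                                max_distance = params$max_distance)

  stage("matrix/cluster")
  mat <- build_matrix(bundle$track, bundle$async,
                      flank = params$flank, binsize = params$binsize)
  clust <- kmeans_cluster(mat, k = params$k, seed = params$seed,
                          n_init = params$n_init)
  cluster_frac <- cluster_overlap_fractions(cls, clust)

  stage("motifs")
  anchor <- pwms[[1]]
  seqs <- bundle$sequences
  async_names <- S4Vectors::mcols(bundle$async)$name
  mit_names <- S4Vectors::mcols(cls$bookmarked_mitotic)$name
  cd_async_only <- count_motifs(cls$async_only,
                                seqs[S4Vectors::mcols(cls$async_only)$name],
                                anchor, params$p_threshold)
  cd_mit <- count_motifs(cls$bookmarked_mitotic, seqs[mit_names],
                         anchor, params$p_threshold)
  sub_hist <- subsample_matched(cd_async_only,
                                n_target = min(length(cd_mit$counts),
                                               length(cd_async_only$counts)),
                                n_rep = params$n_rep, seed = params$seed)
  ks <- ks_compare(cd_async_only$counts, cd_mit$counts)
  cooc <- NULL
  if (length(pwms) > 1L) {
    others <- lapply(pwms[-1], function(p) {
      count_motifs(bundle$async, seqs[async_names], p,
                   params$p_threshold)$counts
    })
    names(others) <- vapply(pwms[-1], `[[`, "", "motif_id")
    cd_async_all <- count_motifs(bundle$async, seqs[async_names],
                                 anchor, params$p_threshold)
    cooc <- co_occurrence(cd_async_all$counts, others)
  }

  stage("states")
  enr_async <- overlap_enrichment(bundle$async, bundle$segmentation,
                                  mode = params$state_mode)
  enr_mit <- overlap_enrichment(cls$bookmarked_mitotic,
                                bundle$segmentation,
                                mode = params$state_mode)
  sfc <- state_fold_change(enr_async, enr_mit,
                           legacy_divisor = params$legacy_divisor)

  stage("difference score")
  diff_score <- signal_difference_score(
    mat, S4Vectors::mcols(cls$async_only)$name,
    S4Vectors::mcols(cls$bookmarked_async)$name)

  report <- list(
    schema_version = "1.0",
    parameters = params,
    counts = as.list(cls$counts),
    gene_bookmark_fraction = gbf$bookmarked_fraction,
    cluster_fractions = cluster_frac,
    ks = ks,
    subsampled_histogram = as.list(sub_hist),
    co_occurrence = as.list(cooc),
    state_fold_change = stats::setNames(
      as.list(sfc$fold_change), sfc$state),
    signal_difference_async_only_minus_bookmarked = as.numeric(diff_score)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(cls$bookmarked_mitotic,
              file.path(out_dir, "bookmarked_mitotic.bed"))
    write_bed(cls$bookmarked_async,
              file.path(out_dir, "bookmarked_async.bed"))
    write_bed(cls$async_only, file.path(out_dir, "async_only.bed"))
    write_bed(cls$mitotic_unique,
              file.path(out_dir, "mitotic_unique.bed"))
    utils::write.table(gbf$table, file.path(out_dir, "gene_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cluster_frac,
                       file.path(out_dir, "cluster_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA file as a named character vector
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
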