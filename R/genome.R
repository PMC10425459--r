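#' Construct a genome coordinate system from chromosome sizes
#'
#' A genome is simply a set of named chromosomes with lengths, represented
#' as a [GenomeInfoDb::Seqinfo] object. All interval containers in the
#' package carry their genome as seqinfo so that bounds can be checked and
#' mismatched inputs rejected early.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return A `Seqinfo` object.
#' @examples
#' gn <- Genome(c(chrS1 = 1e5, chrS2 = 5e4))
#' genome_size(gn)
#' @export
Genome <- function(chrom_sizes) {
  nm <- names(chrom_sizes)
  if (is.null(nm) || any(nm == "")) {
    stop("chrom_sizes must be a named vector")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  len <- as.numeric(chrom_sizes)
  if (any(!is.finite(len)) || any(len <= 0) || any(len != floor(len))) {
    stop("chromosome lengths must be positive integers")
  }
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Read a UCSC chrom.sizes file
#'
#' Expects two whitespace-separated columns: chromosome name and length in
#' bp. Duplicate names and non-positive lengths are errors.
#'
#' @param path Path to a chrom.sizes text file.
#' @return A `Seqinfo` object (see [Genome()]).
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed chrom.sizes line ", bad[1L], " in ", path)
  }
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (any(is.na(len))) {
    stop("non-numeric chromosome length at line ", which(is.na(len))[1L])
  }
  sizes <- stats::setNames(len, nm)
  Genome(sizes)
}

#' Total genome size in bp
#' @param genome A `Seqinfo` object.
#' @return Numeric scalar, sum of chromosome lengths.
#' @export
genome_size <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

#' Write chromosome sizes to a chrom.sizes file
#' @param genome A `Seqinfo` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(genome, path) {
  df <- data.frame(chrom = GenomeInfoDb::seqnames(genome),
                   size = GenomeInfoDb::seqlengths(genome))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
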