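#' Build a genome specification
#'
#' A genome is an ordered set of uniquely named chromosomes with positive
#' lengths, represented as a [GenomeInfoDb::Seqinfo] object. Every peak and
#' fragment container in the package carries one, and all pairwise operations
#' require both operands to share it.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in bp (positive).
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' gs <- genome_spec("chr1", 1e6)
#' @export
genome_spec <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("`chrom` and `length` must have equal length")
  if (anyDuplicated(chrom))
    stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  GenomeInfoDb::Seqinfo(seqnames = chrom, seqlengths = as.integer(length))
}

#' Read a chrom-sizes file
#'
#' Parses the standard two-column tab-separated chromosome sizes format
#' (name, length), as produced by e.g. `samtools faidx` post-processing or
#' UCSC's fetchChromSizes.
#'
#' @param path Path to a chrom-sizes file.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_spec(df$chrom, df$length)
}

#' Total genome length in bp
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return Numeric scalar, sum of chromosome lengths.
#' @export
genome_length <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

## Internal: TRUE if two GRanges (or Seqinfo) describe the same genome.
same_genome <- function(a, b) {
  sa <- if (methods::is(a, "Seqinfo")) a else GenomeInfoDb::seqinfo(a)
  sb <- if (methods::is(b, "Seqinfo")) b else GenomeInfoDb::seqinfo(b)
  identical(GenomeInfoDb::seqnames(sa), GenomeInfoDb::seqnames(sb)) &&
    identical(GenomeInfoDb::seqlengths(sa), GenomeInfoDb::seqlengths(sb))
}

stop_if_genome_mismatch <- function(a, b) {
  if (!same_genome(a, b)) stop("operands are defined on different genomes")
  invisible(TRUE)
}
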