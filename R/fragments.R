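## Fragment containers and the randomization machinery of stage 1.
## A fragment set is a bare GRanges (no metadata columns) whose metadata()
## carries a human-readable label. Fragments are paired-end units: pseudo-
## replicate splitting moves whole fragments, never single mates, so Tn5
## insertion pairing is preserved.

#' Construct a fragment set
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end 0-based half-open fragment coordinates.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param label Replicate label carried in `metadata()`.
#' @return A `GRanges` fragment set.
#' @export
fragment_set <- function(chrom, start, end, genome, label = "fragments") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L | start >= end))
    stop("fragments must satisfy 0 <= start < end")
  known <- chrom %in% GenomeInfoDb::seqnames(genome)
  if (!all(known)) stop("unknown chromosome: ", chrom[which(!known)[1]])
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    seqinfo = genome
  )
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Read fragments from BED3 or BEDPE
#'
#' BEDPE records are collapsed to the fragment spanning the outer mate
#' coordinates. An optional Tn5 +4/-5 shift can be applied for real ATAC
#' data (off by default; synthetic fragments are already insertion-centred).
#'
#' @param path File path.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param format `"auto"` (sniff column count), `"bed"` or `"bedpe"`.
#' @param tn5_shift If `TRUE`, shift fragment starts +4 and ends -5 bp.
#' @param label Replicate label; defaults to the file's base name.
#' @return A `GRanges` fragment set.
#' @export
read_fragments <- function(path, genome, format = c("auto", "bed", "bedpe"),
                           tn5_shift = FALSE, label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- basename(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(fragment_set(character(0), integer(0), integer(0), genome, label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "auto") format <- if (nf[1] >= 6L) "bedpe" else "bed"
  need <- if (format == "bedpe") 6L else 3L
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("fragment format error at line %d: expected >= %d columns, got %d",
                 bad[1], need, nf[bad[1]]))
  fld <- function(k) vapply(fields, `[[`, character(1), k)
  if (format == "bed") {
    chrom <- fld(1); start <- as.integer(fld(2)); end <- as.integer(fld(3))
  } else {
    c1 <- fld(1); c2 <- fld(4)
    trans <- which(c1 != c2)
    if (length(trans))
      stop(sprintf("fragment format error at line %d: BEDPE mates on different chromosomes",
                   trans[1]))
    s1 <- as.integer(fld(2)); e1 <- as.integer(fld(3))
    s2 <- as.integer(fld(5)); e2 <- as.integer(fld(6))
    chrom <- c1
    start <- pmin(s1, s2)
    end <- pmax(e1, e2)
  }
  if (anyNA(start) || anyNA(end))
    stop(sprintf("fragment format error at line %d: non-integer coordinate",
                 which(is.na(start) | is.na(end))[1]))
  if (tn5_shift) {
    start <- start + 4L
    end <- end - 5L
    keep <- start < end
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  }
  fragment_set(chrom, start, end, genome, label)
}

#' Split a fragment set into two pseudo-replicates
#'
#' A uniformly random partition of the fragments into two halves whose sizes
#' differ by at most one. The union of the two halves equals the input as a
#' multiset, and the partition is deterministic given `seed`.
#'
#' @param fs A `GRanges` fragment set.
#' @param seed Integer seed.
#' @return A list of two fragment sets, `pseudo1` and `pseudo2`.
#' @export
split_pseudoreplicates <- function(fs, seed) {
  n <- length(fs)
  label <- S4Vectors::metadata(fs)$label
  idx1 <- if (n == 0L) integer(0) else
    withr::with_seed(as.integer(seed), sample.int(n, n %/% 2L))
  h1 <- fs[sort(idx1)]
  h2 <- if (n == 0L) fs else fs[sort(setdiff(seq_len(n), idx1))]
  S4Vectors::metadata(h1)$label <- paste0(label, ".pseudo1")
  S4Vectors::metadata(h2)$label <- paste0(label, ".pseudo2")
  list(pseudo1 = h1, pseudo2 = h2)
}

#' Pool two fragment sets
#'
#' Multiset concatenation; the basis for the pooled pseudo-replicates used
#' by rescue analysis.
#'
#' @param a,b `GRanges` fragment sets on the same genome.
#' @return A fragment set with `length(a) + length(b)` fragments.
#' @export
pool_fragments <- function(a, b) {
  stop_if_genome_mismatch(a, b)
  out <- c(GenomicRanges::granges(a), GenomicRanges::granges(b))
  S4Vectors::metadata(out)$label <- paste(S4Vectors::metadata(a)$label,
                                          S4Vectors::metadata(b)$label,
                                          sep = "+")
  out
}
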