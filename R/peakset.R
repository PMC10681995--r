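## Peak sets are GRanges with a fixed set of metadata columns mirroring the
## ENCODE narrowPeak (BED6+4) record:
##   name       peak identifier (character)
##   score      integer display score
##   signal     fold enrichment at the peak (>= 0)
##   pLog10     -log10 p-value (>= 0)
##   qLog10     -log10 q-value, the "Q value" used by stage 2 (>= 0)
##   summit     summit offset in bp from the peak's (0-based) start, the
##              "peak point"; -1 when unknown
## Coordinates presented to users (constructors, file I/O) follow the BED
## convention: 0-based, half-open. Internally ranges are ordinary 1-based
## closed GRanges; the shift happens only at the boundary.

PEAK_MCOLS <- c("name", "score", "signal", "pLog10", "qLog10", "summit")

#' Construct a peak set
#'
#' Builds a validated peak container from BED-style (0-based, half-open)
#' coordinates. All narrowPeak attribute columns are optional and default to
#' unknown/zero values, so region-only sets (e.g. from BED3) use the same
#' representation.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open interval bounds.
#' @param genome A [GenomeInfoDb::Seqinfo] from [genome_spec()].
#' @param name,score,strand,signal,pLog10,qLog10,summit narrowPeak attribute
#'   columns; `summit` is the summit offset from `start` (-1 if unknown).
#' @return A `GRanges` with the package's peak metadata columns.
#' @export
peak_set <- function(chrom, start, end, genome,
                     name = NULL, score = 0L, strand = ".",
                     signal = 0, pLog10 = 0, qLog10 = 0, summit = -1L) {
  n <- length(chrom)
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != n || length(end) != n)
    stop("chrom/start/end lengths differ")
  if (n == 0L) return(empty_peak_set(genome))
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  strand <- ifelse(strand == ".", "*", strand)
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stop("invalid interval at record ", bad[1], ": start must satisfy 0 <= start < end")
  known <- chrom %in% GenomeInfoDb::seqnames(genome)
  if (!all(known))
    stop("unknown chromosome: ", chrom[which(!known)[1]])
  lens <- GenomeInfoDb::seqlengths(genome)[chrom]
  over <- which(end > lens)
  if (length(over))
    stop("record ", over[1], " extends beyond chromosome end")
  summit <- as.integer(rep_len(summit, n))
  w <- end - start
  badsum <- which(summit != -1L & (summit < 0L | summit >= w))
  if (length(badsum))
    stop("record ", badsum[1], ": summit offset outside the peak interval")
  qLog10 <- rep_len(as.numeric(qLog10), n)
  if (any(qLog10 < 0)) stop("qLog10 must be non-negative")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand,
    seqinfo = genome
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = as.character(rep_len(name, n)),
    score = as.integer(rep_len(score, n)),
    signal = rep_len(as.numeric(signal), n),
    pLog10 = rep_len(as.numeric(pLog10), n),
    qLog10 = qLog10,
    summit = summit
  )
  sort_peaks(gr)
}

#' An empty peak set on a genome
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return A zero-length peak `GRanges`.
#' @export
empty_peak_set <- function(genome) {
  gr <- GenomicRanges::GRanges(seqinfo = genome)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(0), score = integer(0), signal = numeric(0),
    pLog10 = numeric(0), qLog10 = numeric(0), summit = integer(0)
  )
  gr
}

## Internal: deterministic sort by (chrom order in genome, start, end).
sort_peaks <- function(gr) {
  gr[order(as.integer(GenomeInfoDb::seqnames(gr)),
           GenomicRanges::start(gr), GenomicRanges::end(gr))]
}

## Internal: BED-style 0-based starts / exclusive ends.
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

## Internal: wrap a bare (attribute-free) GRanges as a region-only peak set.
as_region_set <- function(gr, genome) {
  if (length(gr) == 0L) return(empty_peak_set(genome))
  peak_set(as.character(GenomeInfoDb::seqnames(gr)),
           start0(gr), end0(gr), genome,
           name = sprintf("region_%d", seq_along(gr)))
}

#' Read an ENCODE narrowPeak file
#'
#' Strict reader for the 10-column BED6+4 narrowPeak format. The p- and
#' q-value columns are interpreted as -log10-transformed (the convention of
#' MACS2-style callers); column 10 is the summit offset from the peak start.
#' A `"."` score is parsed as 0.
#'
#' @param path File path.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param lenient If `TRUE`, records on chromosomes absent from `genome` are
#'   skipped with a warning instead of raising an error.
#' @return A peak `GRanges` (see [peak_set()]).
#' @export
read_narrowpeak <- function(path, genome, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_peak_set(genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 10L)
  if (length(bad))
    stop(sprintf("narrowPeak format error at line %d: expected 10 tab-separated columns, got %d",
                 bad[1], nf[bad[1]]))
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  chrom <- m[, 1]
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("narrowPeak format error at line %d: non-integer coordinate",
                 which(is.na(start) | is.na(end))[1]))
  badrec <- which(start >= end | start < 0L)
  if (length(badrec))
    stop(sprintf("validation error at line %d: start must satisfy 0 <= start < end", badrec[1]))
  keep <- rep(TRUE, length(chrom))
  unknown <- !(chrom %in% GenomeInfoDb::seqnames(genome))
  if (any(unknown)) {
    if (lenient) {
      warning(sum(unknown), " record(s) on chromosomes absent from the genome were skipped")
      keep <- !unknown
    } else {
      stop(sprintf("validation error at line %d: unknown chromosome '%s'",
                   which(unknown)[1], chrom[which(unknown)[1]]))
    }
  }
  if (!any(keep)) return(empty_peak_set(genome))
  score <- m[, 5]
  score[score == "."] <- "0"
  peak_set(chrom[keep], start[keep], end[keep], genome,
           name = m[keep, 4],
           score = as.integer(score[keep]),
           strand = m[keep, 6],
           signal = as.numeric(m[keep, 7]),
           pLog10 = as.numeric(m[keep, 8]),
           qLog10 = as.numeric(m[keep, 9]),
           summit = as.integer(m[keep, 10]))
}

#' Write a peak set as narrowPeak
#'
#' Emits the canonical 10-column tab-separated form; re-reading a file
#' written by this function and writing it again is byte-identical.
#'
#' @param peaks A peak `GRanges`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_narrowpeak <- function(peaks, path) {
  mc <- S4Vectors::mcols(peaks)
  strand <- as.character(GenomicRanges::strand(peaks))
  strand[strand == "*"] <- "."
  num <- function(x) {
    # plain decimal rendering, no scientific notation, no trailing zeros
    out <- format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
    out
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                   as.character(GenomeInfoDb::seqnames(peaks)),
                   start0(peaks), end0(peaks),
                   mc$name, mc$score, strand,
                   num(mc$signal), num(mc$pLog10), num(mc$qLog10),
                   mc$summit)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 file as a region-only peak set
#'
#' @param path File path.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return A peak `GRanges` with default attribute columns.
#' @export
read_bed3 <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_peak_set(genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(sprintf("BED format error at line %d: fewer than 3 columns", bad[1]))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1), 3L))
  peak_set(chrom, start, end, genome)
}
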