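## Interval algebra over peak sets. All operations are strand-blind (ATAC
## peaks are unstranded); strand is carried through I/O but never consulted.

#' Intersection of two peak-set covers
#'
#' Returns the maximal intervals covered by both inputs, i.e. the pure
#' interval intersection of the two merged covers. Attribute columns of the
#' result are left at their defaults (downstream steps re-attribute them).
#'
#' @param a,b Peak `GRanges` on the same genome.
#' @return A region-only peak `GRanges`.
#' @export
intersect_regions <- function(a, b) {
  stop_if_genome_mismatch(a, b)
  genome <- GenomeInfoDb::seqinfo(a)
  r <- GenomicRanges::intersect(
    GenomicRanges::reduce(GenomicRanges::granges(a), ignore.strand = TRUE),
    GenomicRanges::reduce(GenomicRanges::granges(b), ignore.strand = TRUE),
    ignore.strand = TRUE
  )
  as_region_set(r, genome)
}

#' Merge a peak set
#'
#' Unions intervals whose separation is at most `gap` bp (bookended intervals
#' merge at `gap = 0`). Merged attributes: `qLog10` and `signal` are the
#' maxima over members; the summit is taken from the member with the highest
#' signal (first on ties) and re-expressed as an offset from the merged start.
#'
#' @param a A peak `GRanges`.
#' @param gap Non-negative integer, maximum separation to bridge.
#' @return A sorted, non-overlapping peak `GRanges`. The `revmap` metadata
#'   column maps each merged peak to its member indices in `a`.
#' @export
merge_regions <- function(a, gap = 0L) {
  if (gap < 0) stop("`gap` must be non-negative")
  genome <- GenomeInfoDb::seqinfo(a)
  if (length(a) == 0L) {
    out <- empty_peak_set(genome)
    S4Vectors::mcols(out)$revmap <- IRanges::IntegerList()
    return(out)
  }
  red <- GenomicRanges::reduce(GenomicRanges::granges(a),
                               min.gapwidth = gap + 1L,
                               with.revmap = TRUE,
                               ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  mc <- S4Vectors::mcols(a)
  pick <- function(idx) idx[which.max(mc$signal[idx])]
  best <- vapply(as.list(revmap), pick, integer(1))
  qv <- vapply(as.list(revmap), function(i) max(mc$qLog10[i]), numeric(1))
  sig <- vapply(as.list(revmap), function(i) max(mc$signal[i]), numeric(1))
  bsummit <- mc$summit[best]
  abs_summit <- ifelse(bsummit == -1L, -1L, start0(a)[best] + bsummit)
  out_start0 <- GenomicRanges::start(red) - 1L
  summit <- ifelse(abs_summit == -1L, -1L, abs_summit - out_start0)
  out <- peak_set(as.character(GenomeInfoDb::seqnames(red)),
                  out_start0, GenomicRanges::end(red), genome,
                  name = sprintf("merged_%d", seq_along(red)),
                  score = mc$score[best],
                  signal = sig, pLog10 = mc$pLog10[best],
                  qLog10 = qv, summit = as.integer(summit))
  # peak_set sorts; red is already sorted, so order is preserved
  S4Vectors::mcols(out)$revmap <- revmap
  out
}

#' Fraction of a target interval covered by a peak set
#'
#' @param target A single-peak `GRanges` (length 1).
#' @param cover A peak `GRanges`; overlapping members are union-ed, not summed.
#' @return Numeric in \[0, 1\].
#' @export
coverage_fraction <- function(target, cover) {
  if (length(target) != 1L) stop("`target` must be a single peak")
  stop_if_genome_mismatch(target, cover)
  if (length(cover) == 0L) return(0)
  ov <- GenomicRanges::intersect(
    GenomicRanges::granges(target),
    GenomicRanges::reduce(GenomicRanges::granges(cover), ignore.strand = TRUE),
    ignore.strand = TRUE
  )
  sum(GenomicRanges::width(ov)) / GenomicRanges::width(target)
}

#' Jaccard similarity of two peak-set covers
#'
#' Base pairs in the intersection of the covers divided by base pairs in
#' their union. Undefined (error) when both covers are empty.
#'
#' @param a,b Peak `GRanges` on the same genome.
#' @return Numeric in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  stop_if_genome_mismatch(a, b)
  ra <- GenomicRanges::reduce(GenomicRanges::granges(a), ignore.strand = TRUE)
  rb <- GenomicRanges::reduce(GenomicRanges::granges(b), ignore.strand = TRUE)
  if (length(ra) == 0L && length(rb) == 0L)
    stop("Jaccard similarity is undefined for two empty covers")
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ra, rb, ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(GenomicRanges::reduce(c(ra, rb), ignore.strand = TRUE)))
  inter / uni
}
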