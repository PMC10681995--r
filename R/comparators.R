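## Benchmark comparators: the two length-overlap consensus recipes the
## two-stage method is measured against.

#' Naive length-overlap consensus
#'
#' Keeps each pooled peak iff, for every replicate, more than `min_frac` of
#' the pooled peak's length is covered by that replicate's peaks
#' (strict `>` by default, the fraction-of-pooled-peak convention).
#'
#' @param pooled Peak `GRanges` of pooled peaks.
#' @param replicates Non-empty list of peak `GRanges`.
#' @param min_frac Coverage fraction threshold (default 0.5).
#' @param strict If `TRUE` (default) require coverage strictly greater than
#'   `min_frac`; if `FALSE`, at least `min_frac`.
#' @return The subset of `pooled` passing in every replicate.
#' @export
naive_overlap <- function(pooled, replicates, min_frac = 0.5, strict = TRUE) {
  if (length(replicates) == 0L) stop("at least one replicate is required")
  for (r in replicates) stop_if_genome_mismatch(pooled, r)
  if (length(pooled) == 0L) return(pooled)
  keep <- rep(TRUE, length(pooled))
  for (r in replicates) {
    cov <- GenomicRanges::reduce(GenomicRanges::granges(r), ignore.strand = TRUE)
    ov <- GenomicRanges::intersect(GenomicRanges::granges(pooled), cov,
                                   ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(pooled, ov, ignore.strand = TRUE)
    covered <- numeric(length(pooled))
    if (length(hits)) {
      wid <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(pooled)[S4Vectors::queryHits(hits)],
        GenomicRanges::ranges(ov)[S4Vectors::subjectHits(hits)]))
      agg <- tapply(wid, S4Vectors::queryHits(hits), sum)
      covered[as.integer(names(agg))] <- agg
    }
    frac <- covered / GenomicRanges::width(pooled)
    keep <- keep & (if (strict) frac > min_frac else frac >= min_frac)
  }
  pooled[keep]
}

#' Non-overlapping maximum signal (NOMS) consensus
#'
#' Pools all replicate peaks, then repeatedly emits the remaining peak with
#' the maximum signal (ties: higher `qLog10`, then leftmost, then earliest
#' replicate) and discards every remaining peak overlapping it by >= 1 bp,
#' until none remain. The output is sorted and mutually non-overlapping.
#'
#' @param replicates Non-empty list of peak `GRanges` on one genome.
#' @return A peak `GRanges`.
#' @export
noms <- function(replicates) {
  if (length(replicates) == 0L) stop("at least one replicate is required")
  genome <- GenomeInfoDb::seqinfo(replicates[[1]])
  for (r in replicates) stop_if_genome_mismatch(replicates[[1]], r)
  pooled <- do.call(c, unname(as.list(replicates)))
  if (length(pooled) == 0L) return(empty_peak_set(genome))
  origin <- rep(seq_along(replicates), vapply(replicates, length, integer(1)))
  mc <- S4Vectors::mcols(pooled)
  ord <- order(-mc$signal, -mc$qLog10,
               as.integer(GenomeInfoDb::seqnames(pooled)),
               GenomicRanges::start(pooled), origin)
  alive <- rep(TRUE, length(pooled))
  emitted <- integer(0)
  for (idx in ord) {
    if (!alive[idx]) next
    emitted <- c(emitted, idx)
    hit <- GenomicRanges::findOverlaps(pooled[idx], pooled, ignore.strand = TRUE)
    alive[S4Vectors::subjectHits(hit)] <- FALSE
  }
  sort_peaks(pooled[emitted])
}
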