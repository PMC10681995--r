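## Stage 2: turn each MS1pass pair into its contribution to the optimal
## peak set. The pair's base peaks are the interval intersection of its
## Nt- and Np-consistent regions; the lower medians of the base peaks'
## summit offsets ("peak points") and Q values gate three filters -- on the
## base peaks themselves and on each member replicate's full peak list --
## whose union is the pair's MS2pass set. Optimal peaks are the merged
## union of all MS2pass sets.

## Lower median: element at 1-based index floor((n + 1) / 2) of the
## ascending sort. Chosen (over interpolation) so the threshold is always a
## value attained by an actual peak.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x)[(n + 1L) %/% 2L]
}

#' Base peaks of a replicate pair
#'
#' Intersects the Nt-consistent and Np-consistent region sets. Each base
#' peak inherits `qLog10` and the summit of the overlapping Nt region with
#' the highest `qLog10` (summit clipped into the base-peak interval and
#' re-expressed as an offset). Also computes the lower medians of the
#' base peaks' summit offsets and Q values, the stage-2 thresholds.
#'
#' @param nt_regions,np_regions Peak `GRanges` of consistent regions from
#'   [count_consistent()].
#' @return A list of class `mesia_base_peaks`: `bp` (peak `GRanges`), `pp`
#'   (summit offsets), `qv` (qLog10 values), `medianPP`, `medianQV`, `n`.
#' @export
base_peaks <- function(nt_regions, np_regions) {
  genome <- GenomeInfoDb::seqinfo(nt_regions)
  emptyres <- structure(list(bp = empty_peak_set(genome), pp = integer(0),
                             qv = numeric(0), medianPP = NA_real_,
                             medianQV = NA_real_, n = 0L),
                        class = "mesia_base_peaks")
  if (length(nt_regions) == 0L || length(np_regions) == 0L) {
    warning("empty consistent-region set; base peaks are empty")
    return(emptyres)
  }
  bp <- intersect_regions(nt_regions, np_regions)
  if (length(bp) == 0L) return(emptyres)
  hits <- GenomicRanges::findOverlaps(bp, nt_regions, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  qv_all <- S4Vectors::mcols(nt_regions)$qLog10
  best <- vapply(split(sh, qh), function(cand) cand[which.max(qv_all[cand])],
                 integer(1))
  stopifnot(length(best) == length(bp))   # BP cover is a subset of nt cover
  src <- nt_regions[best]
  bp_start0 <- start0(bp); bp_end0 <- end0(bp)
  src_summit <- S4Vectors::mcols(src)$summit
  abs_summit <- ifelse(src_summit == -1L, -1L, start0(src) + src_summit)
  clipped <- ifelse(abs_summit == -1L, -1L,
                    pmin(pmax(abs_summit, bp_start0), bp_end0 - 1L))
  summit <- as.integer(ifelse(clipped == -1L, -1L, clipped - bp_start0))
  out <- peak_set(as.character(GenomeInfoDb::seqnames(bp)),
                  bp_start0, bp_end0, genome,
                  name = sprintf("bp_%d", seq_along(bp)),
                  score = S4Vectors::mcols(src)$score,
                  signal = S4Vectors::mcols(src)$signal,
                  pLog10 = S4Vectors::mcols(src)$pLog10,
                  qLog10 = qv_all[best],
                  summit = summit)
  pp <- S4Vectors::mcols(out)$summit
  qv <- S4Vectors::mcols(out)$qLog10
  structure(list(bp = out, pp = pp, qv = qv,
                 medianPP = lower_median(pp[pp != -1L]),
                 medianQV = lower_median(qv),
                 n = length(out)),
            class = "mesia_base_peaks")
}

#' Significance filter on peak point and Q value
#'
#' Keeps exactly the peaks whose summit offset is at least `medianPP` AND
#' whose `qLog10` is at least `medianQV` (both conditions, both inclusive,
#' so the median element itself passes). Peaks with an unknown summit
#' (`-1`) are dropped with a counted warning.
#'
#' @param peaks A peak `GRanges`.
#' @param medianPP,medianQV Finite thresholds (typically base-peak medians).
#' @return The filtered peak `GRanges`.
#' @export
sig_filter <- function(peaks, medianPP, medianQV) {
  if (!is.finite(medianPP) || !is.finite(medianQV))
    stop("filter thresholds must be finite")
  if (length(peaks) == 0L) return(peaks)
  mc <- S4Vectors::mcols(peaks)
  unknown <- mc$summit == -1L
  if (any(unknown))
    warning(sum(unknown), " peak(s) with unknown summit offset dropped")
  peaks[!unknown & mc$summit >= medianPP & mc$qLog10 >= medianQV]
}

#' MS2pass set of one replicate pair
#'
#' Filters the base peaks and each member replicate's full peak list by the
#' base peaks' medians ([sig_filter()]) and unions the three survivors.
#' With `per_set_medians = TRUE` the replicate lists are instead filtered by
#' their own medians (alternative reading of the filter bounds).
#'
#' @param bp A `mesia_base_peaks` object from [base_peaks()].
#' @param sp_i,sp_j The two member replicates' full called peak lists.
#' @param per_set_medians Use each list's own medians for SP filtering.
#' @return A list of class `mesia_stage2_pair`: `sigBP`, `sigSP_i`,
#'   `sigSP_j`, `ms2pass` (concatenated peak `GRanges`).
#' @export
ms2pass <- function(bp, sp_i, sp_j, per_set_medians = FALSE) {
  genome <- GenomeInfoDb::seqinfo(bp$bp)
  if (bp$n > 0L && (!is.finite(bp$medianPP) || !is.finite(bp$medianQV))) {
    warning("base-peak medians undefined (all summits unknown); pair contributes nothing")
    e <- empty_peak_set(genome)
    return(structure(list(sigBP = e, sigSP_i = e, sigSP_j = e, ms2pass = e),
                     class = "mesia_stage2_pair"))
  }
  if (bp$n == 0L) {
    warning("empty base-peak set; pair contributes no MS2pass peaks")
    e <- empty_peak_set(genome)
    return(structure(list(sigBP = e, sigSP_i = e, sigSP_j = e, ms2pass = e),
                     class = "mesia_stage2_pair"))
  }
  sig_bp <- sig_filter(bp$bp, bp$medianPP, bp$medianQV)
  thr <- function(sp) {
    if (!per_set_medians) return(c(bp$medianPP, bp$medianQV))
    mc <- S4Vectors::mcols(sp)
    c(lower_median(mc$summit[mc$summit != -1L]), lower_median(mc$qLog10))
  }
  ti <- thr(sp_i); tj <- thr(sp_j)
  sig_i <- sig_filter(sp_i, ti[1], ti[2])
  sig_j <- sig_filter(sp_j, tj[1], tj[2])
  combined <- sort_peaks(c(sig_bp, sig_i, sig_j))
  structure(list(sigBP = sig_bp, sigSP_i = sig_i, sigSP_j = sig_j,
                 ms2pass = combined),
            class = "mesia_stage2_pair")
}

#' Merge MS2pass sets into the optimal peak set
#'
#' Concatenates the MS2pass sets of all pairs and merges them with gap 0;
#' per merged peak the contributing pairs are recorded as provenance.
#'
#' @param results A non-empty list of `mesia_stage2_pair` objects.
#' @param pair_labels Optional character labels, one per result.
#' @return A list of class `mesia_optimal`: `peaks` (merged peak `GRanges`)
#'   and `provenance` (per-peak character vector of contributing pairs).
#' @export
mesia_optimal <- function(results, pair_labels = NULL) {
  if (length(results) == 0L) stop("at least one stage-2 result is required")
  if (is.null(pair_labels)) pair_labels <- sprintf("pair%d", seq_along(results))
  sets <- lapply(results, `[[`, "ms2pass")
  sizes <- vapply(sets, length, integer(1))
  genome <- GenomeInfoDb::seqinfo(sets[[1]])
  if (sum(sizes) == 0L) {
    warning("all MS2pass sets are empty; optimal peak set is empty")
    return(structure(list(peaks = empty_peak_set(genome), provenance = list()),
                     class = "mesia_optimal"))
  }
  all_peaks <- do.call(c, unname(sets))
  origin <- rep(pair_labels, sizes)
  merged <- merge_regions(all_peaks, gap = 0L)
  prov <- lapply(as.list(S4Vectors::mcols(merged)$revmap),
                 function(i) unique(origin[i]))
  S4Vectors::mcols(merged)$revmap <- NULL
  S4Vectors::mcols(merged)$name <- sprintf("mesia_optimal_%d", seq_along(merged))
  structure(list(peaks = merged, provenance = prov), class = "mesia_optimal")
}

#' Run stage 2 over a stage-1 report
#'
#' For every MS1pass pair: build base peaks from the pair's Nt/Np regions,
#' filter, and union into the pair's MS2pass set; then merge across pairs
#' into the optimal peak set.
#'
#' @param s1 A `mesia_stage1` object from [run_stage1()].
#' @param per_set_medians See [ms2pass()].
#' @return A list of class `mesia_stage2`: `pair_results` (named list of
#'   `mesia_stage2_pair`), `optimal` (a `mesia_optimal`), `ms1pass`.
#' @export
run_stage2 <- function(s1, per_set_medians = FALSE) {
  if (!inherits(s1, "mesia_stage1")) stop("`s1` must be a mesia_stage1 object")
  npair <- nrow(s1$ms1pass)
  if (npair == 0L) {
    warning("no pair passed stage 1; optimal peak set is empty")
    return(structure(list(
      pair_results = list(),
      optimal = structure(list(peaks = empty_peak_set(s1$genome),
                               provenance = list()),
                          class = "mesia_optimal"),
      ms1pass = s1$ms1pass), class = "mesia_stage2"))
  }
  pair_results <- vector("list", npair)
  labels <- character(npair)
  for (k in seq_len(npair)) {
    i <- s1$ms1pass[k, "i"]; j <- s1$ms1pass[k, "j"]
    row <- which(s1$pairs$i == i & s1$pairs$j == j)
    bp <- base_peaks(s1$regions[[row]]$nt, s1$regions[[row]]$np)
    pair_results[[k]] <- ms2pass(bp, s1$peaks[[i]], s1$peaks[[j]],
                                 per_set_medians = per_set_medians)
    labels[k] <- sprintf("%s-%s", s1$labels[i], s1$labels[j])
  }
  names(pair_results) <- labels
  opt <- mesia_optimal(pair_results, pair_labels = labels)
  structure(list(pair_results = pair_results, optimal = opt,
                 ms1pass = s1$ms1pass),
            class = "mesia_stage2")
}

#' @export
print.mesia_stage2 <- function(x, ...) {
  cat("Stage 2 result:", length(x$pair_results), "pair(s),",
      length(x$optimal$peaks), "optimal peaks\n")
  invisible(x)
}
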