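## Stage 1: decide, for every replicate pair, whether the pair is
## reproducible. Two screens:
##   rescue analysis  -- Nt (consistent peaks between the true replicates)
##                       versus Np (consistent peaks between the two halves
##                       of the pooled pair); the pair passes when
##                       max(Nt, Np) / min(Nt, Np) <= 2.
##   self-consistency -- each replicate is split into two pseudo-replicate
##                       halves; the ratio of their called peak counts
##                       (max/min) must be <= 2, flagging within-sample bias.
## A pair enters MS1pass only if it passes rescue AND both members pass
## self-consistency.

#' Rescue ratio
#'
#' The orientation-free ratio `max(Nt, Np) / min(Nt, Np)` of the two
#' consistent-peak counts; values at or below 2 mark a reproducible pair.
#'
#' @param nt Consistent-peak count between the true replicates.
#' @param np Consistent-peak count between the pooled pseudo-replicates.
#' @return Numeric ratio >= 1.
#' @export
rescue_ratio <- function(nt, np) {
  if (length(nt) != 1L || length(np) != 1L) stop("nt and np must be scalars")
  if (!is.finite(nt) || !is.finite(np) || nt <= 0 || np <= 0)
    stop("rescue ratio undefined for a zero consistent-peak count; pair is non-reproducible")
  max(nt, np) / min(nt, np)
}

#' Self-consistency of one replicate
#'
#' Splits the replicate's fragments into two pseudo-replicates, calls peaks
#' on each half, and compares the two called peak counts. The replicate
#' passes (`pass = 1`) when `max(N1, N2) / min(N1, N2) <= 2`; a half with
#' zero called peaks fails with a diagnostic.
#'
#' @param fs A `GRanges` fragment set.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param caller A [caller_config()].
#' @param seed Integer seed for the pseudo-replicate split.
#' @return A list: `n1`, `n2`, `ratio`, `pass` (0/1), `note`.
#' @export
self_consistency <- function(fs, genome = GenomeInfoDb::seqinfo(fs),
                             caller = caller_config(), seed = 1L) {
  halves <- split_pseudoreplicates(fs, seed)
  n1 <- length(call_peaks(halves$pseudo1, genome, caller))
  n2 <- length(call_peaks(halves$pseudo2, genome, caller))
  if (n1 == 0L || n2 == 0L)
    return(list(n1 = n1, n2 = n2, ratio = NA_real_, pass = 0L,
                note = "a pseudo-replicate yielded no peaks"))
  ratio <- max(n1, n2) / min(n1, n2)
  list(n1 = n1, n2 = n2, ratio = ratio,
       pass = as.integer(ratio <= 2), note = "")
}

#' Run stage 1 over a set of replicates
#'
#' Calls peaks on every replicate, screens each replicate by
#' [self_consistency()], and evaluates every unordered pair by rescue
#' analysis: Nt from the two true-replicate peak lists, Np from the peak
#' lists of the two halves of the pooled pair (split with the run seed).
#' The result records, per pair, Nt, Np, the rescue ratio, the binary pass
#' flag, and the Nt-/Np-consistent region sets consumed by stage 2.
#'
#' @param replicates A list (>= 2) of `GRanges` fragment sets.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param caller A [caller_config()].
#' @param consistency A [consistency_config()].
#' @param seed Integer master seed; every random split derives from it.
#' @return An object of class `mesia_stage1`: list with `pairs` (data.frame
#'   `i, j, nt, np, rescue, pass`), `self` (data.frame `i, n1, n2, ratio,
#'   pass`), `ms1pass` (two-column matrix of passing pairs), `regions`
#'   (per-pair list with `nt` and `np` region peak sets), `peaks` (per-
#'   replicate called peak lists) and `labels`.
#' @export
run_stage1 <- function(replicates, genome, caller = caller_config(),
                       consistency = consistency_config(), seed = 1L) {
  n <- length(replicates)
  if (n < 2L) stop("stage 1 requires at least 2 replicates")
  seed <- as.integer(seed)
  labels <- vapply(seq_len(n), function(i) {
    lb <- S4Vectors::metadata(replicates[[i]])$label
    if (is.null(lb)) sprintf("rep%d", i) else lb
  }, character(1))
  peaks <- lapply(replicates, call_peaks, genome = genome, config = caller)
  selfs <- lapply(seq_len(n), function(i)
    self_consistency(replicates[[i]], genome, caller, seed = seed + i))
  self_df <- data.frame(
    i = seq_len(n),
    n1 = vapply(selfs, `[[`, integer(1), "n1"),
    n2 = vapply(selfs, `[[`, integer(1), "n2"),
    ratio = vapply(selfs, `[[`, numeric(1), "ratio"),
    pass = vapply(selfs, `[[`, integer(1), "pass")
  )
  pairs <- utils::combn(n, 2)
  regions <- vector("list", ncol(pairs))
  pr <- data.frame(i = pairs[1, ], j = pairs[2, ],
                   nt = NA_integer_, np = NA_integer_,
                   rescue = NA_real_, pass = 0L)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    nt <- count_consistent(peaks[[i]], peaks[[j]], consistency)
    pooled <- pool_fragments(replicates[[i]], replicates[[j]])
    halves <- split_pseudoreplicates(pooled, seed + 1000L + k)
    pp1 <- call_peaks(halves$pseudo1, genome, caller)
    pp2 <- call_peaks(halves$pseudo2, genome, caller)
    np <- count_consistent(pp1, pp2, consistency)
    pr$nt[k] <- nt$count; pr$np[k] <- np$count
    if (nt$count > 0L && np$count > 0L) {
      pr$rescue[k] <- rescue_ratio(nt$count, np$count)
      pr$pass[k] <- as.integer(pr$rescue[k] <= 2)
    }
    regions[[k]] <- list(nt = nt$regions, np = np$regions)
  }
  ok <- pr$pass == 1L & self_df$pass[pr$i] == 1L & self_df$pass[pr$j] == 1L
  ms1pass <- cbind(i = pr$i[ok], j = pr$j[ok])
  structure(list(pairs = pr, self = self_df, ms1pass = ms1pass,
                 regions = regions, peaks = peaks, labels = labels,
                 genome = genome, seed = seed),
            class = "mesia_stage1")
}

#' @export
print.mesia_stage1 <- function(x, ...) {
  cat("Stage 1 reproducibility report (", length(x$peaks), " replicates)\n", sep = "")
  cat("Self-consistency:\n")
  print(x$self, row.names = FALSE)
  cat("Pair rescue analysis:\n")
  print(x$pairs, row.names = FALSE)
  cat(nrow(x$ms1pass), "pair(s) in MS1pass\n")
  invisible(x)
}

#' Write a stage-1 report as TSV + JSON
#'
#' @param report A `mesia_stage1` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_stage1_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "stage1_pairs.tsv")
  utils::write.table(report$pairs, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  tsv2 <- file.path(dir, "stage1_self.tsv")
  utils::write.table(report$self, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "stage1_summary.json")
  jsonlite::write_json(
    list(replicates = report$labels,
         ms1pass = apply(report$ms1pass, 1, function(r) list(i = r[[1]], j = r[[2]])),
         seed = report$seed),
    js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv, tsv2, js))
}
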