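## Pluggable peak-caller layer. The built-in caller is a windowed Poisson
## enrichment scan over fragment midpoints: it is not a re-implementation of
## MACS2's local-lambda model, just a deterministic, dependency-free caller
## so the whole pipeline (and its tests) run without external binaries. Real
## analyses can route through any narrowPeak-emitting caller via
## call_peaks_external().

#' Configuration for the built-in windowed Poisson caller
#'
#' @param windowWidth Window width in bp (default 200, about one nucleosome
#'   footprint). Must be a multiple of `step`.
#' @param step Window step in bp (default 50).
#' @param qThreshold BH-adjusted significance threshold per window
#'   (default 0.05).
#' @param effectiveGenomeFraction Fraction of the genome assumed mappable
#'   when deriving the background rate (default 0.8).
#' @param mergeGap Maximum separation (bp) between significant windows merged
#'   into one peak (default 0).
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(windowWidth = 200L, step = 50L, qThreshold = 0.05,
                          effectiveGenomeFraction = 0.8, mergeGap = 0L) {
  windowWidth <- as.integer(windowWidth); step <- as.integer(step)
  if (step <= 0L || windowWidth <= 0L) stop("window sizes must be positive")
  if (step > windowWidth) stop("`step` must not exceed `windowWidth`")
  if (windowWidth %% step != 0L)
    stop("`windowWidth` must be a multiple of `step`")
  if (qThreshold <= 0 || qThreshold >= 1) stop("`qThreshold` must be in (0, 1)")
  if (effectiveGenomeFraction <= 0 || effectiveGenomeFraction > 1)
    stop("`effectiveGenomeFraction` must be in (0, 1]")
  if (mergeGap < 0) stop("`mergeGap` must be non-negative")
  structure(list(windowWidth = windowWidth, step = step,
                 qThreshold = qThreshold,
                 effectiveGenomeFraction = effectiveGenomeFraction,
                 mergeGap = as.integer(mergeGap)),
            class = "caller_config")
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper over [stats::p.adjust()] with `method = "BH"`; the
#' multiple-testing correction used across caller windows.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, elementwise >= input, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call peaks with the built-in windowed Poisson caller
#'
#' Counts fragment midpoints in sliding windows, scores each window against
#' a uniform Poisson background with rate
#' `lambda = totalMidpoints * windowWidth / (effectiveGenomeFraction * genomeLength)`,
#' adjusts across all windows by Benjamini-Hochberg, and merges significant
#' windows into peaks. Per peak, the summit offset is the (leftmost) argmax
#' of the base-level midpoint pileup, `qLog10` is -log10 of the best member
#' window's q, and `signal` is the best member count divided by `lambda`.
#' Deterministic given its inputs.
#'
#' @param fs A `GRanges` fragment set.
#' @param genome A [GenomeInfoDb::Seqinfo]; defaults to the fragment set's.
#' @param config A [caller_config()].
#' @return A peak `GRanges`.
#' @export
call_peaks <- function(fs, genome = GenomeInfoDb::seqinfo(fs),
                       config = caller_config()) {
  if (genome_length(genome) <= 0) stop("empty genome")
  if (length(fs) == 0L) return(empty_peak_set(genome))
  width <- config$windowWidth; step <- config$step
  w <- width %/% step
  total_mid <- length(fs)
  lambda <- total_mid * width / (config$effectiveGenomeFraction * genome_length(genome))
  mids0 <- (start0(fs) + end0(fs) - 1L) %/% 2L   # 0-based midpoint position
  chrom <- as.character(GenomeInfoDb::seqnames(fs))
  lens <- GenomeInfoDb::seqlengths(genome)
  win_chrom <- character(0); win_start0 <- integer(0); win_k <- integer(0)
  mid_by_chrom <- split(mids0, factor(chrom, levels = GenomeInfoDb::seqnames(genome)))
  for (cn in GenomeInfoDb::seqnames(genome)) {
    L <- lens[[cn]]
    nbins <- L %/% step
    if (nbins < w) next
    mids <- mid_by_chrom[[cn]]
    bins <- tabulate((mids %/% step) + 1L, nbins)
    cs <- cumsum(c(0L, bins))
    nwin <- nbins - w + 1L
    k <- cs[(w + 1L):(nbins + 1L)] - cs[1:nwin]
    win_chrom <- c(win_chrom, rep(cn, nwin))
    win_start0 <- c(win_start0, (seq_len(nwin) - 1L) * step)
    win_k <- c(win_k, k)
  }
  if (length(win_k) == 0L) return(empty_peak_set(genome))
  # log-space tail probabilities and BH, so deeply enriched windows keep
  # continuous scores instead of saturating at the double-precision floor
  logp <- stats::ppois(win_k - 1L, lambda, lower.tail = FALSE, log.p = TRUE)
  nw <- length(logp)
  ord <- order(logp, decreasing = TRUE)          # worst first for the step-up
  logq_sorted <- logp[ord] + log(nw) - log(nw:1)
  logq_sorted <- pmin(cummin(logq_sorted), 0)
  logq <- numeric(nw)
  logq[ord] <- logq_sorted
  sig <- which(logq <= log(config$qThreshold))
  if (length(sig) == 0L) return(empty_peak_set(genome))
  win_gr <- GenomicRanges::GRanges(
    seqnames = win_chrom[sig],
    ranges = IRanges::IRanges(start = win_start0[sig] + 1L,
                              end = pmin(win_start0[sig] + width, lens[win_chrom[sig]])),
    seqinfo = genome
  )
  red <- GenomicRanges::reduce(win_gr, min.gapwidth = config$mergeGap + 1L,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  lqmin <- vapply(as.list(revmap), function(i) min(logq[sig][i]), numeric(1))
  kmax <- vapply(as.list(revmap), function(i) max(win_k[sig][i]), numeric(1))
  lpmin <- vapply(as.list(revmap), function(i) min(logp[sig][i]), numeric(1))
  pk_start0 <- GenomicRanges::start(red) - 1L
  pk_end0 <- GenomicRanges::end(red)
  pk_chrom <- as.character(GenomeInfoDb::seqnames(red))
  sorted_mids <- lapply(mid_by_chrom, function(x) as.double(sort(x)))
  summit <- integer(length(red))
  for (i in seq_along(red)) {
    mids <- sorted_mids[[pk_chrom[i]]]
    lo <- findInterval(pk_start0[i] - 1L, mids) + 1L
    hi <- findInterval(pk_end0[i] - 1L, mids)
    if (hi < lo) {
      summit[i] <- (pk_end0[i] - pk_start0[i]) %/% 2L
    } else {
      pile <- tabulate(mids[lo:hi] - pk_start0[i] + 1L,
                       pk_end0[i] - pk_start0[i])
      summit[i] <- which.max(pile) - 1L   # leftmost on ties
    }
  }
  qlog <- -lqmin / log(10)
  plog <- -lpmin / log(10)
  label <- S4Vectors::metadata(fs)$label
  if (is.null(label)) label <- "sample"
  peak_set(pk_chrom, pk_start0, pk_end0, genome,
           name = sprintf("%s_peak_%d", label, seq_along(red)),
           score = pmin(1000L, as.integer(round(qlog * 10))),
           signal = kmax / lambda, pLog10 = plog, qLog10 = qlog,
           summit = summit)
}

#' Call peaks through an external caller
#'
#' Runs a user-configured shell command (e.g. a MACS2 invocation) built from
#' a template with `{input}`, `{output}` and `{name}` placeholders, then
#' parses the narrowPeak file it produces. Never required by the built-in
#' pipeline or its tests.
#'
#' @param fragmentsPath Path handed to the `{input}` placeholder.
#' @param commandTemplate Shell command template; must contain `{output}`.
#' @param genome A [GenomeInfoDb::Seqinfo] for parsing the output.
#' @param workdir Working directory for the subprocess (default tempdir).
#' @param name Value for the `{name}` placeholder.
#' @return A peak `GRanges` parsed from the caller's narrowPeak output.
#' @export
call_peaks_external <- function(fragmentsPath, commandTemplate, genome,
                                workdir = tempdir(), name = "mesia") {
  if (!grepl("{output}", commandTemplate, fixed = TRUE))
    stop("configuration error: command template lacks an {output} placeholder")
  outfile <- file.path(workdir, paste0(name, "_external.narrowPeak"))
  if (file.exists(outfile)) unlink(outfile)   # never parse a stale result
  cmd <- commandTemplate
  cmd <- gsub("{input}", fragmentsPath, cmd, fixed = TRUE)
  cmd <- gsub("{output}", outfile, cmd, fixed = TRUE)
  cmd <- gsub("{name}", name, cmd, fixed = TRUE)
  res <- suppressWarnings(system2("sh", c("-c", shQuote(cmd)), stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L)
    stop("external caller failed (exit ", status, "): ",
         paste(res, collapse = "\n"))
  if (!file.exists(outfile))
    stop("external caller produced no output file: ", outfile)
  read_narrowpeak(outfile, genome)
}
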