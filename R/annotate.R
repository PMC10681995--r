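## Downstream evaluation: classify peaks against a gene model (promoter /
## gene body / distal intergenic), extract promoter gene sets, and compare
## the expression of gene sets found by different consensus methods.

#' Construct a gene model
#'
#' @param id Gene identifiers (unique).
#' @param chrom Chromosome names.
#' @param txStart,txEnd 0-based half-open transcript bounds.
#' @param strand `"+"` or `"-"`; determines which end is the TSS.
#' @return A data.frame of class `gene_model`.
#' @export
gene_model <- function(id, chrom, txStart, txEnd, strand) {
  txStart <- as.integer(txStart); txEnd <- as.integer(txEnd)
  if (any(txStart >= txEnd)) stop("txStart must be < txEnd")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  structure(data.frame(id = as.character(id), chrom = as.character(chrom),
                       txStart = txStart, txEnd = txEnd,
                       strand = as.character(strand),
                       stringsAsFactors = FALSE),
            class = c("gene_model", "data.frame"))
}

#' Read a gene model from BED12 or a 5-column TSV
#'
#' BED12 files (>= 12 tab-separated columns, no header) use columns 1-4 and
#' 6; otherwise the file must be a header-less 5-column TSV
#' `id, chrom, txStart, txEnd, strand`.
#'
#' @param path File path.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(first) >= 12L) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    gene_model(df[[4]], df[[1]], df[[2]], df[[3]], df[[6]])
  } else if (length(first) == 5L) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    gene_model(df[[1]], df[[2]], df[[3]], df[[4]], df[[5]])
  } else {
    stop("gene model must be BED12 or a 5-column TSV (id, chrom, start, end, strand)")
  }
}

#' Read a two-column expression table
#'
#' Tab-separated `gene id, expression` (log2-normalized upstream), no header.
#'
#' @param path File path.
#' @return A named numeric vector.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "expr"),
                          colClasses = c("character", "numeric"))
  if (any(!is.finite(df$expr))) stop("expression values must be finite")
  stats::setNames(df$expr, df$id)
}

## Internal: promoter windows [TSS - w, TSS + w), 0-based half-open,
## clipped at chromosome bounds. TSS is txStart for + genes, txEnd for -.
promoter_windows <- function(model, genome, promoter_window = 3000L) {
  tss0 <- ifelse(model$strand == "+", model$txStart, model$txEnd)
  lens <- GenomeInfoDb::seqlengths(genome)[model$chrom]
  s0 <- pmax(tss0 - promoter_window, 0L)
  e0 <- pmin(tss0 + promoter_window, lens)
  GenomicRanges::GRanges(model$chrom,
                         IRanges::IRanges(start = s0 + 1L, end = e0),
                         seqinfo = genome)
}

#' Classify peaks as promoter / gene body / distal intergenic
#'
#' The TSS of a gene is `txStart` on the plus strand and `txEnd` on the
#' minus strand; the promoter window extends `promoter_window` bp to either
#' side (half-open). A peak overlapping any promoter window is `promoter`
#' (promoter wins ties); otherwise a peak overlapping any transcript span
#' is `gene_body`; otherwise `distal_intergenic`.
#'
#' @param peaks A peak `GRanges`.
#' @param model A `gene_model`.
#' @param promoter_window Half-width of the promoter window in bp
#'   (default 3000).
#' @return A factor of length `length(peaks)` with levels `promoter`,
#'   `gene_body`, `distal_intergenic`.
#' @export
classify_peaks <- function(peaks, model, promoter_window = 3000L) {
  genome <- GenomeInfoDb::seqinfo(peaks)
  lv <- c("promoter", "gene_body", "distal_intergenic")
  if (length(peaks) == 0L) return(factor(character(0), levels = lv))
  prom <- promoter_windows(model, genome, promoter_window)
  body <- GenomicRanges::GRanges(model$chrom,
                                 IRanges::IRanges(start = model$txStart + 1L,
                                                  end = model$txEnd),
                                 seqinfo = genome)
  in_prom <- IRanges::overlapsAny(peaks, prom, ignore.strand = TRUE)
  in_body <- IRanges::overlapsAny(peaks, body, ignore.strand = TRUE)
  factor(ifelse(in_prom, "promoter",
                ifelse(in_body, "gene_body", "distal_intergenic")),
         levels = lv)
}

#' Genes whose promoter is hit by at least one peak
#'
#' @inheritParams classify_peaks
#' @return A character vector of gene ids (set semantics, sorted).
#' @export
promoter_genes <- function(peaks, model, promoter_window = 3000L) {
  if (length(peaks) == 0L) return(character(0))
  prom <- promoter_windows(model, GenomeInfoDb::seqinfo(peaks), promoter_window)
  hit <- IRanges::overlapsAny(prom, peaks, ignore.strand = TRUE)
  sort(unique(model$id[hit]))
}

#' Compare the expression of two gene sets
#'
#' Partitions the two sets into exclusive and shared genes, drops genes
#' missing from the expression table (counted), and compares the expression
#' of the exclusive sets by a two-sided Wilcoxon rank-sum test.
#'
#' @param setA,setB Character vectors of gene ids.
#' @param expr Named numeric expression vector (see [read_expression()]).
#' @return A list: `exclusiveA`, `exclusiveB`, `shared`, `droppedA`,
#'   `droppedB` (counts of genes without expression), `pValue` (`NA` with a
#'   `note` when an exclusive set is empty).
#' @export
compare_gene_sets <- function(setA, setB, expr) {
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  if (length(setA) == 0L || length(setB) == 0L)
    stop("both gene sets must be non-empty")
  droppedA <- sum(!(setA %in% names(expr)))
  droppedB <- sum(!(setB %in% names(expr)))
  setA <- intersect(setA, names(expr))
  setB <- intersect(setB, names(expr))
  shared <- intersect(setA, setB)
  exA <- setdiff(setA, setB); exB <- setdiff(setB, setA)
  if (length(exA) == 0L || length(exB) == 0L) {
    return(list(exclusiveA = exA, exclusiveB = exB, shared = shared,
                droppedA = droppedA, droppedB = droppedB,
                pValue = NA_real_,
                note = "an exclusive set is empty; p-value undefined"))
  }
  p <- stats::wilcox.test(expr[exA], expr[exB], alternative = "two.sided",
                          exact = FALSE)$p.value
  list(exclusiveA = exA, exclusiveB = exB, shared = shared,
       droppedA = droppedA, droppedB = droppedB, pValue = p, note = "")
}
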