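## One-command pipeline: fragments -> peaks -> stage 1 -> stage 2 ->
## optimal peaks, with every artifact written to an output directory and a
## manifest tying outputs to the configuration, seed, package version and
## input checksums. Re-running with the same inputs and seed reproduces
## byte-identical peak files.

#' Run the full two-stage pipeline
#'
#' @param replicates A list (>= 2) of fragment sets (`GRanges`) or file
#'   paths readable by [read_fragments()].
#' @param genome A [GenomeInfoDb::Seqinfo], or a chrom-sizes file path.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @param caller A [caller_config()].
#' @param consistency A [consistency_config()].
#' @param per_set_medians See [ms2pass()].
#' @param comparators If `TRUE`, also write naive-overlap and NOMS consensus
#'   sets for the same replicates.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `status` (0 = success, 2 = no replicate
#'   pair passed stage 1), `stage1`, `stage2`, `optimal` and `files`.
#' @export
mesia_run <- function(replicates, genome, outdir, seed,
                      caller = caller_config(),
                      consistency = consistency_config(),
                      per_set_medians = FALSE,
                      comparators = FALSE,
                      quiet = FALSE) {
  if (missing(seed)) stop("`seed` is mandatory; the pipeline refuses silent nondeterminism")
  seed <- as.integer(seed)
  if (is.character(genome)) genome <- read_chrom_sizes(genome)
  say <- function(...) if (!quiet) message("[mesia] ", ...)
  input_paths <- character(0)
  if (length(replicates) < 2L) stop("at least 2 replicates are required")
  replicates <- lapply(replicates, function(r) {
    if (is.character(r)) {
      input_paths <<- c(input_paths, r)
      read_fragments(r, genome)
    } else r
  })
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(seq_along(replicates), function(i) {
    lb <- S4Vectors::metadata(replicates[[i]])$label
    if (is.null(lb)) sprintf("rep%d", i) else lb
  }, character(1))
  say("stage 1: ", length(replicates), " replicates")
  s1 <- run_stage1(replicates, genome, caller, consistency, seed)
  files <- write_stage1_report(s1, outdir)
  for (i in seq_along(s1$peaks)) {
    f <- file.path(outdir, sprintf("replicate_%s.narrowPeak", labels[i]))
    write_narrowpeak(s1$peaks[[i]], f)
    files <- c(files, f)
  }
  say("stage 1: ", nrow(s1$ms1pass), " pair(s) in MS1pass")
  manifest <- list(
    tool = "mesia", version = as.character(utils::packageVersion("mesia")),
    seed = seed,
    genome = as.list(stats::setNames(as.integer(GenomeInfoDb::seqlengths(genome)),
                                     GenomeInfoDb::seqnames(genome))),
    replicates = labels,
    input_md5 = if (length(input_paths))
      as.list(tools::md5sum(input_paths)) else list(),
    caller = unclass(caller), consistency = unclass(consistency),
    per_set_medians = per_set_medians
  )
  if (nrow(s1$ms1pass) == 0L) {
    say("no reproducible pair; exiting with status 2")
    manifest$status <- 2L
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(status = 2L, stage1 = s1, stage2 = NULL,
                          optimal = NULL, files = files)))
  }
  say("stage 2: filtering and merging")
  s2 <- run_stage2(s1, per_set_medians = per_set_medians)
  for (nm in names(s2$pair_results)) {
    f <- file.path(outdir, sprintf("ms2pass_%s.narrowPeak", nm))
    write_narrowpeak(s2$pair_results[[nm]]$ms2pass, f)
    files <- c(files, f)
  }
  fopt <- file.path(outdir, "mesia_optimal.narrowPeak")
  write_narrowpeak(s2$optimal$peaks, fopt)
  files <- c(files, fopt)
  jsonlite::write_json(
    lapply(seq_along(s2$optimal$provenance), function(i)
      list(peak = S4Vectors::mcols(s2$optimal$peaks)$name[i],
           pairs = s2$optimal$provenance[[i]])),
    file.path(outdir, "optimal_provenance.json"),
    auto_unbox = TRUE, pretty = TRUE)
  if (comparators) {
    say("comparators: naive overlap and NOMS")
    pooled_frags <- Reduce(pool_fragments, replicates)
    pooled_peaks <- call_peaks(pooled_frags, genome, caller)
    nv <- naive_overlap(pooled_peaks, s1$peaks)
    fn <- file.path(outdir, "naive_overlap.narrowPeak")
    write_narrowpeak(nv, fn)
    nm <- noms(s1$peaks)
    fm <- file.path(outdir, "noms.narrowPeak")
    write_narrowpeak(nm, fm)
    files <- c(files, fn, fm)
  }
  say("optimal peaks: ", length(s2$optimal$peaks))
  manifest$status <- 0L
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = 0L, stage1 = s1, stage2 = s2,
                 optimal = s2$optimal, files = files))
}
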