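## Replicate-design simulator. The suite mirrors a benchmark construction
## in which one real peak list is split into three "large sets"; two of
## them are recombined into samples A and B that share a common half of
## their peaks (the "body" peaks) while each keeps its own specific
## ("function") peaks, making the A-B pair non-reproducible by design. The
## remaining large set becomes the unrelated sample C, and samples D-G are
## random subsamples of A and B at 10/30/50/60% whose reproducibility with
## A and B grows with the sampled fraction. Fragment depths are expressed
## as absolute counts: the defaults, 8,000 body and 32,000 function
## fragments, are a 1/100 scale of the 0.8M/3.2M design point at which the
## A-B rescue analysis exceeds 2 (ratios, not magnitudes, drive the rescue
## statistic).

#' Default simulation genome
#'
#' A single 3 Mb chromosome. Together with the default 1,400 seed peaks
#' this places a typical body peak's summit-window midpoint count (about
#' 12-13 at 8,000 body fragments over ~470 body peaks, before the
#' signal-weighted spread) at the built-in caller's detection boundary,
#' reproducing the depth-limited calling regime in which the rescue
#' statistic separates reproducible from non-reproducible pairs: the
#' designed A-B pair shows the consistent-count collapse between true
#' replicates and a rescue ratio well above 2.
#'
#' @param length Chromosome length in bp.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
sim_genome <- function(length = 3e6) genome_spec("chrS", length)

#' Simulation configuration
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param n_seed_peaks Number of non-overlapping seed peaks.
#' @param adjacency_gap Joining distance (bp) when grouping seed peaks into
#'   small sets before the three-way partition.
#' @param body_reads Fragments allocated to a sample's body peaks.
#' @param function_reads Fragments allocated to a sample's function peaks.
#' @param fractions Named sampling fractions for samples D-G.
#' @param background_fraction Extra uniform-background fragments as a
#'   fraction of `body_reads + function_reads`.
#' @param fragment_meanlog,fragment_sdlog Lognormal fragment-length model.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome = sim_genome(), n_seed_peaks = 1400L,
                       adjacency_gap = 1000L,
                       body_reads = 8000L, function_reads = 32000L,
                       fractions = c(D = 0.10, E = 0.30, F = 0.50, G = 0.60),
                       background_fraction = 0.05,
                       fragment_meanlog = log(120), fragment_sdlog = 0.35) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("sampling fractions must lie in (0, 1)")
  if (body_reads <= 0 || function_reads <= 0) stop("read counts must be positive")
  structure(list(genome = genome, n_seed_peaks = as.integer(n_seed_peaks),
                 adjacency_gap = as.integer(adjacency_gap),
                 body_reads = as.integer(body_reads),
                 function_reads = as.integer(function_reads),
                 fractions = fractions,
                 background_fraction = background_fraction,
                 fragment_meanlog = fragment_meanlog,
                 fragment_sdlog = fragment_sdlog),
            class = "sim_config")
}

#' Generate non-overlapping seed peaks
#'
#' Widths are lognormal with median 400 bp (clamped to 150-2000 bp),
#' summits uniform within each peak, `qLog10` exponential with mean 3.
#' Peaks are placed left to right with random gaps of at least 100 bp,
#' allocated across chromosomes proportionally to length.
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param n Number of peaks.
#' @param seed Integer seed.
#' @return A peak `GRanges` of `n` mutually non-overlapping peaks.
#' @export
make_seed_peaks <- function(genome, n, seed) {
  if (n == 0L) return(empty_peak_set(genome))
  lens <- GenomeInfoDb::seqlengths(genome)
  alloc <- round(n * as.numeric(lens) / sum(as.numeric(lens)))
  alloc[1] <- alloc[1] + (n - sum(alloc))
  withr::with_seed(as.integer(seed), {
    chrom <- character(0); st <- integer(0); en <- integer(0)
    for (ci in seq_along(lens)) {
      nc <- alloc[ci]
      if (nc <= 0L) next
      L <- lens[[ci]]
      w <- pmin(pmax(round(stats::rlnorm(nc, log(400), 0.3)), 150L), 2000L)
      mingap <- 100L
      free <- L - sum(w) - (nc + 1L) * mingap
      if (free < 0) stop("cannot place ", nc, " non-overlapping peaks on ",
                         names(lens)[ci])
      extra <- as.vector(stats::rmultinom(1, free, rep(1, nc + 1L)))
      gaps <- mingap + extra
      starts <- cumsum(gaps[-(nc + 1L)]) + c(0L, cumsum(w[-nc]))
      chrom <- c(chrom, rep(names(lens)[ci], nc))
      st <- c(st, as.integer(starts)); en <- c(en, as.integer(starts + w))
    }
    w_all <- en - st
    qv <- stats::rexp(n, rate = 1 / 3)
    peak_set(chrom, st, en, genome,
             name = sprintf("sim_peak_%d", seq_len(n)),
             score = pmin(1000L, as.integer(round(qv * 100))),
             signal = 1 + qv * stats::runif(n, 0.8, 1.2),
             pLog10 = qv + stats::runif(n, 0, 0.5),
             qLog10 = qv,
             summit = as.integer(floor(stats::runif(n) * w_all)))
  })
}

#' Partition seed peaks into three large sets
#'
#' Seed peaks within `gap` bp of one another are joined into small sets;
#' small sets are randomly assigned to three groups of near-equal small-set
#' counts (sizes differ by at most 1); each group is then expanded back to
#' its member peaks.
#'
#' @param seed_peaks A peak `GRanges`.
#' @param gap Joining distance in bp.
#' @param seed Integer seed.
#' @return A list of three peak `GRanges` (`L1`, `L2`, `L3`) that partition
#'   `seed_peaks`.
#' @export
partition_large_sets <- function(seed_peaks, gap, seed) {
  red <- GenomicRanges::reduce(GenomicRanges::granges(seed_peaks),
                               min.gapwidth = gap + 1L, with.revmap = TRUE,
                               ignore.strand = TRUE)
  nsmall <- length(red)
  if (nsmall < 3L) stop("fewer than 3 small sets; decrease `gap` or add peaks")
  grp <- withr::with_seed(as.integer(seed),
                          sample(rep_len(1:3, nsmall)))
  revmap <- S4Vectors::mcols(red)$revmap
  take <- function(g) {
    idx <- sort(unlist(as.list(revmap[grp == g])))
    seed_peaks[idx]
  }
  list(L1 = take(1L), L2 = take(2L), L3 = take(3L))
}

## Internal: draw a fragment set for a truth peak list. Fragments are
## allocated to peaks multinomially with weights proportional to the truth
## signal (peak strengths span an order of magnitude, as in real ATAC
## data); midpoints are triangular around each truth summit with
## half-width equal to the peak half-width, fragment lengths lognormal,
## plus a uniform background component. Consumes the RNG stream; callers
## wrap in withr::with_seed().
sample_fragments <- function(truth, body_names, config, label,
                             ref_depths = NULL) {
  genome <- config$genome
  lens <- GenomeInfoDb::seqlengths(genome)
  mc <- S4Vectors::mcols(truth)
  is_body <- mc$name %in% body_names
  counts <- integer(length(truth))
  draw <- function(total, idx) {
    if (total > 0L && length(idx) > 0L)
      counts[idx] <<- counts[idx] +
        as.vector(stats::rmultinom(1, total, mc$signal[idx]))
  }
  if (is.null(ref_depths)) {
    budget_body <- config$body_reads
    budget_func <- config$function_reads
  } else {
    # subsamples inherit their parents' per-peak depths: a thinner peak
    # universe must not concentrate the full read budget
    budget_body <- as.integer(round(ref_depths$body * sum(is_body)))
    budget_func <- as.integer(round(ref_depths$func * sum(!is_body)))
  }
  n_total <- budget_body + budget_func
  if (any(is_body) && any(!is_body)) {
    draw(budget_body, which(is_body))
    draw(budget_func, which(!is_body))
  } else {
    draw(n_total, seq_along(truth))   # single-kind samples get the full budget
  }
  pk <- rep(seq_along(truth), counts)
  nfrag <- length(pk)
  summit_abs <- start0(truth)[pk] + mc$summit[pk]
  half <- GenomicRanges::width(truth)[pk] / 2
  tri <- round((stats::runif(nfrag) + stats::runif(nfrag) - 1) * half)
  chrom <- as.character(GenomeInfoDb::seqnames(truth))[pk]
  mid <- pmin(pmax(summit_abs + tri, 0L), lens[chrom] - 1L)
  nbg <- round(config$background_fraction * n_total)
  if (nbg > 0L) {
    bg_chrom <- sample(names(lens), nbg, replace = TRUE,
                       prob = as.numeric(lens) / sum(as.numeric(lens)))
    bg_mid <- floor(stats::runif(nbg) * (lens[bg_chrom] - 1L))
    chrom <- c(chrom, bg_chrom)
    mid <- c(mid, bg_mid)
  }
  n_all <- length(mid)
  len <- pmax(50L, as.integer(round(stats::rlnorm(n_all, config$fragment_meanlog,
                                                  config$fragment_sdlog))))
  s0 <- pmax(mid - len %/% 2L, 0L)
  e0 <- pmin(s0 + len, lens[chrom])
  s0 <- pmin(s0, e0 - 1L)
  ord <- order(match(chrom, names(lens)), s0, e0)
  fragment_set(chrom[ord], s0[ord], e0[ord], genome, label = label)
}

#' Compose the seven-sample simulation suite
#'
#' Builds samples A-G from three large sets: the body peaks are a random
#' half of `L1` and `L2`'s union, shared verbatim by A and B; A keeps the
#' remaining `L1` peaks and B the remaining `L2` peaks as their function
#' peaks; C is `L3`; D-G are per-fraction random subsamples of A's and B's
#' peak sets (union of the two draws), whose reproducibility with A and B
#' grows with the sampled fraction. Each sample receives a seeded fragment
#' set at the configured depths.
#'
#' @param L1,L2,L3 Peak `GRanges` from [partition_large_sets()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `sim_suite`: `samples` (named list `A`-`G`, each
#'   with `truth` and `fragments`), `body_peaks`, `large_sets`, `config`,
#'   `seed`.
#' @export
compose_samples <- function(L1, L2, L3, config, seed) {
  genome <- config$genome
  withr::with_seed(as.integer(seed), {
    ab <- sort_peaks(c(L1, L2))
    nm <- S4Vectors::mcols(ab)$name
    body_names <- sample(nm, length(ab) %/% 2L)
    in_body <- nm %in% body_names
    body <- ab[in_body]
    l1_names <- S4Vectors::mcols(L1)$name
    func_a <- ab[!in_body & nm %in% l1_names]
    func_b <- ab[!in_body & !(nm %in% l1_names)]
    truth <- list(
      A = sort_peaks(c(body, func_a)),
      B = sort_peaks(c(body, func_b)),
      C = L3
    )
    union_ab <- sort_peaks(c(truth$A, truth$B[!(S4Vectors::mcols(truth$B)$name %in%
                                                  S4Vectors::mcols(truth$A)$name)]))
    subsample <- function(f) {
      pick <- function(x) {
        k <- round(f * length(x))
        S4Vectors::mcols(x)$name[sample(length(x), k)]
      }
      sel <- unique(c(pick(truth$A), pick(truth$B)))
      union_ab[S4Vectors::mcols(union_ab)$name %in% sel]
    }
    for (lbl in names(config$fractions))
      truth[[lbl]] <- subsample(config$fractions[[lbl]])
    ref_depths <- list(
      body = config$body_reads / length(body),
      func = config$function_reads / mean(c(length(func_a), length(func_b)))
    )
    samples <- lapply(names(truth), function(lbl) {
      ref <- if (lbl %in% names(config$fractions)) ref_depths else NULL
      list(truth = truth[[lbl]],
           fragments = sample_fragments(truth[[lbl]], body_names, config,
                                        label = lbl, ref_depths = ref))
    })
    names(samples) <- names(truth)
    structure(list(samples = samples, body_peaks = body,
                   large_sets = list(L1 = L1, L2 = L2, L3 = L3),
                   body_names = body_names, ref_depths = ref_depths,
                   config = config, seed = as.integer(seed)),
              class = "sim_suite")
  })
}

#' Build the full simulation suite from a configuration
#'
#' Convenience wrapper: seed peaks, three-way partition, sample
#' composition, all derived deterministically from one seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `sim_suite` (see [compose_samples()]).
#' @export
simulate_suite <- function(config = sim_config(), seed = 1L) {
  seed <- as.integer(seed)
  sp <- make_seed_peaks(config$genome, config$n_seed_peaks, seed)
  ls <- partition_large_sets(sp, config$adjacency_gap, seed + 1L)
  suite <- compose_samples(ls$L1, ls$L2, ls$L3, config, seed + 2L)
  suite$seed_peaks <- sp
  suite
}

#' Draw replicate fragment sets from one sample's truth peaks
#'
#' Independent fragment draws over the same truth peak list; such
#' replicates are exchangeable and should pass stage 1 against each other.
#'
#' @param suite A `sim_suite`.
#' @param label Sample label (`"A"` ... `"G"`).
#' @param n Number of replicate draws.
#' @param seed Integer seed; draw `k` uses `seed + k`.
#' @return A list of `n` fragment sets.
#' @export
replicate_fragments <- function(suite, label, n, seed) {
  truth <- suite$samples[[label]]$truth
  ref <- if (label %in% names(suite$config$fractions)) suite$ref_depths else NULL
  lapply(seq_len(n), function(k)
    withr::with_seed(as.integer(seed) + k,
      sample_fragments(truth, suite$body_names, suite$config,
                       label = sprintf("%s_rep%d", label, k),
                       ref_depths = ref)))
}

#' Replicate lists for the named benchmark states
#'
#' Reproducibility states pair A and B with one of their subsamples:
#' `standard` uses F (50% overlap), `hard` uses E (30%), `soft` uses G
#' (60%). Replication-count states vary how many exchangeable pairs enter
#' stage 1: `strong` draws four F-like replicates (6 expected passing
#' pairs), `normal` three (3 pairs), `weak` two plus the unrelated sample C
#' (1 pair).
#'
#' @param suite A `sim_suite`.
#' @param state One of `"standard"`, `"hard"`, `"soft"`, `"strong"`,
#'   `"normal"`, `"weak"`.
#' @param seed Integer seed (used by the replicate-drawing states).
#' @return A named list of fragment sets.
#' @export
state_suite <- function(suite,
                        state = c("standard", "hard", "soft",
                                  "strong", "normal", "weak"),
                        seed = 1L) {
  state <- match.arg(state)
  frag <- function(lbl) suite$samples[[lbl]]$fragments
  switch(state,
    standard = list(A = frag("A"), B = frag("B"), F = frag("F")),
    hard     = list(A = frag("A"), B = frag("B"), E = frag("E")),
    soft     = list(A = frag("A"), B = frag("B"), G = frag("G")),
    strong   = stats::setNames(replicate_fragments(suite, "F", 4L, seed),
                               sprintf("F%d", 1:4)),
    normal   = stats::setNames(replicate_fragments(suite, "F", 3L, seed),
                               sprintf("F%d", 1:3)),
    weak     = c(stats::setNames(replicate_fragments(suite, "F", 2L, seed),
                                 c("F1", "F2")),
                 list(C = frag("C")))
  )
}

## Internal: stage-1 pair metrics only (no self-consistency), used by the
## depth grid.
stage1_pair_metrics <- function(fsA, fsB, genome, caller, consistency, seed) {
  pa <- call_peaks(fsA, genome, caller)
  pb <- call_peaks(fsB, genome, caller)
  nt <- count_consistent(pa, pb, consistency)$count
  pooled <- pool_fragments(fsA, fsB)
  halves <- split_pseudoreplicates(pooled, seed)
  np <- count_consistent(call_peaks(halves$pseudo1, genome, caller),
                         call_peaks(halves$pseudo2, genome, caller),
                         consistency)$count
  rescue <- if (nt > 0L && np > 0L) rescue_ratio(nt, np) else NA_real_
  c(nt = nt, np = np, rescue = rescue)
}

#' Rescue-analysis grid over body/function depths
#'
#' Rebuilds the A/B fragment sets of a suite at every combination of body
#' and function depth and tabulates Np, Nt and the rescue ratio, scanning
#' the regime in which the consistent-peak count between true replicates
#' stabilizes once the function depth passes a multiple of the body depth.
#'
#' @param suite A `sim_suite`.
#' @param body_levels,function_levels Integer fragment-count levels.
#' @param seed Integer seed.
#' @param caller A [caller_config()].
#' @param consistency A [consistency_config()].
#' @return A data.frame with columns `body`, `fun`, `np`, `nt`, `rescue`.
#' @export
table_grid <- function(suite, body_levels, function_levels, seed = 1L,
                       caller = caller_config(),
                       consistency = consistency_config()) {
  if (length(body_levels) == 0L || length(function_levels) == 0L)
    stop("depth grid must be non-empty")
  cfg <- suite$config
  grid <- expand.grid(body = body_levels, fun = function_levels)
  out <- grid; out$np <- NA_integer_; out$nt <- NA_integer_; out$rescue <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cfg_r <- cfg
    cfg_r$body_reads <- as.integer(grid$body[r])
    cfg_r$function_reads <- as.integer(grid$fun[r])
    fsA <- withr::with_seed(as.integer(seed) + 2L * r,
      sample_fragments(suite$samples$A$truth, suite$body_names, cfg_r, "A"))
    fsB <- withr::with_seed(as.integer(seed) + 2L * r + 1L,
      sample_fragments(suite$samples$B$truth, suite$body_names, cfg_r, "B"))
    m <- stage1_pair_metrics(fsA, fsB, cfg$genome, caller, consistency,
                             seed = as.integer(seed) + 10000L + r)
    out$nt[r] <- m[["nt"]]; out$np[r] <- m[["np"]]; out$rescue[r] <- m[["rescue"]]
  }
  out
}
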