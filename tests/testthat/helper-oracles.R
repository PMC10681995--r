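# Brute-force per-base oracles and small fixture builders. The oracles
# represent intervals as logical occupancy vectors over a short chromosome,
# so every interval operation reduces to elementwise boolean algebra; they
# are deliberately independent of the package's IRanges-based code paths.

tiny_genome <- function(len = 10000L, chrom = "chrT") genome_spec(chrom, len)

# occupancy vector of a peak set on a single-chrom genome (0-based coords:
# base b is covered iff cover[b + 1])
oracle_cover <- function(starts, ends, len) {
  v <- logical(len)
  for (k in seq_along(starts)) {
    if (ends[k] > starts[k]) v[(starts[k] + 1):ends[k]] <- TRUE
  }
  v
}

# connected TRUE runs of an occupancy vector -> data.frame(start, end), 0-based
oracle_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

cover_of <- function(ps, len) {
  oracle_cover(GenomicRanges::start(ps) - 1L, GenomicRanges::end(ps), len)
}

random_regions <- function(n, len, max_w = 400L) {
  s <- sample.int(len - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(start = s, end = pmin(s + w, len))
}

make_region_set <- function(df, genome) {
  len <- genome_length(genome)
  peak_set(rep(GenomeInfoDb::seqnames(genome)[1], nrow(df)), df$start, df$end,
           genome)
}

# random attributed peaks (non-degenerate narrowPeak records)
random_peaks <- function(n, genome, max_w = 400L) {
  len <- genome_length(genome)
  df <- random_regions(n, len, max_w)
  w <- df$end - df$start
  peak_set(rep(GenomeInfoDb::seqnames(genome)[1], n), df$start, df$end, genome,
           name = sprintf("rp%d", seq_len(n)),
           score = sample.int(1000, n),
           signal = round(stats::runif(n, 1, 50), 3),
           pLog10 = round(stats::rexp(n, 1 / 4), 3),
           qLog10 = round(stats::rexp(n, 1 / 3), 3),
           summit = vapply(w, function(x) sample.int(x, 1) - 1L, integer(1)))
}

# fragment set with midpoints clustered at given positions
clustered_fragments <- function(centers, n_per, genome, spread = 50L, frag_len = 100L) {
  len <- genome_length(genome)
  mids <- unlist(lapply(centers, function(cc)
    pmin(pmax(cc + sample(seq(-spread, spread), n_per, replace = TRUE), 60L),
         len - 60L)))
  s0 <- mids - frag_len %/% 2L
  fragment_set(rep(GenomeInfoDb::seqnames(genome)[1], length(mids)),
               s0, s0 + frag_len, genome, label = "clustered")
}

uniform_fragments <- function(n, genome, frag_len = 100L, label = "uniform") {
  len <- genome_length(genome)
  s0 <- sample.int(len - frag_len, n, replace = TRUE) - 1L
  fragment_set(rep(GenomeInfoDb::seqnames(genome)[1], n), s0, s0 + frag_len,
               genome, label = label)
}
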