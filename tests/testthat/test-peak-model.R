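# Peak container, narrowPeak I/O and interval algebra.

test_that("narrowPeak reader maps fields, handles '.' scores and empty files", {
  g <- genome_spec("chr1", 1e6)
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tp1\t0\t.\t5.0\t3.0\t2.0\t50", f)
  ps <- read_narrowpeak(f, g)
  expect_equal(length(ps), 1L)
  expect_equal(GenomicRanges::start(ps), 101L)  # 0-based 100 -> 1-based 101
  expect_equal(GenomicRanges::end(ps), 200L)
  expect_equal(ps$signal, 5.0)
  expect_equal(ps$pLog10, 3.0)
  expect_equal(ps$qLog10, 2.0)
  expect_equal(ps$summit, 50L)

  writeLines("chr1\t10\t20\tp2\t.\t.\t1\t1\t1\t-1", f)
  expect_equal(read_narrowpeak(f, g)$score, 0L)

  writeLines(character(0), f)
  expect_equal(length(read_narrowpeak(f, g)), 0L)
})

test_that("narrowPeak reader rejects malformed records with line numbers", {
  g <- genome_spec("chr1", 1e6)
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t1\t2\ta\t0\t.\t1\t1\t1\t0",
               "chr1\t5\t9\tb\t0\t.\t1\t1"), f)
  expect_error(read_narrowpeak(f, g), "line 2.*10 tab-separated")
  writeLines("chr1\t200\t100\ta\t0\t.\t1\t1\t1\t0", f)
  expect_error(read_narrowpeak(f, g), "line 1.*start")
  writeLines("chrZ\t100\t200\ta\t0\t.\t1\t1\t1\t0", f)
  expect_error(read_narrowpeak(f, g), "unknown chromosome")
  expect_warning(ps <- read_narrowpeak(f, g, lenient = TRUE), "skipped")
  expect_equal(length(ps), 0L)
})

test_that("write/read round trip is byte-identical for canonical files", {
  withr::local_seed(41)
  g <- tiny_genome(50000L)
  ps <- random_peaks(40, g)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_narrowpeak(ps, f1)
  write_narrowpeak(read_narrowpeak(f1, g), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("peak constructor enforces the record invariants", {
  g <- genome_spec("chr1", 1000)
  expect_error(peak_set("chr1", 10, 10, g), "start")
  expect_error(peak_set("chr1", 10, 2000, g), "beyond chromosome end")
  expect_error(peak_set("chr1", 10, 100, g, summit = 90), "summit")
  expect_error(peak_set("chr1", 10, 100, g, qLog10 = -1), "qLog10")
  ok <- peak_set("chr1", 10, 100, g, summit = 89)
  expect_equal(length(ok), 1L)
})

test_that("intersection matches the hand examples and rejects genome mismatch", {
  g <- tiny_genome(1000L)
  a <- make_region_set(data.frame(start = 0, end = 100), g)
  b <- make_region_set(data.frame(start = 50, end = 150), g)
  r <- intersect_regions(a, b)
  expect_equal(GenomicRanges::start(r) - 1L, 50L)
  expect_equal(GenomicRanges::end(r), 100L)

  d <- make_region_set(data.frame(start = 500, end = 600), g)
  expect_equal(length(intersect_regions(a, d)), 0L)

  a2 <- make_region_set(data.frame(start = c(0, 20), end = c(10, 30)), g)
  b2 <- make_region_set(data.frame(start = 5, end = 25), g)
  r2 <- intersect_regions(a2, b2)
  expect_equal(GenomicRanges::start(r2) - 1L, c(5L, 20L))
  expect_equal(GenomicRanges::end(r2), c(10L, 25L))

  g2 <- genome_spec("chrX", 1000)
  x <- make_region_set(data.frame(start = 0, end = 10), g2)
  expect_error(intersect_regions(a, x), "different genomes")
})

test_that("merge handles bookended intervals and aggregates attributes", {
  g <- tiny_genome(1000L)
  a <- make_region_set(data.frame(start = c(0, 10), end = c(10, 20)), g)
  m <- merge_regions(a, gap = 0)
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::end(m), 20L)

  b <- make_region_set(data.frame(start = c(0, 15), end = c(10, 20)), g)
  expect_equal(length(merge_regions(b, gap = 0)), 2L)
  expect_equal(length(merge_regions(b, gap = 5)), 1L)

  # attribute aggregation: max q/signal, summit from the strongest member
  p <- peak_set(c("chrT", "chrT"), c(0, 5), c(10, 25), g,
                signal = c(2, 9), qLog10 = c(7, 3), summit = c(4, 15))
  m2 <- merge_regions(p, gap = 0)
  expect_equal(m2$qLog10, 7)
  expect_equal(m2$signal, 9)
  expect_equal(m2$summit, 20L)  # absolute 5 + 15, relative to merged start 0
})

test_that("interval algebra agrees with the per-base oracle on random instances", {
  withr::local_seed(42)
  g <- tiny_genome(10000L)
  len <- 10000L
  for (rep in 1:40) {
    a <- make_region_set(random_regions(sample(1:30, 1), len), g)
    b <- make_region_set(random_regions(sample(1:30, 1), len), g)
    va <- cover_of(a, len); vb <- cover_of(b, len)

    ri <- intersect_regions(a, b)
    expect_identical(cover_of(ri, len), va & vb)

    gap <- sample(0:50, 1)
    rm_ <- merge_regions(a, gap = gap)
    # oracle: right-dilate every interval end by `gap`; boolean runs then
    # fuse exactly when the separation is <= gap; snap each fused run back
    # to the extent of the original cover inside it
    s0a <- GenomicRanges::start(a) - 1L
    e0a <- pmin(GenomicRanges::end(a) + gap, len)
    vg <- oracle_cover(s0a, e0a, len)
    mr <- oracle_runs(vg)
    vm <- logical(len)
    if (nrow(mr)) for (k in seq_len(nrow(mr))) {
      members <- which(va[(mr$start[k] + 1):mr$end[k]]) + mr$start[k]
      if (length(members)) vm[min(members):max(members)] <- TRUE
    }
    expect_identical(cover_of(rm_, len), vm)

    t1 <- a[1]
    frac <- coverage_fraction(t1, b)
    tg <- cover_of(t1, len)
    expect_equal(frac, sum(tg & vb) / sum(tg))

    if (any(va) || any(vb)) {
      expect_equal(jaccard(a, b), sum(va & vb) / sum(va | vb))
    }
  }
})

test_that("merge is idempotent and intersection is a per-base subset of both inputs", {
  withr::local_seed(7)
  g <- tiny_genome(10000L)
  for (rep in 1:10) {
    a <- make_region_set(random_regions(25, 10000L), g)
    b <- make_region_set(random_regions(25, 10000L), g)
    m1 <- merge_regions(a, 0)
    m2 <- merge_regions(m1, 0)
    expect_equal(GenomicRanges::ranges(m1), GenomicRanges::ranges(m2))
    vi <- cover_of(intersect_regions(a, b), 10000L)
    expect_true(all(vi <= cover_of(a, 10000L)))
    expect_true(all(vi <= cover_of(b, 10000L)))
  }
})

test_that("jaccard hits the hand values and rejects the empty-empty case", {
  g <- tiny_genome(1000L)
  a <- make_region_set(data.frame(start = 0, end = 100), g)
  b <- make_region_set(data.frame(start = 50, end = 150), g)
  expect_equal(jaccard(a, a), 1.0)
  expect_equal(jaccard(a, b), 50 / 150)
  d <- make_region_set(data.frame(start = 500, end = 600), g)
  expect_equal(jaccard(a, d), 0.0)
  e <- empty_peak_set(g)
  expect_error(jaccard(e, e), "undefined")
})

test_that("chrom-sizes reader and genome invariants", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t1000", "chr2\t2000"), f)
  g <- read_chrom_sizes(f)
  expect_equal(genome_length(g), 3000)
  expect_error(genome_spec(c("a", "a"), c(1, 2)), "unique")
  expect_error(genome_spec("a", 0), "positive")
})
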