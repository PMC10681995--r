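# Base peaks, the median significance filter, MS2pass and the optimal merge.

test_that("base peaks inherit attributes with the summit clipped into the interval", {
  g <- tiny_genome(1000L)
  nt <- peak_set("chrT", 0, 100, g, qLog10 = 3, summit = 50L, signal = 4)
  np <- make_region_set(data.frame(start = 50, end = 150), g)
  bp <- base_peaks(nt, np)
  expect_equal(bp$n, 1L)
  expect_equal(GenomicRanges::start(bp$bp) - 1L, 50L)
  expect_equal(GenomicRanges::end(bp$bp), 100L)
  expect_equal(bp$bp$qLog10, 3)
  expect_equal(bp$bp$summit, 0L)   # original summit 50 clips to the interval start

  bp2 <- base_peaks(nt, nt)
  expect_equal(GenomicRanges::ranges(bp2$bp), GenomicRanges::ranges(nt))

  far <- make_region_set(data.frame(start = 500, end = 600), g)
  expect_equal(base_peaks(nt, far)$n, 0L)
  expect_warning(base_peaks(empty_peak_set(g), np), "empty")
})

test_that("the significance filter keeps the upper-median quadrant inclusively", {
  g <- tiny_genome(10000L)
  starts <- seq(0L, by = 500L, length.out = 5L)
  pk <- peak_set(rep("chrT", 5), starts, starts + 100L, g,
                 qLog10 = 1:5, summit = c(10L, 20L, 30L, 40L, 50L))
  kept <- sig_filter(pk, 30, 3)
  expect_equal(length(kept), 3L)
  expect_true(all(kept$summit >= 30 & kept$qLog10 >= 3))

  # all identical values: boundary is inclusive, everything passes
  same <- peak_set(rep("chrT", 4), starts[1:4], starts[1:4] + 100L, g,
                   qLog10 = 2, summit = 50L)
  expect_equal(length(sig_filter(same, 50, 2)), 4L)

  expect_equal(length(sig_filter(empty_peak_set(g), 1, 1)), 0L)
  unk <- peak_set("chrT", 0, 100, g, qLog10 = 9, summit = -1L)
  expect_warning(out <- sig_filter(unk, 0, 0), "unknown summit")
  expect_equal(length(out), 0L)
})

test_that("rank-aligned distinct values keep exactly the upper-median count", {
  withr::local_seed(73)
  g <- tiny_genome(1e6)
  for (n in c(5L, 8L, 13L, 20L)) {
    starts <- seq(0L, by = 1000L, length.out = n)
    pp <- sort(sample(1:400, n))
    qv <- sort(stats::runif(n, 1, 50))
    pk <- peak_set(rep("chrT", n), starts, starts + 450L, g,
                   qLog10 = qv, summit = pp)
    mpp <- sort(pp)[(n + 1L) %/% 2L]
    mqv <- sort(qv)[(n + 1L) %/% 2L]
    kept <- sig_filter(pk, mpp, mqv)
    expect_equal(length(kept), n - (n + 1L) %/% 2L + 1L)
  }
})

test_that("ms2pass equals the brute-force filter-then-union oracle", {
  withr::local_seed(79)
  g <- tiny_genome(100000L)
  for (rep in 1:10) {
    nt <- random_peaks(50, g)
    np <- make_region_set(random_regions(40, 100000L), g)
    bp <- suppressWarnings(base_peaks(nt, np))
    if (bp$n == 0L) next
    spI <- random_peaks(30, g)
    spJ <- random_peaks(30, g)
    res <- ms2pass(bp, spI, spJ)
    # oracle: filter each set independently by the base-peak medians
    keep <- function(ps) {
      mc <- S4Vectors::mcols(ps)
      ps[mc$summit != -1L & mc$summit >= bp$medianPP & mc$qLog10 >= bp$medianQV]
    }
    oracle <- c(keep(bp$bp), keep(spI), keep(spJ))
    expect_equal(length(res$ms2pass), length(oracle))
    expect_identical(sort(GenomicRanges::start(res$ms2pass)),
                     sort(GenomicRanges::start(oracle)))
    # cover containment
    vo <- cover_of(res$ms2pass, 100000L)
    vin <- cover_of(bp$bp, 100000L) | cover_of(spI, 100000L) | cover_of(spJ, 100000L)
    expect_true(all(vo <= vin))
  }
})

test_that("optimal peaks are the per-base union of all MS2pass covers with provenance", {
  withr::local_seed(83)
  g <- tiny_genome(50000L)
  mk <- function(df) {
    ps <- make_region_set(df, g)
    structure(list(sigBP = ps, sigSP_i = ps, sigSP_j = ps, ms2pass = ps),
              class = "mesia_stage2_pair")
  }
  r1 <- mk(data.frame(start = 0, end = 10))
  r2 <- mk(data.frame(start = 5, end = 20))
  r3 <- mk(data.frame(start = 30, end = 40))
  opt <- mesia_optimal(list(r1, r2, r3), pair_labels = c("p1", "p2", "p3"))
  expect_equal(GenomicRanges::start(opt$peaks) - 1L, c(0L, 30L))
  expect_equal(GenomicRanges::end(opt$peaks), c(20L, 40L))
  expect_identical(opt$provenance[[1]], c("p1", "p2"))
  expect_identical(opt$provenance[[2]], "p3")

  # idempotence: two identical results give the same cover as one
  opt2 <- mesia_optimal(list(r1, r1))
  expect_equal(GenomicRanges::ranges(opt2$peaks),
               GenomicRanges::ranges(mesia_optimal(list(r1))$peaks))

  # random instances against the per-base union oracle
  for (rep in 1:10) {
    rs <- lapply(1:3, function(i) mk(random_regions(10, 50000L)))
    opt3 <- mesia_optimal(rs)
    vu <- Reduce(`|`, lapply(rs, function(r) cover_of(r$ms2pass, 50000L)))
    expect_identical(cover_of(opt3$peaks, 50000L), vu)
  }
})

test_that("lower median follows the attainable-element convention", {
  expect_equal(mesia:::lower_median(c(5, 1, 3)), 3)
  expect_equal(mesia:::lower_median(c(4, 1, 3, 2)), 2)
  expect_equal(mesia:::lower_median(7), 7)
  expect_true(is.na(mesia:::lower_median(numeric(0))))
})
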