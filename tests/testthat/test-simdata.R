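# The replicate-design simulator: seed peaks, partition, sample composition.

small_cfg <- function() sim_config(genome = genome_spec("chrS", 8e5),
                                   n_seed_peaks = 300L,
                                   body_reads = 3000L, function_reads = 6000L)

test_that("seed peaks are non-overlapping, seeded and bounded", {
  cfg <- small_cfg()
  sp <- make_seed_peaks(cfg$genome, 300L, seed = 5)
  expect_equal(length(sp), 300L)
  expect_false(any(GenomicRanges::countOverlaps(sp, sp) > 1))
  expect_true(all(sp$summit >= 0 & sp$summit < GenomicRanges::width(sp)))
  sp2 <- make_seed_peaks(cfg$genome, 300L, seed = 5)
  expect_identical(GenomicRanges::ranges(sp), GenomicRanges::ranges(sp2))
  expect_equal(length(make_seed_peaks(cfg$genome, 0L, seed = 5)), 0L)
  expect_error(make_seed_peaks(genome_spec("c", 1e4), 100L, seed = 1),
               "cannot place")
})

test_that("the three large sets partition the seed peaks with balanced small-set counts", {
  cfg <- small_cfg()
  sp <- make_seed_peaks(cfg$genome, 300L, seed = 7)
  ls <- partition_large_sets(sp, gap = cfg$adjacency_gap, seed = 8)
  expect_setequal(
    c(ls$L1$name, ls$L2$name, ls$L3$name),
    sp$name
  )
  expect_equal(length(ls$L1) + length(ls$L2) + length(ls$L3), 300L)
  # peaks closer than the gap stay in one large set
  red <- GenomicRanges::reduce(GenomicRanges::granges(sp),
                               min.gapwidth = cfg$adjacency_gap + 1L,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  grp_of <- integer(length(sp))
  for (k in 1:3) grp_of[match(ls[[k]]$name, sp$name)] <- k
  for (ss in as.list(revmap)) expect_equal(length(unique(grp_of[ss])), 1L)
})

test_that("samples A and B share exactly the body peaks and D-G are read fractions", {
  cfg <- small_cfg()
  suite <- simulate_suite(cfg, seed = 9)
  tA <- suite$samples$A$truth; tB <- suite$samples$B$truth
  shared <- intersect(tA$name, tB$name)
  expect_setequal(shared, suite$body_peaks$name)
  # C is the remaining large set
  expect_setequal(suite$samples$C$truth$name, suite$large_sets$L3$name)
  # D-G: peak subsamples of the A-B union at their configured fractions
  nAB <- length(unique(c(tA$name, tB$name)))
  for (lbl in names(cfg$fractions)) {
    f <- cfg$fractions[[lbl]]
    n_l <- length(suite$samples[[lbl]]$truth)
    # union of an f-draw from A and an f-draw from B: between f and 2f of the union
    expect_gt(n_l, 0.8 * f * nAB)
    expect_lt(n_l, 2.4 * f * nAB)
    expect_true(all(suite$samples[[lbl]]$truth$name %in% c(tA$name, tB$name)))
  }
})

test_that("fragment counts are conserved at the configured depths", {
  cfg <- small_cfg()
  suite <- simulate_suite(cfg, seed = 13)
  n_exp <- cfg$body_reads + cfg$function_reads
  bg <- round(cfg$background_fraction * n_exp)
  for (lbl in c("A", "B", "C")) {
    expect_equal(length(suite$samples[[lbl]]$fragments), n_exp + bg)
  }
})

test_that("suite generation is deterministic by seed", {
  cfg <- small_cfg()
  s1 <- simulate_suite(cfg, seed = 21)
  s2 <- simulate_suite(cfg, seed = 21)
  expect_identical(GenomicRanges::ranges(s1$samples$A$fragments),
                   GenomicRanges::ranges(s2$samples$A$fragments))
  expect_identical(s1$body_names, s2$body_names)
  s3 <- simulate_suite(cfg, seed = 22)
  expect_false(identical(GenomicRanges::ranges(s1$samples$A$fragments),
                         GenomicRanges::ranges(s3$samples$A$fragments)))
})

test_that("state suites map to the documented samples and replicate counts", {
  cfg <- small_cfg()
  suite <- simulate_suite(cfg, seed = 17)
  hard <- state_suite(suite, "hard", seed = 1)
  expect_identical(names(hard), c("A", "B", "E"))
  expect_identical(S4Vectors::metadata(hard$E)$label, "E")
  soft <- state_suite(suite, "soft", seed = 1)
  expect_identical(names(soft), c("A", "B", "G"))
  expect_equal(length(state_suite(suite, "strong", seed = 1)), 4L)
  expect_equal(length(state_suite(suite, "normal", seed = 1)), 3L)
  weak <- state_suite(suite, "weak", seed = 1)
  expect_equal(length(weak), 3L)
  expect_identical(names(weak)[3], "C")
  expect_error(state_suite(suite, "nope"), "arg")
})

test_that("replicate draws from one sample are distinct but exchangeable in size", {
  cfg <- small_cfg()
  suite <- simulate_suite(cfg, seed = 19)
  reps <- replicate_fragments(suite, "F", 3L, seed = 4)
  expect_equal(length(reps), 3L)
  sizes <- vapply(reps, length, integer(1))
  expect_equal(length(unique(sizes)), 1L)
  expect_false(identical(GenomicRanges::ranges(reps[[1]]),
                         GenomicRanges::ranges(reps[[2]])))
  # same seed reproduces the same draws
  reps2 <- replicate_fragments(suite, "F", 3L, seed = 4)
  expect_identical(GenomicRanges::ranges(reps[[2]]), GenomicRanges::ranges(reps2[[2]]))
})

test_that("the depth grid tabulates rescue ratios always at or above 1", {
  cfg <- small_cfg()
  suite <- simulate_suite(cfg, seed = 23)
  tg <- table_grid(suite, body_levels = 3000L, function_levels = c(3000L, 9000L),
                   seed = 29)
  expect_equal(nrow(tg), 2L)
  expect_true(all(tg$rescue >= 1 | is.na(tg$rescue)))
  expect_true(all(tg$nt >= 0 & tg$np >= 0))
})
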