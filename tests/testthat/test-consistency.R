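# Peak matching and the two consistency backends.

test_that("greedy matching follows overlap order with deterministic ties", {
  g <- tiny_genome(1000L)
  a <- make_region_set(data.frame(start = 0, end = 100), g)
  b <- make_region_set(data.frame(start = 50, end = 150), g)
  m <- match_peaks(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$overlapBp, 50L)

  d <- make_region_set(data.frame(start = 500, end = 600), g)
  expect_equal(nrow(match_peaks(a, d)), 0L)

  # one a-peak, two equally overlapping b-peaks: tie resolved to leftmost b,
  # and only one pair emitted (a is consumed)
  b2 <- make_region_set(data.frame(start = c(0, 60), end = c(40, 100)), g)
  m2 <- match_peaks(a, b2)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$bIdx, 1L)
  expect_equal(m2$overlapBp, 40L)
})

test_that("matching is one-to-one with positive overlap on random instances", {
  withr::local_seed(23)
  g <- tiny_genome(10000L)
  for (rep in 1:20) {
    a <- make_region_set(random_regions(15, 10000L), g)
    b <- make_region_set(random_regions(15, 10000L), g)
    m <- match_peaks(a, b)
    expect_false(any(duplicated(m$aIdx)))
    expect_false(any(duplicated(m$bIdx)))
    expect_true(all(m$overlapBp >= 1))
    if (nrow(m)) {
      ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(a)[m$aIdx], GenomicRanges::ranges(b)[m$bIdx]))
      expect_identical(as.integer(m$overlapBp), ov)
    }
  }
})

test_that("identical peak lists with one shared score are fully consistent", {
  withr::local_seed(29)
  g <- tiny_genome(100000L)
  starts <- seq(0L, by = 2000L, length.out = 20L)
  a <- peak_set(rep("chrT", 20), starts, starts + 500L, g,
                qLog10 = 5, signal = 10, summit = 250L)
  cc <- consistency_config(backend = "rank_product")
  res <- count_consistent(a, a, cc)
  expect_equal(res$count, 20L)
  expect_equal(length(res$regions), 20L)
})

test_that("rank-product pass rate under independent scores matches a Monte-Carlo oracle", {
  withr::local_seed(31)
  n <- 200L
  # oracle: simulate the definition directly on random distinct ranks
  mc_pass <- replicate(2000, {
    ua <- sample.int(n) / n; ub <- sample.int(n) / n
    sum(sqrt(ua * ub) <= 0.5)
  })
  p_exp <- mean(mc_pass) / n
  sd_exp <- stats::sd(mc_pass / n)

  g <- tiny_genome(1e6)
  starts <- seq(0L, by = 3000L, length.out = n)
  scores <- stats::runif(n, 1, 100)
  a <- peak_set(rep("chrT", n), starts, starts + 500L, g, qLog10 = scores,
                signal = 1, summit = 250L)
  cc <- consistency_config(backend = "rank_product")
  obs <- replicate(20, {
    b <- peak_set(rep("chrT", n), starts, starts + 500L, g,
                  qLog10 = sample(scores), signal = 1, summit = 250L)
    count_consistent(a, b, cc)$count / n
  })
  expect_lt(abs(mean(obs) - p_exp), 3 * sd_exp)
})

test_that("count_consistent returns empty results for disjoint lists and warns on tiny copula fits", {
  g <- tiny_genome(10000L)
  a <- make_region_set(data.frame(start = 0, end = 100), g)
  b <- make_region_set(data.frame(start = 5000, end = 5100), g)
  res <- count_consistent(a, b)
  expect_equal(res$count, 0L)
  expect_equal(length(res$regions), 0L)

  b2 <- make_region_set(data.frame(start = 50, end = 150), g)
  expect_warning(count_consistent(a, b2, consistency_config(backend = "copula_idr")),
                 "rank_product")
})

# shared helper: draw (n) pairs from the copula mixture model itself
draw_mixture_pairs <- function(n, pi1, rho, mu) {
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  rep_flag <- stats::runif(n) < pi1
  z[rep_flag, 2] <- rho * z[rep_flag, 1] + sqrt(1 - rho^2) * z[rep_flag, 2]
  z[rep_flag, ] <- z[rep_flag, ] + mu
  z
}

test_that("copula EM recovers the reproducible proportion from its own model", {
  withr::local_seed(37)
  fit <- copula_idr_fit(draw_mixture_pairs(2000, 0.7, 0.8, 2))
  expect_lt(abs(fit$params$pi1 - 0.7), 0.1)
  expect_gt(fit$params$rho, 0.5)
})

test_that("copula IDR passes almost nothing on pure noise and almost everything at the reproducible limit", {
  withr::local_seed(43)
  ok <- 0L
  for (s in 1:10) {
    fit <- copula_idr_fit(draw_mixture_pairs(2000, 0, 0.8, 2))
    ok <- ok + (fit$passCount / 2000 <= 0.05)
  }
  expect_gte(ok, 9L)

  fit <- copula_idr_fit(draw_mixture_pairs(2000, 1, 0.99, 2))
  expect_gte(fit$passCount / 2000, 0.9)
})

test_that("copula fit is deterministic and refuses tiny inputs", {
  withr::local_seed(47)
  x <- draw_mixture_pairs(500, 0.6, 0.8, 2)
  f1 <- copula_idr_fit(x); f2 <- copula_idr_fit(x)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$pass, f2$pass)
  expect_error(copula_idr_fit(x[1:5, ]), "at least 10")
})
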