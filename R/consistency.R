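## Consistency engine: peak matching between two lists and the backends that
## decide which matched pairs count as "consistent". Two backends:
##   copula_idr   -- two-component Gaussian copula mixture fit by EM, pairs
##                   pass when their global irreproducible discovery rate is
##                   at or below the threshold (the default, statistically
##                   principled route);
##   rank_product -- geometric mean of the two within-list rank percentiles,
##                   pairs pass below a percentile threshold (a light,
##                   fit-free fallback for tiny pair counts).

#' Configuration for the consistency backend
#'
#' @param backend `"copula_idr"` (default) or `"rank_product"`.
#' @param idrThreshold Global IDR pass threshold in (0, 1) (default 0.05).
#' @param rankProductThreshold Rank-product percentile threshold in (0, 1)
#'   (default 0.5).
#' @param scoreField Peak attribute used to rank peaks: `"qLog10"` (default),
#'   `"signal"` or `"pLog10"`.
#' @return A list of class `consistency_config`.
#' @export
consistency_config <- function(backend = c("copula_idr", "rank_product"),
                               idrThreshold = 0.05,
                               rankProductThreshold = 0.5,
                               scoreField = c("qLog10", "signal", "pLog10")) {
  backend <- match.arg(backend)
  scoreField <- match.arg(scoreField)
  if (idrThreshold <= 0 || idrThreshold >= 1)
    stop("`idrThreshold` must be in (0, 1)")
  if (rankProductThreshold <= 0 || rankProductThreshold >= 1)
    stop("`rankProductThreshold` must be in (0, 1)")
  structure(list(backend = backend, idrThreshold = idrThreshold,
                 rankProductThreshold = rankProductThreshold,
                 scoreField = scoreField),
            class = "consistency_config")
}

#' Greedily match peaks between two lists
#'
#' Each peak participates in at most one pair. Candidate pairs (overlap of
#' at least 1 bp) are taken in order of decreasing overlap, ties broken by
#' leftmost start and then input order.
#'
#' @param a,b Peak `GRanges` on the same genome.
#' @return A data.frame with columns `aIdx`, `bIdx`, `overlapBp`.
#' @export
match_peaks <- function(a, b) {
  stop_if_genome_mismatch(a, b)
  empty <- data.frame(aIdx = integer(0), bIdx = integer(0), overlapBp = integer(0))
  if (length(a) == 0L || length(b) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(a)[qh], GenomicRanges::ranges(b)[sh]))
  ord <- order(-ov, GenomicRanges::start(a)[qh], GenomicRanges::start(b)[sh], qh, sh)
  used_a <- logical(length(a)); used_b <- logical(length(b))
  keep <- logical(length(ord))
  for (t in seq_along(ord)) {
    i <- qh[ord[t]]; j <- sh[ord[t]]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; keep[t] <- TRUE
    }
  }
  sel <- ord[keep]
  out <- data.frame(aIdx = qh[sel], bIdx = sh[sel], overlapBp = ov[sel])
  out[order(out$aIdx), , drop = FALSE]
}

## Internal: rank-product backend. Percentile of a peak is its rank from the
## top (ties share the best/min rank) divided by n; the pair statistic is the
## geometric mean of the two percentiles.
rank_product_pass <- function(sa, sb, threshold) {
  n <- length(sa)
  ua <- rank(-sa, ties.method = "min") / n
  ub <- rank(-sb, ties.method = "min") / n
  sqrt(ua * ub) <= threshold
}

#' Fit the Gaussian copula mixture and compute the IDR of each pair
#'
#' Rank-transforms each margin to pseudo-values through the current mixture
#' marginal, then fits by EM a two-component bivariate Gaussian mixture: a
#' reproducible component with mean `mu > 0`, standard deviation `sigma` and
#' correlation `rho` in (0, 1), against an independent standard-normal noise
#' component. The local idr of a pair is its posterior probability of noise;
#' the global IDR is the running mean of sorted local idr values, and a pair
#' passes when its global IDR is at or below `threshold`.
#'
#' The EM is run from two fixed starting points (`mu = 1, sigma = 1,
#' rho = 0.5` and the reference-customary `mu = 2.6, sigma = 1.3,
#' rho = 0.8`, both with `pi1 = 0.5`) and the higher-likelihood solution is
#' kept; the reproducible component's standard deviation is floored at 0.5
#' so it cannot collapse onto blocks of tied scores. The fit is fully
#' deterministic given the input order.
#'
#' @param scores Two-column numeric matrix of paired scores (higher = better).
#' @param threshold Global IDR pass threshold (default 0.05).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-6).
#' @return A list: `passCount`, `pass` (logical per pair), `localIdr`,
#'   `globalIdr`, `params` (`pi1`, `mu`, `sigma`, `rho`), `converged`,
#'   `loglik`.
#' @export
copula_idr_fit <- function(scores, threshold = 0.05, max_iter = 500L, tol = 1e-6) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 10L)
    stop("copula IDR needs at least 10 matched pairs; use the rank_product backend")
  u1 <- rank(scores[, 1], ties.method = "average") / (n + 1)
  u2 <- rank(scores[, 2], ties.method = "average") / (n + 1)
  # one mixture-CDF grid per parameter set, shared by both margins
  pseudo_grid <- function(pi1, mu, sigma) {
    lo <- min(-5, mu - 5 * sigma); hi <- max(5, mu + 5 * sigma)
    grid <- seq(lo, hi, length.out = 2000L)
    G <- pi1 * stats::pnorm(grid, mu, sigma) + (1 - pi1) * stats::pnorm(grid)
    list(grid = grid, G = G)
  }
  pseudo_from <- function(pg, u) {
    stats::approx(pg$G, pg$grid, xout = u, rule = 2, ties = "ordered")$y
  }
  pseudo <- function(u, pi1, mu, sigma) {
    pseudo_from(pseudo_grid(pi1, mu, sigma), u)
  }
  bvn <- function(z1, z2, mu, sigma, rho) {
    a <- (z1 - mu) / sigma; b <- (z2 - mu) / sigma
    exp(-(a * a - 2 * rho * a * b + b * b) / (2 * (1 - rho^2))) /
      (2 * pi * sigma^2 * sqrt(1 - rho^2))
  }
  run_em <- function(pi1, mu, sigma, rho) {
    ll_old <- -Inf; converged <- FALSE; p <- rep(0.5, n)
    for (iter in seq_len(max_iter)) {
      pg <- pseudo_grid(pi1, mu, sigma)
      z1 <- pseudo_from(pg, u1)
      z2 <- pseudo_from(pg, u2)
      d1 <- bvn(z1, z2, mu, sigma, rho)
      d0 <- stats::dnorm(z1) * stats::dnorm(z2)
      denom <- pi1 * d1 + (1 - pi1) * d0
      denom[denom <= 0] <- .Machine$double.xmin
      p <- pi1 * d1 / denom
      sp <- sum(p)
      pi1 <- min(max(sp / n, 1e-4), 1 - 1e-4)
      if (sp > 0) {
        mu <- max(sum(p * (z1 + z2)) / (2 * sp), 1e-3)
        s2 <- sum(p * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * sp)
        # variance floor: stops the component collapsing onto tied score blocks
        sigma <- sqrt(max(s2, 0.25))
        rho <- sum(p * (z1 - mu) * (z2 - mu)) / (sp * sigma^2)
        rho <- min(max(rho, 1e-3), 0.999)
      }
      ll <- sum(log(denom))
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
      ll_old <- ll
      # no dependence left: the likelihood-ratio guard will void this fit
      # whatever EM does next, so stop drifting
      if (iter >= 25L && rho <= 0.02) break
    }
    list(pi1 = pi1, mu = mu, sigma = sigma, rho = rho, p = p,
         ll = ll_old, converged = converged)
  }
  fit1 <- run_em(0.5, 1, 1, 0.5)
  fit2 <- run_em(0.5, 2.6, 1.3, 0.8)
  best <- if (fit2$ll > fit1$ll) fit2 else fit1
  pi1 <- best$pi1; mu <- best$mu; sigma <- best$sigma; rho <- best$rho
  p <- best$p; ll_old <- best$ll; converged <- best$converged
  # Guard against the degenerate fit in which the "reproducible" component
  # collapses onto the noise distribution (mu ~ 0, rho ~ 0) and the
  # posterior blanket-passes every pair. Ranks fit the fitted marginal by
  # construction, so only the dependence carries evidence: require the
  # joint mixture to beat the independence model with the same mixture
  # marginals by a likelihood-ratio margin, else declare that there is no
  # reproducible component and nothing passes.
  z1 <- pseudo(u1, pi1, mu, sigma)
  z2 <- pseudo(u2, pi1, mu, sigma)
  gmarg <- function(z) pi1 * stats::dnorm(z, mu, sigma) + (1 - pi1) * stats::dnorm(z)
  ll_indep <- sum(log(pmax(gmarg(z1), .Machine$double.xmin))) +
    sum(log(pmax(gmarg(z2), .Machine$double.xmin)))
  if (2 * (ll_old - ll_indep) < stats::qchisq(0.999, df = 2)) {
    p <- rep(0, n)
  }
  local_idr <- 1 - p
  ord <- order(local_idr)
  cum <- cumsum(local_idr[ord]) / seq_len(n)
  kpass <- which(cum <= threshold)
  pass <- logical(n)
  if (length(kpass)) pass[ord[seq_len(max(kpass))]] <- TRUE
  global_idr <- numeric(n)
  global_idr[ord] <- cum
  list(passCount = sum(pass), pass = pass, localIdr = local_idr,
       globalIdr = global_idr,
       params = list(pi1 = pi1, mu = mu, sigma = sigma, rho = rho),
       converged = converged, loglik = ll_old)
}

#' Count consistent peaks between two lists
#'
#' Matches peaks one-to-one ([match_peaks()]), scores each matched pair with
#' the configured backend, and returns the number of passing pairs together
#' with their consensus regions (the intersection interval of each passing
#' pair, carrying the pair's maximum `qLog10` and the higher-signal member's
#' summit, clipped into the consensus interval).
#'
#' With the copula backend and fewer than 10 matched pairs the call falls
#' back to the rank-product backend with a warning.
#'
#' @param a,b Peak `GRanges` on the same genome.
#' @param config A [consistency_config()].
#' @return A list: `count` (integer) and `regions` (peak `GRanges`).
#' @export
count_consistent <- function(a, b, config = consistency_config()) {
  stop_if_genome_mismatch(a, b)
  genome <- GenomeInfoDb::seqinfo(a)
  m <- match_peaks(a, b)
  if (nrow(m) == 0L)
    return(list(count = 0L, regions = empty_peak_set(genome)))
  sa <- S4Vectors::mcols(a)[[config$scoreField]][m$aIdx]
  sb <- S4Vectors::mcols(b)[[config$scoreField]][m$bIdx]
  backend <- config$backend
  if (backend == "copula_idr" && nrow(m) < 10L) {
    warning("fewer than 10 matched pairs; falling back to the rank_product backend")
    backend <- "rank_product"
  }
  pass <- if (backend == "copula_idr") {
    copula_idr_fit(cbind(sa, sb), threshold = config$idrThreshold)$pass
  } else {
    rank_product_pass(sa, sb, config$rankProductThreshold)
  }
  if (!any(pass))
    return(list(count = 0L, regions = empty_peak_set(genome)))
  pa <- a[m$aIdx[pass]]; pb <- b[m$bIdx[pass]]
  rint <- IRanges::pintersect(GenomicRanges::ranges(pa), GenomicRanges::ranges(pb))
  r_start0 <- GenomicRanges::start(rint) - 1L
  r_end0 <- GenomicRanges::end(rint)
  mca <- S4Vectors::mcols(pa); mcb <- S4Vectors::mcols(pb)
  use_a <- mca$signal >= mcb$signal
  src <- ifelse(use_a, "a", "b")
  src_start0 <- ifelse(use_a, start0(pa), start0(pb))
  src_summit <- ifelse(use_a, mca$summit, mcb$summit)
  abs_summit <- ifelse(src_summit == -1L, -1L, src_start0 + src_summit)
  clipped <- ifelse(abs_summit == -1L, -1L,
                    pmin(pmax(abs_summit, r_start0), r_end0 - 1L))
  summit <- ifelse(clipped == -1L, -1L, clipped - r_start0)
  regions <- peak_set(as.character(GenomeInfoDb::seqnames(pa)),
                      r_start0, r_end0, genome,
                      name = sprintf("consistent_%d", seq_along(pa)),
                      score = pmax(mca$score, mcb$score),
                      signal = pmax(mca$signal, mcb$signal),
                      pLog10 = pmax(mca$pLog10, mcb$pLog10),
                      qLog10 = pmax(mca$qLog10, mcb$qLog10),
                      summit = as.integer(summit))
  list(count = sum(pass), regions = regions)
}
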