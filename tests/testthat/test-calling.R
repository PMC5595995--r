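# Brute-force binomial upper tail by direct summation; the independent
# oracle for binom_pvalue.
brute_upper_tail <- function(k, n, p) {
  if (k == 0L) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

mk_counts <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(chrom = "c", pos = r$pos, strand = "+",
                           aligner = r$al, t = r$t, M = r$M)
  }))
}

test_that("level integration is the depth-weighted average minus the
           non-conversion rate, clamped at zero", {
  cfg <- integration_config(0.005)
  tab <- mk_counts(list(pos = 1L, al = "A", t = 10L, M = 4L),
                   list(pos = 1L, al = "B", t = 20L, M = 10L))
  rec <- integrate_methylation(tab, cfg)
  expect_equal(rec$level, 14 / 30 - 0.005, tolerance = 1e-12)
  expect_equal(rec$depth, 30L)
  expect_equal(rec$n_aligners, 2L)

  # all-unmethylated site: raw -0.005 clamps to zero
  tab <- mk_counts(list(pos = 2L, al = "A", t = 10L, M = 0L))
  expect_equal(integrate_methylation(tab, cfg)$level, 0)

  # single aligner at rate zero degenerates to M / t
  cfg0 <- integration_config(0)
  tab <- mk_counts(list(pos = 3L, al = "A", t = 7L, M = 3L))
  expect_equal(integrate_methylation(tab, cfg0)$level, 3 / 7)
})

test_that("integration is invariant to aligner relabeling and splitting", {
  cfg <- integration_config(0.005)
  base <- mk_counts(list(pos = 1L, al = "A", t = 12L, M = 5L),
                    list(pos = 1L, al = "B", t = 8L, M = 2L))
  relab <- data.table::copy(base)[, aligner := rev(aligner)]
  split2 <- mk_counts(list(pos = 1L, al = "A1", t = 7L, M = 3L),
                      list(pos = 1L, al = "A2", t = 5L, M = 2L),
                      list(pos = 1L, al = "B", t = 8L, M = 2L))
  expect_equal(integrate_methylation(base, cfg)$level,
               integrate_methylation(relab, cfg)$level)
  expect_equal(integrate_methylation(base, cfg)$level,
               integrate_methylation(split2, cfg)$level)
})

test_that("integration config rejects out-of-range rates", {
  expect_error(integration_config(-0.01))
  expect_error(integration_config(0.1))
  expect_warning(integration_config(0.06), "0.05")
})

test_that("binomial p-value equals brute-force summation for all n <= 30", {
  for (p in c(0.005, 0.01, 0.3)) {
    for (n in c(1L, 5L, 17L, 30L)) {
      k <- 0:n
      got <- binom_pvalue(k, rep(n, n + 1L), p)
      want <- vapply(k, brute_upper_tail, numeric(1), n = n, p = p)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  expect_equal(binom_pvalue(0L, 10L, 0.005), 1)
  expect_equal(binom_pvalue(10L, 10L, 0.005), 0.005^10)
  expect_error(binom_pvalue(11L, 10L, 0.005), "exceed")
  expect_error(binom_pvalue(1L, 10L, 0), "in \\(0, 1\\)")
})

test_that("binomial p-value is monotone in k and in p", {
  n <- 20L
  pv <- binom_pvalue(0:n, rep(n, n + 1L), 0.01)
  expect_true(all(diff(pv) <= 0))
  k <- 4L
  ps <- c(0.001, 0.005, 0.02, 0.1, 0.4)
  pv <- vapply(ps, function(p) binom_pvalue(k, n, p), numeric(1))
  expect_true(all(diff(pv) >= 0))
})

test_that("calls at stricter thresholds are nested subsets", {
  set.seed(3)
  rec <- data.table::data.table(
    chrom = "c", pos = 1:500, strand = "+",
    depth = stats::rpois(500, 15))
  rec[, meth_reads := stats::rbinom(500, depth, 0.05)]
  prev <- NULL
  for (thr in c(1e-2, 1e-3, 1e-4, 1e-5)) {
    called <- call_methylated(rec, 0.005, thr)
    idx <- which(called$called)
    if (!is.null(prev)) expect_true(all(idx %in% prev))
    prev <- idx
  }
  # k = 0 sites are never called
  z <- call_methylated(data.table::data.table(
    chrom = "c", pos = 1L, strand = "+", depth = 30L, meth_reads = 0L),
    0.005, 0.999)
  expect_false(z$called)
})

test_that("artificial methylome has the required marginals and is seeded", {
  depths <- rep(20L, 1000L)
  expect_true(all(simulate_artificial_methylome(depths, 0, 1) == 0L))
  expect_true(all(simulate_artificial_methylome(depths, 1, 1) == depths))
  expect_identical(simulate_artificial_methylome(depths, 0.3, 7),
                   simulate_artificial_methylome(depths, 0.3, 7))
  # law of large numbers at 1e5 sites
  d <- rep(10L, 1e5L)
  k <- simulate_artificial_methylome(d, 0.005, 5)
  se <- sqrt(0.005 * 0.995 / (10 * 1e5))
  expect_lt(abs(mean(k / 10) - 0.005), 3 * se)
})

test_that("FDR curve equals the hand-computed ratio of call counts", {
  set.seed(9)
  n <- sample(5:25, 1000L, replace = TRUE)
  k <- stats::rbinom(1000L, n, ifelse(stats::runif(1000) < 0.05, 0.5, 0.003))
  grid <- 10^-(2:6)
  calib <- calibrate_fdr(k, n, 0.005, thresholds = grid, seed = 31L)
  k_null <- simulate_artificial_methylome(n, 0.005, 31L)
  for (i in seq_along(grid)) {
    real <- sum(binom_pvalue(k, n, 0.005) < grid[i])
    null <- sum(binom_pvalue(k_null, n, 0.005) < grid[i])
    expect_equal(calib$curve$real_calls[i], real)
    expect_equal(calib$curve$null_calls[i], null)
    if (real > 0) expect_equal(calib$curve$fdr[i], null / real)
  }
  # reproducibility under a fixed seed
  calib2 <- calibrate_fdr(k, n, 0.005, thresholds = grid, seed = 31L)
  expect_identical(calib$curve, calib2$curve)
})

test_that("null-versus-null calibration reports FDR near one", {
  set.seed(13)
  n <- rep(15L, 20000L)
  k <- stats::rbinom(length(n), n, 0.005)  # the "real" data is pure null
  calib <- calibrate_fdr(k, n, 0.005, thresholds = c(1e-1, 1e-2), seed = 2L)
  with_calls <- calib$curve[real_calls > 10]
  expect_true(all(abs(with_calls$fdr - 1) < 0.5))
})

test_that("non-conversion rate is estimable from an unmethylated control", {
  tab <- data.table::data.table(
    chrom = c("chrL", "chrL", "chr1"), pos = 1:3, strand = "+",
    aligner = "A", t = c(100L, 300L, 50L), M = c(1L, 2L, 40L))
  expect_equal(estimate_non_conversion(tab, "chrL"), 3 / 400)
  expect_error(estimate_non_conversion(tab, "chrX"), "no covered sites")
})
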