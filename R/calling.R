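# Multi-aligner integration of methylation levels, binomial methylation
# calling against the bisulfite non-conversion rate, and FDR calibration
# against an artificial (simulated-null) methylome.

#' Methylation-status level cutoffs
#'
#' Named constants used downstream: a CpG is methylated at level >= 0.8 and
#' unmethylated below 0.2; a CpH is hyper-methylated above 0.5 (used for
#' motif extraction). CpH methylated status for distance-probability
#' counting uses the binomial call, not the 0.5 cutoff.
#'
#' @format list with elements `mcpg`, `unmethylated_cpg`, `hyper_mcph`.
#' @export
meth_cutoffs <- list(mcpg = 0.8, unmethylated_cpg = 0.2, hyper_mcph = 0.5)

#' Integration configuration
#'
#' @param non_conversion_rate bisulfite non-conversion rate in `[0, 0.1)`;
#'   the subtraction term of the level integration and the null success
#'   probability of the binomial caller. Values above 0.05 trigger a warning
#'   (they usually indicate a failed conversion control).
#' @param clamp_negative clamp levels below zero to zero (default TRUE).
#' @return a list of class `integration_config`.
#' @export
integration_config <- function(non_conversion_rate, clamp_negative = TRUE) {
  if (!is.numeric(non_conversion_rate) || non_conversion_rate < 0 ||
      non_conversion_rate >= 0.1) {
    stop("non_conversion_rate must be in [0, 0.1)")
  }
  if (non_conversion_rate > 0.05) {
    warning("non-conversion rate above 0.05; check the conversion control")
  }
  structure(list(non_conversion_rate = non_conversion_rate,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "integration_config")
}

#' Integrate multi-aligner counts into methylation levels
#'
#' Pools reads across aligners per cytosine and computes the read-depth
#' weighted methylation level: sum of methylated reads over sum of total
#' reads, minus the non-conversion rate, clamped at zero. Sites with zero
#' pooled depth are skipped with a warning.
#'
#' @param table long multi-aligner count table (ideally after
#'   [coverage_filter()]).
#' @param cfg an [integration_config()].
#' @param context optional context table from [classify_cytosines()]; when
#'   given, sites are annotated with `cclass`, `trinuc`, `symclass` and sites
#'   absent from the index are dropped.
#' @return a `data.table` with columns `chrom`, `pos`, `strand`, `level`,
#'   `depth`, `meth_reads`, `n_aligners` (plus context columns when
#'   annotated).
#' @export
integrate_methylation <- function(table, cfg, context = NULL) {
  stopifnot(inherits(cfg, "integration_config"))
  t <- M <- NULL
  rec <- table[, .(depth = sum(t), meth_reads = sum(M), n_aligners = sum(t > 0L)),
               by = .(chrom, pos, strand)]
  n_zero <- sum(rec$depth == 0L)
  if (n_zero > 0L) {
    warning(sprintf("%d site(s) with zero pooled depth skipped", n_zero))
    rec <- rec[depth > 0L]
  }
  rec[, level := meth_reads / depth - cfg$non_conversion_rate]
  if (cfg$clamp_negative) rec[, level := pmax(level, 0)]
  if (!is.null(context)) {
    rec <- context[rec, on = c("chrom", "pos", "strand"), nomatch = NULL]
  }
  data.table::setorder(rec, chrom, pos, strand)
  rec[]
}

#' Upper-tail binomial p-value
#'
#' Probability of observing at least `k` methylated reads out of `n` under
#' the null that every methylated read is a non-conversion artifact:
#' `Pr(X >= k)` for `X ~ Binomial(n, p)`. Vectorised over `k` and `n`.
#'
#' @param k methylated read count(s), `0 <= k <= n`.
#' @param n total read count(s).
#' @param p null success probability (the non-conversion rate), in (0, 1).
#' @return p-values in (0, 1].
#' @export
binom_pvalue <- function(k, n, p) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (any(k < 0) || any(n < 0)) stop("k and n must be non-negative")
  if (any(k > n)) stop("k must not exceed n")
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Call methylated cytosines
#'
#' Applies the upper-tail binomial test to the raw pooled counts of each
#' site and flags sites whose p-value is strictly below the threshold.
#'
#' @param records integrated methylome (needs `meth_reads` and `depth`), or
#'   any `data.table` with those columns.
#' @param p null success probability (non-conversion rate).
#' @param threshold p-value threshold in (0, 1); default `1e-5`.
#' @return a copy of `records` with `pvalue` and `called` columns.
#' @export
call_methylated <- function(records, p, threshold = 1e-5) {
  stopifnot(threshold > 0, threshold < 1)
  out <- data.table::copy(records)
  out[, pvalue := binom_pvalue(meth_reads, depth, p)]
  out[, called := pvalue < threshold]
  out[]
}

#' Simulate an artificial (null) methylome
#'
#' For every site, draws a methylated read count from
#' `Binomial(depth, p)` with the non-conversion rate as success probability,
#' keeping the real read depths. This is the empirical-null methylome used
#' for FDR calibration.
#'
#' @param depths integer vector of per-site read depths (from the real
#'   sample).
#' @param p non-conversion rate.
#' @param seed RNG seed; the draw is reproducible given the seed.
#' @return integer vector of simulated methylated read counts.
#' @export
simulate_artificial_methylome <- function(depths, p, seed) {
  stopifnot(p >= 0, p <= 1)
  with_seed(seed, stats::rbinom(length(depths), depths, p))
}

#' Calibrate the calling threshold to a target FDR
#'
#' Computes, over a descending grid of p-value thresholds, the number of
#' real calls and the number of calls in an artificial methylome with the
#' same per-site depths, and their ratio `fdr(t) = null_calls / real_calls`.
#' The chosen threshold is the largest grid value whose FDR is strictly
#' below the target; `NA` when no threshold achieves it. With several
#' artificial replicates, null call counts are averaged.
#'
#' @param k,n methylated and total read counts of the real sample.
#' @param p non-conversion rate.
#' @param fdr_target target FDR (default 0.01).
#' @param thresholds descending grid of p-value cutoffs (default
#'   `10^-(2:8)`).
#' @param seed RNG seed for the artificial methylome.
#' @param n_reps number of artificial replicates (default 1).
#' @return object of class `fdr_calibration`: list with `curve` (a
#'   `data.table` threshold/real_calls/null_calls/fdr), `chosen_threshold`,
#'   `fdr_target`, `seed`.
#' @export
calibrate_fdr <- function(k, n, p, fdr_target = 0.01, thresholds = 10^-(2:8),
                          seed = 1L, n_reps = 1L) {
  stopifnot(length(k) == length(n), n_reps >= 1L)
  thresholds <- sort(thresholds, decreasing = TRUE)
  pv_real <- binom_pvalue(k, n, p)
  null_mat <- matrix(0, nrow = length(thresholds), ncol = n_reps)
  for (r in seq_len(n_reps)) {
    k_null <- simulate_artificial_methylome(n, p, seed + (r - 1L))
    pv_null <- binom_pvalue(k_null, n, p)
    null_mat[, r] <- vapply(thresholds, function(t) sum(pv_null < t), numeric(1))
  }
  real_calls <- vapply(thresholds, function(t) sum(pv_real < t), numeric(1))
  null_calls <- rowMeans(null_mat)
  fdr <- ifelse(real_calls == 0, NaN, null_calls / real_calls)
  curve <- data.table::data.table(threshold = thresholds,
                                  real_calls = real_calls,
                                  null_calls = null_calls, fdr = fdr)
  ok <- which(!is.nan(fdr) & fdr < fdr_target)
  chosen <- if (length(ok)) thresholds[min(ok)] else NA_real_
  structure(list(curve = curve, chosen_threshold = chosen,
                 fdr_target = fdr_target, seed = seed),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat("FDR calibration (target", x$fdr_target, ")\n")
  print(x$curve)
  cat("chosen threshold:",
      if (is.na(x$chosen_threshold)) "none" else format(x$chosen_threshold),
      "\n")
  invisible(x)
}

#' Estimate the non-conversion rate from an unmethylated control contig
#'
#' Pools raw counts over a designated fully-unmethylated control sequence
#' (for example a spiked lambda phage chromosome) and returns the pooled
#' fraction of methylated reads.
#'
#' @param table long multi-aligner count table.
#' @param control_chrom name of the control sequence.
#' @return estimated non-conversion rate.
#' @export
estimate_non_conversion <- function(table, control_chrom) {
  sub <- table[chrom == control_chrom]
  if (nrow(sub) == 0L || sum(sub$t) == 0L) {
    stop("no covered sites on control sequence '", control_chrom, "'")
  }
  sum(sub$M) / sum(sub$t)
}

#' Write an FDR calibration curve as TSV
#'
#' @param calib an `fdr_calibration` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_calibration <- function(calib, path) {
  write_tsv_file(calib$curve, path)
}
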