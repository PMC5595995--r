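test_that("genome blocks reproduce naive per-site means", {
  meth <- random_methylome(n = 800L, seed = 21)
  blocks <- bin_genome(meth, 1000L)
  # independent recount: split by coarse position, average by class/strand
  for (i in sample(nrow(blocks), 10L)) {
    b <- blocks[i]
    sub <- meth[pos >= b$start & pos < b$end]
    expect_equal(b$n_cpg, sum(sub$cclass == "CpG"))
    expect_equal(b$n_cph, sum(sub$cclass == "CpH"))
    if (b$n_cpg > 0) {
      expect_equal(b$mean_mcpg, mean(sub$level[sub$cclass == "CpG"]))
    }
    fw <- sub$cclass == "CpH" & sub$strand == "+"
    if (any(fw)) expect_equal(b$mean_mcph_fwd, mean(sub$level[fw]))
  }
  # one-site classes and empty blocks behave
  tiny <- data.table::data.table(
    chrom = "c", pos = c(10L, 20L), strand = "+",
    cclass = c("CpG", "CpH"), trinuc = c("CGA", "CAG"),
    symclass = c("CpG", "CpHpG"), level = c(0.9, 0.1), depth = 10L)
  b <- bin_genome(tiny, 1000L)
  expect_equal(b$mean_mcpg, 0.9)
  expect_equal(b$mean_mcph, 0.1)
  expect_true(is.na(b$mean_mcph_rev))
})

test_that("block correlation handles exact, degenerate and coupled inputs", {
  mkblocks <- function(mcpg, mcph, n = 20L) {
    data.table::data.table(
      chrom = "c", block = seq_along(mcpg),
      start = 0L, end = 1000L, n_cpg = n, n_cph = n,
      mean_mcpg = mcpg, mean_mcph = mcph,
      mean_mcpg_fwd = mcpg, mean_mcpg_rev = mcpg,
      mean_mcph_fwd = mcph, mean_mcph_rev = mcph)
  }
  x <- seq(0.1, 0.9, length.out = 15)
  expect_equal(block_correlation(mkblocks(x, 0.1 * x)), 1)
  expect_warning(r <- block_correlation(mkblocks(x, rep(0.2, 15))),
                 "constant")
  expect_true(is.nan(r))
  expect_error(block_correlation(mkblocks(x, x, n = 5L)),
               "insufficient blocks")
  # planted positive coupling in the simulator survives binning
  blocks <- bin_genome(esc_sim()$meth)
  expect_gt(block_correlation(blocks), 0)
})

test_that("hemi-methylated blocks show cis-strand CpH preference", {
  # assignment: the strand carrying the higher mCpG is cis
  b1 <- data.table::data.table(
    chrom = "c", block = 1L, start = 0L, end = 1000L,
    n_cpg = 20L, n_cph = 20L, mean_mcpg = 0.5, mean_mcph = 0.1,
    mean_mcpg_fwd = 0.9, mean_mcpg_rev = 0.1,
    mean_mcph_fwd = 0.08, mean_mcph_rev = 0.02)
  h <- hemi_strand_analysis(b1)
  expect_equal(h$cis_mean, 0.08)
  expect_equal(h$trans_mean, 0.02)

  # strand-symmetric null: no systematic cis excess
  set.seed(17)
  n <- 60L
  fwd_high <- sample(c(TRUE, FALSE), n, replace = TRUE)
  null_blocks <- data.table::data.table(
    chrom = "c", block = seq_len(n), start = 0L, end = 1000L,
    n_cpg = 20L, n_cph = 20L, mean_mcpg = 0.5, mean_mcph = 0.05,
    mean_mcpg_fwd = ifelse(fwd_high, 0.9, 0.1),
    mean_mcpg_rev = ifelse(fwd_high, 0.1, 0.9),
    mean_mcph_fwd = stats::runif(n, 0, 0.1),
    mean_mcph_rev = stats::runif(n, 0, 0.1))
  h0 <- hemi_strand_analysis(null_blocks)
  expect_gt(h0$p_value, 0.01)
  expect_lt(abs(h0$cis_mean - h0$trans_mean), 0.02)
  expect_error(hemi_strand_analysis(b1, diff_cut = 0.9), "no blocks")

  # generator plants hemi segments whose cis strand carries the mCpH
  sim <- cached_sim("esc_hemi", simulation_config(
    "esc", seed = 120, genome_length = 400000L, n_genes = 20L,
    hemi_fraction = 0.08))
  h1 <- hemi_strand_analysis(bin_genome(sim$meth))
  expect_gt(h1$cis_mean, h1$trans_mean)
  expect_lt(h1$p_value, 0.05)
})

test_that("distance probability profile matches a brute-force window scan", {
  meth <- random_methylome(n = 700L, chrom_len = 15000L, seed = 5)
  set.seed(6)
  cph <- meth[cclass == "CpH"]
  called <- cph[sample(.N, 150L)][, .(chrom, pos, strand)]
  radius <- 200L; bw <- 10L
  prof <- distance_probability_profile(meth, called, radius, bw,
                                       cph_strand = "both")
  anchors <- meth[cclass == "CpG" & level >= 0.8]
  nbins <- 2L * radius / bw
  brute <- matrix(0, nrow = nbins, ncol = 1)
  for (a in seq_len(nrow(anchors))) {
    apos <- anchors$pos[a]; astr <- anchors$strand[a]
    d <- called$pos - apos
    if (astr == "-") d <- -d
    bins <- (d + radius) %/% bw
    bins <- bins[bins >= 0 & bins < nbins]
    brute[unique(bins) + 1L, 1] <- brute[unique(bins) + 1L, 1] + 1
  }
  got <- prof[anchor_state == "methylated"][order(offset)]
  expect_equal(got$value, as.numeric(brute[, 1] / nrow(anchors)))

  # trivial extremes: no calls anywhere -> all zero
  none <- distance_probability_profile(meth, called[0], radius, bw)
  expect_true(all(none$value == 0))
})

test_that("distance level profile is flat on uniform methylomes and matches
           a brute-force scan", {
  meth <- random_methylome(n = 700L, chrom_len = 15000L, seed = 8)
  uni <- data.table::copy(meth)[, level := 0.02]
  uni[cclass == "CpG" & seq_len(.N) %% 2 == 0, level := 0.9]  # some anchors
  prof <- distance_level_profile(uni, "methylated", radius = 100)
  vals <- prof$value[!is.na(prof$value)]
  expect_true(all(abs(vals - 0.02) < 1e-12))

  prof2 <- distance_level_profile(meth, "methylated", radius = 50)
  anchors <- meth[cclass == "CpG" & level >= 0.8]
  cph <- meth[cclass == "CpH"]
  for (off in c(-50L, -7L, 3L, 50L)) {
    acc <- numeric(0)
    for (a in seq_len(nrow(anchors))) {
      tgt <- if (anchors$strand[a] == "+") anchors$pos[a] + off
             else anchors$pos[a] - off
      hit <- cph[pos == tgt & strand == anchors$strand[a]]
      if (nrow(hit)) acc <- c(acc, hit$level)
    }
    got <- prof2[offset == off]
    if (length(acc)) {
      expect_equal(got$value, mean(acc))
      expect_equal(got$n, length(acc))
    } else {
      expect_true(is.na(got$value))
    }
  }
})

test_that("sliding window smoothing preserves constants and impulse mass", {
  prof <- data.table::data.table(anchor_state = "methylated",
                                 offset = -50:50,
                                 value = 0.3, n = 1L)
  data.table::setattr(prof, "binwidth", 1)
  sm <- sliding_window_profile(prof, 10)
  expect_equal(sm$value, rep(0.3, 101))

  imp <- data.table::copy(prof)[, value := 0][offset == 0, value := 1]
  sm <- sliding_window_profile(imp, 10)
  expect_equal(sum(sm$value), 1, tolerance = 1e-12)  # away from edges
  expect_error(sliding_window_profile(prof, 500), "window larger")
})

test_that("periodicity detection finds analytic and planted periods", {
  prof <- data.table::data.table(offset = 0:199,
                                 value = cos(2 * pi * (0:199) / 9))
  data.table::setattr(prof, "binwidth", 1)
  ps <- periodicity_score(prof, c(5, 15))
  expect_equal(ps$best_lag, 9)
  expect_gt(ps$score, 0.99)

  # white noise does not beat its own circular-shift null
  set.seed(23)
  wn <- data.table::data.table(offset = 0:199, value = stats::rnorm(200))
  data.table::setattr(wn, "binwidth", 1)
  ps0 <- periodicity_score(wn, c(5, 15), n_perm = 200L, seed = 4L)
  expect_lt(ps0$score, stats::quantile(ps0$null_scores, 0.95) + 0.05)
  expect_error(periodicity_score(prof, c(150, 300)), "shorter")
})

test_that("replicate samples cluster by deposition mode", {
  ms <- replicate_methylomes()
  pat <- proximal_pattern_matrix(ms)
  expect_true(isSymmetric(pat$pcc))
  expect_equal(unname(diag(pat$pcc)), rep(1, 4))
  grp <- stats::cutree(pat$hclust, k = 2)
  expect_equal(grp[["esc_r1"]], grp[["esc_r2"]])
  expect_equal(grp[["neuron_r1"]], grp[["neuron_r2"]])
  expect_false(grp[["esc_r1"]] == grp[["neuron_r1"]])
  expect_match(pat$newick, "esc_r1")

  # a duplicated sample is perfectly correlated and merges first
  dup <- list(a = ms$esc_r1, b = ms$esc_r1, c = ms$neuron_r1)
  pd <- proximal_pattern_matrix(dup)
  expect_equal(pd$pcc["a", "b"], 1)
  expect_equal(sort(pd$hclust$merge[1, ]), c(-2, -1))
})

test_that("anchor-CpH correlation is maximal within the coupling range", {
  sim <- esc_sim()
  prof <- distance_correlation_profile(sim$meth, radius = 500)
  best <- prof$offset[which.max(prof$value)]
  expect_lte(abs(best + 5), 100)  # bin start; center within +/-100 bp
  # probability profile: methylated anchors dominate at central bins
  calls <- call_methylated(sim$meth, sim$cfg$ncr)
  called <- calls[called == TRUE & cclass == "CpH", .(chrom, pos, strand)]
  pp <- distance_probability_profile(sim$meth, called)
  cen <- abs(pp$offset + 5) <= 55
  pm <- pp[anchor_state == "methylated" & cen, mean(value)]
  pu <- pp[anchor_state == "unmethylated" & cen, mean(value)]
  expect_gt(pm, pu)
})
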