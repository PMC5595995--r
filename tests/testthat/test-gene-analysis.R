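mk_genes <- function(starts, ends, strands, ids = NULL) {
  n <- length(starts)
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(n))
  data.table::data.table(
    gene_id = ids, chrom = "chr1", strand = strands,
    tss = ifelse(strands == "+", starts + 1L, ends),
    tts = ifelse(strands == "+", ends, starts + 1L),
    start = starts, end = ends, length = ends - starts)
}

test_that("gene-body means equal a brute-force interval scan", {
  meth <- random_methylome(n = 900L, chrom_len = 60000L, seed = 41)
  set.seed(42)
  starts <- sort(sample.int(55000L, 50L)) - 1L
  genes <- mk_genes(starts, starts + sample(1100:3000, 50L, replace = TRUE),
                    sample(c("+", "-"), 50L, replace = TRUE))
  res <- suppressWarnings(gene_body_methylation(meth, genes, "cph"))
  cph <- meth[cclass == "CpH"]
  for (i in sample(nrow(genes), 10L)) {
    g <- genes[i]
    inside <- cph[pos >= g$start & pos < g$end]
    row <- res[gene_id == g$gene_id]
    if (nrow(inside)) {
      expect_equal(row$mean_level, mean(inside$level))
      expect_equal(row$n_sites, nrow(inside))
    } else {
      expect_equal(nrow(row), 0L)
    }
  }
  # context filters isolate CAG and CpHpG sites
  meth2 <- data.table::copy(meth)[, level := ifelse(trinuc == "CAG", 0.08, 0.01)]
  res_cag <- suppressWarnings(gene_body_methylation(meth2, genes, "cag"))
  expect_true(all(abs(res_cag$mean_level - 0.08) < 1e-12))
  res_sym <- suppressWarnings(gene_body_methylation(meth, genes, "cphpg"))
  some <- res_sym$gene_id[1]
  g <- genes[gene_id == some]
  inside <- cph[pos >= g$start & pos < g$end & symclass == "CpHpG"]
  expect_equal(res_sym[gene_id == some, mean_level], mean(inside$level))
})

test_that("short genes are excluded from gene-body summaries", {
  meth <- random_methylome(n = 200L, chrom_len = 5000L, seed = 43)
  genes <- mk_genes(c(0L, 2000L), c(900L, 4500L), c("+", "+"))
  res <- suppressWarnings(gene_body_methylation(meth, genes, "cph"))
  expect_false("G001" %in% res$gene_id)  # 900 bp < 1000
})

test_that("metagene landmarks sit at bins 142 and 857 for any gene", {
  lm <- metagene_landmarks()
  expect_equal(lm$tss_bin, 142L)
  expect_equal(lm$tts_bin, 857L)
  set.seed(44)
  for (i in 1:10) {
    L <- sample(1200:30000, 1)
    s <- sample.int(100000L, 1)
    # body boundaries map onto the landmark bins regardless of length:
    # the 5' boundary base edge is the TSS, the 3' boundary edge the TTS
    expect_equal(mchscape:::metagene_bin_of(s, s, s + L, "+"), 142)
    expect_equal(mchscape:::metagene_bin_of(s + L, s, s + L, "+"), 857)
    expect_equal(mchscape:::metagene_bin_of(s + L - 1L, s, s + L, "-"), 142)
    expect_equal(mchscape:::metagene_bin_of(s - 1L, s, s + L, "-"), 857)
  }
})

test_that("metagene profiles are flat on uniform methylomes and flip with
           strand", {
  meth <- random_methylome(n = 2000L, chrom_len = 50000L, seed = 45)
  meth[, level := 0.04]
  genes <- mk_genes(c(5000L, 25000L), c(15000L, 35000L), c("+", "-"))
  expr <- data.table::data.table(gene_id = genes$gene_id, fpkm = c(5, 50))
  mg <- metagene_profile(meth, genes, expr, groups = "all")
  vals <- mg[!is.na(value), value]
  expect_true(all(abs(vals - 0.04) < 1e-12))
  expect_equal(attr(mg, "tss_bin"), 142L)
  expect_equal(attr(mg, "tts_bin"), 857L)

  # reversing the strand reverses the bin mapping
  pos <- seq(25100L, 34900L, by = 50L)
  fwd_bins <- mchscape:::metagene_bin_of(pos, 25000L, 35000L, "+")
  rev_bins <- mchscape:::metagene_bin_of(pos, 25000L, 35000L, "-")
  expect_true(all(diff(fwd_bins) >= 0))
  expect_true(all(diff(rev_bins) <= 0))
  expect_equal(stats::cor(fwd_bins, rev_bins), -1, tolerance = 1e-6)
})

test_that("expression correlation recovers exact and planted orderings", {
  summ <- data.table::data.table(
    gene_id = sprintf("G%02d", 1:20),
    mean_mcph = seq(0.01, 0.2, length.out = 20),
    fpkm = exp(seq(0, 3, length.out = 20)))
  expect_equal(as.numeric(expression_correlation(summ)), 1)
  summ$mean_mcph <- rep(0.05, 20)
  expect_warning(r <- expression_correlation(summ), "constant")
  expect_true(is.nan(r))
  expect_error(expression_correlation(summ[1:5]), "at least 10")
})

test_that("histone overlap rate equals a per-base bitmap count", {
  genes <- mk_genes(c(1000L, 6000L), c(2000L, 9000L), c("+", "-"))
  peaks <- data.table::data.table(
    chrom = "chr1", start = c(1200L, 1400L, 500L, 8000L),
    end = c(1700L, 1900L, 1100L, 9500L))
  ov <- histone_overlap_rate(genes, peaks)
  # bitmap oracle
  for (i in 1:2) {
    bm <- logical(10000L)
    for (j in seq_len(nrow(peaks))) {
      bm[(peaks$start[j] + 1L):peaks$end[j]] <- TRUE
    }
    inside <- bm[(genes$start[i] + 1L):genes$end[i]]
    expect_equal(ov$overlap_rate[i], mean(inside))
  }
  # overlapping peaks count once; adding peaks never decreases the rate
  p1 <- peaks[1:2]
  merged_rate <- histone_overlap_rate(genes[1], p1)$overlap_rate
  expect_equal(merged_rate, 700 / 1000)  # union [1200,1900) counted once
  more <- rbind(p1, data.table::data.table(chrom = "chr1", start = 1000L,
                                           end = 1250L))
  expect_gte(histone_overlap_rate(genes[1], more)$overlap_rate, merged_rate)
  # a simple half-covered gene
  half <- histone_overlap_rate(
    mk_genes(0L, 1000L, "+"),
    data.table::data.table(chrom = "chr1", start = 0L, end = 500L))
  expect_equal(half$overlap_rate, 0.5)
})

test_that("gene screen applies all cuts and matches a direct filter", {
  set.seed(46)
  n <- 100L
  summ <- data.table::data.table(
    gene_id = c(sprintf("GENE%03d", 1:90), sprintf("LOC%03d", 91:95),
                sprintf("%03dRik", 96:100)),
    length = sample(c(800L, 2000L), n, replace = TRUE),
    mean_mcph = stats::runif(n, 0, 0.1),
    mean_mcag = stats::runif(n, 0, 0.12),
    fpkm = stats::rlnorm(n),
    overlap_rate = stats::runif(n))
  summ[gene_id == "LOC091", `:=`(mean_mcag = 0.2, overlap_rate = 0.9,
                                 length = 5000L)]
  scr <- screen_genes(summ)
  direct <- summ[!startsWith(gene_id, "LOC") &
                   !startsWith(gene_id, "Rik") &
                   length > 1000L & mean_mcag > 0.05 & overlap_rate > 0.5]
  expect_setequal(scr$genes$gene_id, direct$gene_id)
  expect_false("LOC091" %in% scr$genes$gene_id)
  expect_true(all(diff(scr$genes$mean_mcag) <= 0))
  expect_true(scr$mcag_quantile >= 0 && scr$mcag_quantile <= 1)
  # all genes below the cuts: empty result
  low <- data.table::copy(summ)[, `:=`(mean_mcag = 0.01, overlap_rate = 0.1)]
  expect_equal(nrow(screen_genes(low)$genes), 0L)
})

test_that("gene tables and peaks round-trip through their file dialects", {
  genes <- mk_genes(c(100L, 5000L), c(2000L, 9000L), c("+", "-"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_genes(genes, p)
  back <- read_genes(p)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$length, genes$length)
  expect_equal(back$strand, genes$strand)
})

test_that("genic block annotation assigns promoter precedence", {
  genes <- mk_genes(10000L, 20000L, "+")
  blocks <- data.table::data.table(
    chrom = "chr1", block = c(5L, 17L, 40L),
    start = c(5000L, 17000L, 40000L), end = c(6000L, 18000L, 41000L),
    n_cpg = 20L, n_cph = 20L, mean_mcpg = 0.5, mean_mcph = 0.02,
    mean_mcpg_fwd = 0.5, mean_mcpg_rev = 0.5,
    mean_mcph_fwd = 0.02, mean_mcph_rev = 0.02)
  ann <- annotate_blocks_genic(blocks, genes)
  expect_equal(ann$region, c("promoter", "intragenic", "intergenic"))
})
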