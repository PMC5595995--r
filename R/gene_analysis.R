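# Gene-body methylation summaries, metagene profiles by expression group,
# methylation-expression correlation, histone peak overlap rates, and the
# H3K36me3 + mCAG gene screen.

#' Read a gene model table
#'
#' The native dialect is a 6-column TSV with header: `gene_id`, `chrom`,
#' `strand`, `tss`, `tts`, `length`, where `tss`/`tts` are 1-based positions
#' of the first and last transcribed base (TSS is the 5' end in strand
#' orientation, so `tss > tts` on the minus strand). BED12 input is
#' supported through `rtracklayer` when installed.
#'
#' @param path gene table.
#' @param format `"tsv"` or `"bed12"`.
#' @return a `data.table` with `gene_id`, `chrom`, `strand`, `tss`, `tts`
#'   (as given), `start`/`end` (0-based half-open genomic interval) and
#'   `length`.
#' @export
read_genes <- function(path, format = c("tsv", "bed12")) {
  format <- match.arg(format)
  if (format == "bed12") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("BED12 input needs the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "BED")
    dt <- data.table::data.table(
      gene_id = gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr))
    dt[, `:=`(tss = ifelse(strand == "+", start + 1L, end),
              tts = ifelse(strand == "+", end, start + 1L))]
  } else {
    dt <- read_tsv_file(path, header = TRUE)
    dt[, `:=`(start = pmin(tss, tts) - 1L, end = pmax(tss, tts))]
  }
  dt[, length := end - start]
  if (any(dt$length <= 0L)) stop("gene(s) with non-positive length")
  data.table::setcolorder(dt, c("gene_id", "chrom", "strand", "tss", "tts",
                                "start", "end", "length"))
  dt[]
}

#' Write a gene model table in the native TSV dialect
#'
#' @param genes gene table from [read_genes()] or the simulator.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genes <- function(genes, path) {
  write_tsv_file(genes[, .(gene_id, chrom, strand, tss, tts, length)], path)
}

#' Read a histone peak BED (coordinates only)
#'
#' Accepts BED3 or wider (narrowPeak); only the first three columns are
#' used. BED coordinates are 0-based half-open, matching the internal
#' convention.
#'
#' @param path BED file.
#' @return a `data.table` with `chrom`, `start`, `end`.
#' @export
read_peaks <- function(path) {
  dt <- read_tsv_file(path, header = FALSE)
  if (ncol(dt) < 3L) stop("peak file needs at least 3 columns")
  out <- dt[, 1:3]
  data.table::setnames(out, c("chrom", "start", "end"))
  out[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (any(out$end <= out$start)) stop("peak(s) with non-positive width")
  out[]
}

#' Read an expression table
#'
#' Two-column TSV with header: `gene_id`, `fpkm`.
#'
#' @param path expression table.
#' @return a `data.table` with `gene_id`, `fpkm`.
#' @export
read_expression <- function(path) {
  dt <- read_tsv_file(path, header = TRUE)
  stopifnot(all(c("gene_id", "fpkm") %in% names(dt)))
  dt[, .(gene_id, fpkm = as.numeric(fpkm))]
}

#' Gene-body CpH methylation levels
#'
#' Unweighted mean level of qualifying CpH sites within each gene body
#' (TSS..TTS). Genes shorter than `min_len` are excluded up front; genes
#' whose bodies contain no qualifying site are absent from the result and
#' counted in a warning.
#'
#' @param methylome integrated, context-annotated methylome.
#' @param genes gene table from [read_genes()].
#' @param context_filter `"cph"` (all CpH), `"cag"` (CAG trinucleotides
#'   only) or `"cphpg"` (symmetric CpHpG only).
#' @param min_len strict minimum gene length in bp (default 1000).
#' @return a `data.table` with `gene_id`, `mean_level`, `n_sites`,
#'   `length`.
#' @export
gene_body_methylation <- function(methylome, genes,
                                  context_filter = c("cph", "cag", "cphpg"),
                                  min_len = 1000L) {
  context_filter <- match.arg(context_filter)
  g <- genes[length > min_len]
  sites <- methylome[cclass == "CpH"]
  sites <- switch(context_filter,
                  cph = sites,
                  cag = sites[trinuc == "CAG"],
                  cphpg = sites[symclass == "CpHpG"])
  if (nrow(g) == 0L) stop("no genes longer than min_len")
  hit <- sites[g, on = .(chrom, pos >= start, pos < end), nomatch = NULL,
               .(gene_id = i.gene_id, level = x.level)]
  res <- hit[, .(mean_level = mean(level), n_sites = .N), by = gene_id]
  n_empty <- nrow(g) - nrow(res)
  if (n_empty > 0L) {
    warning(sprintf("%d gene(s) without qualifying sites omitted", n_empty))
  }
  res <- res[g[, .(gene_id, length)], on = "gene_id", nomatch = NULL]
  data.table::setorder(res, gene_id)
  res[]
}

#' Landmark bin indices of the metagene axis
#'
#' With `flank_frac` flanks on each side of the body mapped together onto
#' `n_bins` bins, the TSS and TTS land at fixed bins for every gene
#' (142 and 857 with the defaults).
#'
#' @param n_bins number of metagene bins (default 1000).
#' @param flank_frac flank length as a fraction of gene length (default
#'   0.2).
#' @return list with `tss_bin` and `tts_bin`.
#' @export
metagene_landmarks <- function(n_bins = 1000L, flank_frac = 0.2) {
  span <- 1 + 2 * flank_frac
  list(tss_bin = as.integer(floor(flank_frac / span * n_bins)),
       tts_bin = as.integer(floor((flank_frac + 1) / span * n_bins)))
}

# Map positions to metagene bins for one gene. u runs 0..1 across
# [5' flank start, 3' flank end] in strand orientation; the bin ordinal is
# floor(u * n_bins), clamped into 1..n_bins. Minus-strand bases enter
# through their 5'-facing edge (pos + 1) so that the mapping is the exact
# mirror of the plus strand and the gene-body boundaries land on the
# landmark bins for every gene length.
metagene_bin_of <- function(pos, gene_start, gene_end, strand,
                            n_bins = 1000L, flank_frac = 0.2) {
  L <- gene_end - gene_start
  span <- L * (1 + 2 * flank_frac)
  if (strand == "+") {
    a <- gene_start - flank_frac * L
    u <- (pos - a) / span
  } else {
    a <- gene_end + flank_frac * L
    u <- (a - (pos + 1)) / span
  }
  pmin(pmax(floor(u * n_bins), 1L), n_bins)
}

#' Metagene CpH methylation profile by expression group
#'
#' Each gene body plus `flank_frac`-of-length flanks is normalised onto
#' `n_bins` bins (strand-oriented, so bin 1 is the 5' flank edge); CpH site
#' levels are averaged per gene per bin, then across genes, and finally
#' smoothed with a centered sliding window. Genes are grouped by FPKM
#' quantile: `high20` (top 20%), `low20` (bottom 20%) and `all`.
#'
#' @param methylome integrated, context-annotated methylome.
#' @param genes gene table.
#' @param expression expression table (`gene_id`, `fpkm`).
#' @param groups subset of `c("high20", "low20", "all")`.
#' @param n_bins number of bins (default 1000).
#' @param flank_frac flank fraction (default 0.2).
#' @param smooth_window smoothing window in bins (default 30).
#' @param min_len strict minimum gene length (default 1000).
#' @return a `data.table` with `bin`, `group`, `value`, `n_genes`, plus the
#'   landmark bins as attributes `tss_bin`/`tts_bin`.
#' @export
metagene_profile <- function(methylome, genes, expression,
                             groups = c("high20", "low20", "all"),
                             n_bins = 1000L, flank_frac = 0.2,
                             smooth_window = 30L, min_len = 1000L) {
  groups <- match.arg(groups, several.ok = TRUE)
  g <- genes[length > min_len]
  g <- g[expression, on = "gene_id", nomatch = NULL]
  if (nrow(g) == 0L) stop("no genes with expression values")
  hi_cut <- stats::quantile(g$fpkm, 0.8, names = FALSE)
  lo_cut <- stats::quantile(g$fpkm, 0.2, names = FALSE)
  members <- list(high20 = g$fpkm >= hi_cut, low20 = g$fpkm <= lo_cut,
                  all = rep(TRUE, nrow(g)))
  sites <- methylome[cclass == "CpH"]
  # per-gene per-bin means over the extended span
  ext <- data.table::copy(g)
  ext[, `:=`(xstart = as.integer(floor(start - flank_frac * length)),
             xend = as.integer(ceiling(end + flank_frac * length)))]
  hit <- sites[ext, on = .(chrom, pos >= xstart, pos < xend), nomatch = NULL,
               .(gene_id = i.gene_id, gstart = i.start, gend = i.end,
                 gstrand = i.strand, spos = x.pos, level = x.level)]
  if (nrow(hit) == 0L) stop("no CpH sites within any gene span")
  hit[, bin := metagene_bin_of(spos, gstart[1L], gend[1L], gstrand[1L],
                               n_bins, flank_frac), by = gene_id]
  per_gene <- hit[, .(v = mean(level)), by = .(gene_id, bin)]
  out <- list()
  for (grp in groups) {
    ids <- g$gene_id[members[[grp]]]
    if (length(ids) == 0L) stop("empty expression group: ", grp)
    sub <- per_gene[gene_id %in% ids]
    agg <- sub[, .(value = mean(v), n_genes = .N), by = bin]
    grid <- data.table::data.table(bin = seq_len(n_bins))
    agg <- agg[grid, on = "bin"]
    agg[is.na(n_genes), n_genes := 0L]
    agg[, value := moving_average(value, smooth_window)]
    agg[, group := grp]
    out[[grp]] <- agg
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("bin", "group", "value", "n_genes"))
  lm <- metagene_landmarks(n_bins, flank_frac)
  data.table::setattr(res, "tss_bin", lm$tss_bin)
  data.table::setattr(res, "tts_bin", lm$tts_bin)
  res[]
}

#' Spearman correlation between gene-body methylation and expression
#'
#' @param summaries a `data.table` with one row per gene holding the
#'   methylation column and `fpkm` (e.g. from [gene_meth_summaries()]).
#' @param meth_col name of the methylation column (default `"mean_mcph"`).
#' @return Spearman's rho (`NaN` with a warning when either variable is
#'   constant), with attribute `n` (genes used).
#' @export
expression_correlation <- function(summaries, meth_col = "mean_mcph") {
  x <- summaries[[meth_col]]
  y <- summaries$fpkm
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10L) stop("need at least 10 genes with both values")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("constant vector; correlation undefined")
    return(structure(NaN, n = sum(ok)))
  }
  rho <- stats::cor(x[ok], y[ok], method = "spearman")
  structure(rho, n = sum(ok))
}

#' Histone peak overlap rate of gene bodies
#'
#' Fraction of each gene body covered by the union of peak intervals:
#' overlapping peaks are merged before measuring, so the rate is
#' insensitive to redundant peak calls.
#'
#' @param genes gene table from [read_genes()].
#' @param peaks peak table from [read_peaks()] (0-based half-open).
#' @return a `data.table` with `gene_id` and `overlap_rate` in `[0, 1]`.
#' @export
histone_overlap_rate <- function(genes, peaks) {
  if (any(genes$length <= 0L)) stop("zero-length gene")
  covered <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pk <- peaks[chrom == ch]
    if (nrow(pk) == 0L) next
    red <- IRanges::reduce(IRanges::IRanges(pk$start + 1L, pk$end))
    gr <- IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi])
    hits <- IRanges::findOverlaps(gr, red)
    if (length(hits) == 0L) next
    w <- IRanges::width(IRanges::pintersect(
      gr[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]))
    covered[gi] <- as.numeric(tapply(
      w, factor(S4Vectors::queryHits(hits), levels = seq_along(gi)), sum,
      default = 0))
  }
  data.table::data.table(gene_id = genes$gene_id,
                         overlap_rate = covered / genes$length)
}

#' Assemble per-gene methylation summaries
#'
#' Joins gene-body mean CpH level, mean CAG-context level, expression and
#' histone overlap rate into one table suitable for
#' [expression_correlation()] and [screen_genes()].
#'
#' @param methylome integrated, context-annotated methylome.
#' @param genes gene table.
#' @param expression optional expression table.
#' @param peaks optional peak table.
#' @param min_len strict minimum gene length (default 1000).
#' @return a `data.table` with `gene_id`, `length`, `mean_mcph`,
#'   `mean_mcag`, and (when available) `fpkm`, `overlap_rate`.
#' @export
gene_meth_summaries <- function(methylome, genes, expression = NULL,
                                peaks = NULL, min_len = 1000L) {
  mcph <- suppressWarnings(
    gene_body_methylation(methylome, genes, "cph", min_len))
  mcag <- suppressWarnings(
    gene_body_methylation(methylome, genes, "cag", min_len))
  out <- mcph[, .(gene_id, length, mean_mcph = mean_level)]
  out <- merge(out, mcag[, .(gene_id, mean_mcag = mean_level)],
               by = "gene_id", all.x = TRUE)
  if (!is.null(expression)) {
    out <- merge(out, expression[, .(gene_id, fpkm)], by = "gene_id",
                 all.x = TRUE)
  }
  if (!is.null(peaks)) {
    ov <- histone_overlap_rate(genes[length > min_len], peaks)
    out <- merge(out, ov, by = "gene_id", all.x = TRUE)
  }
  data.table::setorder(out, gene_id)
  out[]
}

#' Screen for H3K36me3-marked, CAG-hyper-methylated genes
#'
#' Keeps genes whose gene-body mean CAG level exceeds `mcag_cut`, whose
#' histone overlap rate exceeds `overlap_cut`, that are longer than
#' `min_len`, and whose identifiers do not start with an excluded prefix.
#' The empirical quantile of `mcag_cut` among all eligible genes is
#' reported so the cutoff's stringency can be audited.
#'
#' @param summaries table from [gene_meth_summaries()] including
#'   `mean_mcag` and `overlap_rate`.
#' @param mcag_cut strict lower bound on mean CAG level (default 0.05).
#' @param overlap_cut strict lower bound on overlap rate (default 0.5).
#' @param min_len strict lower bound on gene length (default 1000).
#' @param excluded_prefixes identifier prefixes dropped before screening
#'   (default `LOC`, `Rik`).
#' @return list with `genes` (screened table sorted by descending
#'   `mean_mcag`) and `mcag_quantile` (fraction of eligible genes at or
#'   below the cutoff).
#' @export
screen_genes <- function(summaries, mcag_cut = 0.05, overlap_cut = 0.5,
                         min_len = 1000L,
                         excluded_prefixes = c("LOC", "Rik")) {
  eligible <- data.table::copy(summaries)
  for (pre in excluded_prefixes) {
    eligible <- eligible[!startsWith(gene_id, pre)]
  }
  eligible <- eligible[length > min_len & !is.na(mean_mcag) &
                         !is.na(overlap_rate)]
  hits <- eligible[mean_mcag > mcag_cut & overlap_rate > overlap_cut]
  data.table::setorder(hits, -mean_mcag)
  list(genes = hits[],
       mcag_quantile = if (nrow(eligible)) mean(eligible$mean_mcag <= mcag_cut)
                       else NA_real_)
}
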