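# Genome-binned mCpG/mCpH correlation, hemi-methylation strand analysis,
# distance-resolved CpH methylation profiles around CpG anchors, pattern
# clustering across samples, and periodicity detection.

# Enumerate (anchor, site) pairs within +/- radius. Offsets are
# strand-oriented: negative means 5' of the anchor cytosine on the anchor's
# strand. With strand_mode "anchor", only sites on the anchor's strand pair
# with it; with "both", sites on either strand do. Returns a data.table with
# aid (row of `anchors`), sid (row of `sites`) and d (signed offset in bp).
pair_offsets <- function(anchors, sites, radius, strand_mode = c("anchor", "both")) {
  strand_mode <- match.arg(strand_mode)
  a <- data.table::copy(anchors)[, aid := .I]
  s <- data.table::copy(sites)[, sid := .I]
  keys <- if (strand_mode == "anchor") c("chrom", "strand") else "chrom"
  groups <- unique(a[, keys, with = FALSE])
  res <- vector("list", nrow(groups))
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi]
    ag <- a[g, on = keys]
    sg <- s[g, on = keys, nomatch = NULL]
    if (nrow(ag) == 0L || nrow(sg) == 0L) next
    data.table::setorder(sg, pos)
    sp <- sg$pos
    lo <- findInterval(ag$pos - radius - 1L, sp) + 1L
    hi <- findInterval(ag$pos + radius, sp)
    cnt <- pmax(hi - lo + 1L, 0L)
    if (sum(cnt) == 0L) next
    idx <- sequence(cnt, from = lo)
    aid <- rep(ag$aid, cnt)
    d <- sp[idx] - rep(ag$pos, cnt)
    neg <- rep(ag$strand, cnt) == "-"
    d[neg] <- -d[neg]
    res[[gi]] <- data.table::data.table(aid = aid, sid = sg$sid[idx], d = d)
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(aid = integer(), sid = integer(), d = integer())
  }
  out
}

# Split CpG anchors of a methylome by methylation state.
anchor_sets <- function(methylome) {
  cpg <- methylome[cclass == "CpG"]
  list(methylated = cpg[level >= meth_cutoffs$mcpg],
       unmethylated = cpg[level < meth_cutoffs$unmethylated_cpg])
}

new_distance_profile <- function(dt, mode, binwidth, radius) {
  data.table::setattr(dt, "mode", mode)
  data.table::setattr(dt, "binwidth", binwidth)
  data.table::setattr(dt, "radius", radius)
  data.table::setattr(dt, "class", c("distance_profile", class(dt)))
  dt
}

#' Probability of finding a called mCpH around CpGs
#'
#' For every CpG anchor (split into methylated, level >= 0.8, and
#' unmethylated, level < 0.2), the +/-`radius` window is divided into
#' `binwidth`-bp bins and each bin is scored by whether it contains at least
#' `min_mcph` called mCpH site(s). The profile value at a bin is the
#' fraction of anchor windows whose bin is occupied. Offsets are
#' strand-oriented (negative = 5' of the anchor).
#'
#' @param methylome integrated, context-annotated methylome.
#' @param called table of called mCpH sites (`chrom`, `pos`, `strand`), e.g.
#'   the called CpH subset of [call_methylated()].
#' @param radius window half-width in bp (default 500).
#' @param binwidth bin width in bp (default 10).
#' @param cph_strand `"both"` counts called mCpHs on either strand around
#'   the anchor; `"anchor"` restricts to the anchor's strand.
#' @param min_mcph minimum called mCpHs for a bin to count as occupied
#'   (default 1).
#' @return a `distance_profile` `data.table` with columns `anchor_state`,
#'   `offset` (bin start), `value` (probability) and `n` (anchor count).
#' @export
distance_probability_profile <- function(methylome, called, radius = 500,
                                         binwidth = 10,
                                         cph_strand = c("both", "anchor"),
                                         min_mcph = 1L) {
  cph_strand <- match.arg(cph_strand)
  anch <- anchor_sets(methylome)
  nbins <- as.integer(2 * radius / binwidth)
  starts <- seq_len(nbins) * binwidth - binwidth - radius
  out <- list()
  for (state in names(anch)) {
    a <- anch[[state]]
    if (nrow(a) == 0L) {
      warning("no ", state, " CpG anchors; profile absent")
      next
    }
    pr <- pair_offsets(a, called, radius, cph_strand)
    value <- numeric(nbins)
    if (nrow(pr) > 0L) {
      pr[, bin := (d + as.integer(radius)) %/% as.integer(binwidth)]
      pr <- pr[bin >= 0L & bin < nbins]
      occ <- pr[, .N, by = .(aid, bin)][N >= min_mcph]
      cnt <- occ[, .N, by = bin]
      value[cnt$bin + 1L] <- cnt$N / nrow(a)
    }
    out[[state]] <- data.table::data.table(
      anchor_state = state, offset = starts, value = value, n = nrow(a))
  }
  new_distance_profile(data.table::rbindlist(out), "probability", binwidth, radius)
}

#' Mean CpH methylation level at each distance from CpG anchors
#'
#' Per-bp profile of the mean integrated CpH level at each signed offset
#' from CpG anchors of the requested methylation state. By default only
#' CpHs on the anchor's strand contribute, which preserves asymmetric
#' features such as the ESC -4 bp peak; the both-strand mode is available.
#'
#' @param methylome integrated, context-annotated methylome.
#' @param anchor_state `"methylated"` (level >= 0.8) or `"unmethylated"`
#'   (level < 0.2).
#' @param radius window half-width in bp (default 500).
#' @param cph_strand `"anchor"` (default) or `"both"`.
#' @return a `distance_profile` `data.table` with `anchor_state`, `offset`
#'   (per bp), `value` (mean level; `NA` where no CpH occurs) and `n`
#'   (contributing site count).
#' @export
distance_level_profile <- function(methylome,
                                   anchor_state = c("methylated", "unmethylated"),
                                   radius = 500,
                                   cph_strand = c("anchor", "both")) {
  anchor_state <- match.arg(anchor_state)
  cph_strand <- match.arg(cph_strand)
  a <- anchor_sets(methylome)[[anchor_state]]
  if (nrow(a) == 0L) stop("no ", anchor_state, " CpG anchors")
  sites <- methylome[cclass == "CpH"]
  pr <- pair_offsets(a, sites, radius, cph_strand)
  grid <- data.table::data.table(offset = seq(-radius, radius))
  if (nrow(pr) > 0L) {
    pr[, level := sites$level[sid]]
    agg <- pr[, .(value = mean(level), n = .N), by = .(offset = d)]
    grid <- agg[grid, on = "offset"]
    grid[is.na(n), n := 0L]
  } else {
    grid[, `:=`(value = NA_real_, n = 0L)]
  }
  grid[, anchor_state := anchor_state]
  data.table::setcolorder(grid, c("anchor_state", "offset", "value", "n"))
  data.table::setorder(grid, offset)
  new_distance_profile(grid, "level", 1, radius)
}

#' Smooth a distance profile with a centered sliding window
#'
#' Centered moving average over `window` profile units (bins); even windows
#' are widened by one unit to stay symmetric, and edge windows are
#' truncated. Profiles holding several anchor states are smoothed per
#' state.
#'
#' @param profile a `distance_profile`.
#' @param window window size in profile units (default 10).
#' @return the smoothed profile (same shape).
#' @export
sliding_window_profile <- function(profile, window = 10) {
  out <- data.table::copy(profile)
  grp <- if ("anchor_state" %in% names(out)) "anchor_state" else NULL
  data.table::setorderv(out, c(grp, "offset"))
  if (is.null(grp)) {
    out[, value := moving_average(value, window)]
  } else {
    out[, value := moving_average(value, window), by = anchor_state]
  }
  new_distance_profile(out, attr(profile, "mode"),
                       attr(profile, "binwidth"), attr(profile, "radius"))
}

#' Dominant periodicity of a distance profile
#'
#' Mean-detrended autocorrelation of the profile values over a range of
#' lags; the best lag is the autocorrelation argmax. An optional
#' circular-shift permutation null quantifies whether the score exceeds
#' chance.
#'
#' @param profile a single-state `distance_profile` (or any table with
#'   `offset` and `value`).
#' @param lag_range numeric length-2, lag range in bp (default `c(5, 15)`;
#'   use `c(100, 300)` for nucleosome-scale spacing).
#' @param n_perm number of circular-shift permutations for the null (0 =
#'   none).
#' @param seed RNG seed for the permutations.
#' @return list with `best_lag` (bp), `score` (autocorrelation at the best
#'   lag), and `null_scores` (permutation maxima, when requested).
#' @export
periodicity_score <- function(profile, lag_range = c(5, 15), n_perm = 0L,
                              seed = 1L) {
  if ("anchor_state" %in% names(profile) &&
      length(unique(profile$anchor_state)) > 1L) {
    stop("profile holds several anchor states; subset to one")
  }
  bw <- attr(profile, "binwidth")
  if (is.null(bw)) bw <- 1
  x <- profile$value[order(profile$offset)]
  lags_units <- seq(ceiling(lag_range[1] / bw), floor(lag_range[2] / bw))
  if (length(lags_units) == 0L) stop("lag range contains no whole bins")
  if (length(x) < 2L * max(lags_units)) stop("profile shorter than 2x max lag")
  ac <- function(v) {
    vapply(lags_units, function(l) {
      suppressWarnings(stats::cor(v[seq_len(length(v) - l)],
                                  v[seq_len(length(v) - l) + l],
                                  use = "pairwise.complete.obs"))
    }, numeric(1))
  }
  r <- ac(x)
  best <- which.max(r)
  null_scores <- NULL
  if (n_perm > 0L) {
    null_scores <- with_seed(seed, {
      shifts <- sample.int(length(x) - 1L, n_perm, replace = TRUE)
      vapply(shifts, function(s) {
        xs <- c(x[(s + 1L):length(x)], x[seq_len(s)])
        max(ac(xs), na.rm = TRUE)
      }, numeric(1))
    })
  }
  list(best_lag = lags_units[best] * bw, score = r[best],
       null_scores = null_scores)
}

#' Bin a methylome into fixed-size genome blocks
#'
#' Unweighted per-block means of site levels by cytosine class and strand,
#' with site counts. Blocks are half-open `[start, start + block_size)` in
#' 0-based coordinates; empty classes yield `NA` means.
#'
#' @param methylome integrated, context-annotated methylome.
#' @param block_size block length in bp (default 1000).
#' @return a `data.table` of blocks with per-class/strand means and counts.
#' @export
bin_genome <- function(methylome, block_size = 1000L) {
  stopifnot(block_size >= 1L)
  nan2na <- function(x) ifelse(is.nan(x), NA_real_, x)
  blocks <- methylome[, {
    cg <- cclass == "CpG"; ch <- cclass == "CpH"; fw <- strand == "+"
    .(n_cpg = sum(cg), n_cph = sum(ch),
      mean_mcpg = nan2na(mean(level[cg])),
      mean_mcph = nan2na(mean(level[ch])),
      mean_mcpg_fwd = nan2na(mean(level[cg & fw])),
      mean_mcpg_rev = nan2na(mean(level[cg & !fw])),
      mean_mcph_fwd = nan2na(mean(level[ch & fw])),
      mean_mcph_rev = nan2na(mean(level[ch & !fw])))
  }, by = .(chrom, block = pos %/% as.integer(block_size))]
  blocks[, `:=`(start = block * as.integer(block_size),
                end = (block + 1L) * as.integer(block_size))]
  data.table::setorder(blocks, chrom, start)
  data.table::setcolorder(blocks, c("chrom", "block", "start", "end"))
  blocks[]
}

#' Genome-wide mCpG-mCpH block correlation
#'
#' Pearson correlation between per-block mean CpG and mean CpH levels over
#' blocks containing more than `min_cpg` CpGs and more than `min_cph` CpHs.
#'
#' @param blocks block table from [bin_genome()].
#' @param min_cpg,min_cph strict lower bounds on per-block site counts
#'   (default 10, matching the more-than-10 rule).
#' @return the correlation coefficient (`NaN`, with a warning, when either
#'   mean is constant over qualifying blocks).
#' @export
block_correlation <- function(blocks, min_cpg = 10L, min_cph = 10L) {
  q <- blocks[n_cpg > min_cpg & n_cph > min_cph &
                !is.na(mean_mcpg) & !is.na(mean_mcph)]
  if (nrow(q) < 3L) stop("insufficient blocks")
  if (stats::sd(q$mean_mcpg) == 0 || stats::sd(q$mean_mcph) == 0) {
    warning("constant block means; correlation undefined")
    return(NaN)
  }
  stats::cor(q$mean_mcpg, q$mean_mcph)
}

#' Strand-specific (hemi-methylation) CpH analysis
#'
#' Over blocks where the CpG level differs between strands by more than
#' `diff_cut`, pairs the mean CpH level on the strand carrying the higher
#' CpG methylation (cis) with that on the opposite strand (trans), and
#' tests the paired difference with a Wilcoxon signed-rank test.
#'
#' @param blocks block table from [bin_genome()].
#' @param diff_cut minimum between-strand mCpG difference (default 0.5).
#' @return list with `cis_mean`, `trans_mean`, `p_value`, `n_blocks`.
#' @export
hemi_strand_analysis <- function(blocks, diff_cut = 0.5) {
  q <- blocks[!is.na(mean_mcpg_fwd) & !is.na(mean_mcpg_rev) &
                !is.na(mean_mcph_fwd) & !is.na(mean_mcph_rev) &
                abs(mean_mcpg_fwd - mean_mcpg_rev) > diff_cut]
  if (nrow(q) == 0L) stop("no blocks pass the hemi-methylation criterion")
  fwd_high <- q$mean_mcpg_fwd > q$mean_mcpg_rev
  cis <- ifelse(fwd_high, q$mean_mcph_fwd, q$mean_mcph_rev)
  trans <- ifelse(fwd_high, q$mean_mcph_rev, q$mean_mcph_fwd)
  pv <- tryCatch(
    suppressWarnings(stats::wilcox.test(cis, trans, paired = TRUE)$p.value),
    error = function(e) NA_real_)
  list(cis_mean = mean(cis), trans_mean = mean(trans), p_value = pv,
       n_blocks = nrow(q))
}

#' Annotate genome blocks with genic region classes
#'
#' Assigns each block to `promoter` (TSS +/- `promoter_flank`),
#' `intragenic` (TSS..TTS) or `intergenic`, requiring more than
#' `min_overlap` bp of the block to be covered by the region; promoter
#' takes precedence over intragenic.
#'
#' @param blocks block table from [bin_genome()].
#' @param genes gene table from [read_genes()].
#' @param promoter_flank promoter half-width around the TSS (default 5000).
#' @param min_overlap strict minimum covered bp for assignment (default
#'   500).
#' @return `blocks` with a `region` column added.
#' @export
annotate_blocks_genic <- function(blocks, genes, promoter_flank = 5000L,
                                  min_overlap = 500L) {
  out <- data.table::copy(blocks)
  out[, region := "intergenic"]
  tss0 <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  prom <- data.table::data.table(chrom = genes$chrom,
                                 start = pmax(tss0 - promoter_flank, 0L),
                                 end = tss0 + promoter_flank + 1L)
  body <- genes[, .(chrom, start, end)]
  cov_by <- function(regions) {
    covered <- numeric(nrow(out))
    for (ch in unique(out$chrom)) {
      bi <- which(out$chrom == ch)
      rg <- regions[chrom == ch]
      if (nrow(rg) == 0L) next
      red <- IRanges::reduce(IRanges::IRanges(rg$start + 1L, rg$end))
      bir <- IRanges::IRanges(out$start[bi] + 1L, out$end[bi])
      hits <- IRanges::findOverlaps(bir, red)
      if (length(hits) == 0L) next
      w <- IRanges::width(IRanges::pintersect(
        bir[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]))
      covered[bi] <- covered[bi] +
        as.numeric(tapply(w, factor(S4Vectors::queryHits(hits),
                                    levels = seq_along(bi)), sum,
                          default = 0))
    }
    covered
  }
  out[cov_by(body) > min_overlap, region := "intragenic"]
  out[cov_by(prom) > min_overlap, region := "promoter"]
  out[]
}

#' mCpG-proximal pattern vectors, PCC matrix and sample clustering
#'
#' In `"proximal"` mode each sample is summarised by its per-offset mean
#' CpH level within +/-`radius` bp of its methylated CpGs (anchor strand);
#' in `"blocks"` mode by its per-block mean level (CpH or CpG) over the
#' common block grid. Samples are compared by Pearson correlation and
#' clustered on distance `1 - PCC`.
#'
#' @param methylomes named list (>= 2) of integrated, context-annotated
#'   methylomes.
#' @param mode `"proximal"` or `"blocks"`.
#' @param radius proximal window half-width in bp (default 100).
#' @param value_class which site class drives the block mode (`"cph"` or
#'   `"cpg"`).
#' @param linkage hierarchical clustering linkage (default `"average"`).
#' @param block_size block size for the block mode.
#' @return list of class `pattern_clustering` with `vectors` (feature x
#'   sample matrix), `pcc`, `hclust`, `order` (dendrogram label order) and
#'   `newick`.
#' @export
proximal_pattern_matrix <- function(methylomes, mode = c("proximal", "blocks"),
                                    radius = 100L,
                                    value_class = c("cph", "cpg"),
                                    linkage = "average", block_size = 1000L) {
  mode <- match.arg(mode)
  value_class <- match.arg(value_class)
  stopifnot(length(methylomes) >= 2L, !is.null(names(methylomes)))
  if (mode == "proximal") {
    vecs <- lapply(methylomes, function(m) {
      pr <- distance_level_profile(m, "methylated", radius = radius)
      stats::setNames(pr$value, pr$offset)
    })
    feat <- as.character(seq(-radius, radius))
    V <- vapply(vecs, function(v) v[feat], numeric(length(feat)))
  } else {
    col <- if (value_class == "cph") "mean_mcph" else "mean_mcpg"
    tabs <- lapply(names(methylomes), function(nm) {
      b <- bin_genome(methylomes[[nm]], block_size)
      data.table::data.table(chrom = b$chrom, block = b$block, v = b[[col]])
    })
    merged <- Reduce(function(x, y) merge(x, y, by = c("chrom", "block")),
                     tabs)
    V <- as.matrix(merged[, -(1:2)])
    colnames(V) <- names(methylomes)
  }
  keep <- rowSums(is.na(V)) == 0
  V <- V[keep, , drop = FALSE]
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0)) warning("constant pattern vector(s): ",
                             paste(colnames(V)[sds == 0], collapse = ", "))
  pcc <- suppressWarnings(stats::cor(V))
  h <- stats::hclust(stats::as.dist(1 - pcc), method = linkage)
  structure(list(vectors = V, pcc = pcc, hclust = h,
                 order = h$labels[h$order],
                 newick = ape::write.tree(ape::as.phylo(h))),
            class = "pattern_clustering")
}

#' Per-offset association between CpG anchors and surrounding CpH levels
#'
#' Pearson correlation between anchor CpG level and CpH level, computed per
#' signed-offset bin over all (anchor, CpH) pairs at that offset. On data
#' with distance-local mCpG/mCpH coupling the correlation is maximal near
#' offset zero and decays with distance.
#'
#' @param methylome integrated, context-annotated methylome.
#' @param radius window half-width in bp (default 500).
#' @param binwidth offset bin width in bp (default 10).
#' @param cph_strand `"anchor"` (default) or `"both"`.
#' @return a `distance_profile` with `offset` (bin start), `value`
#'   (per-bin PCC) and `n` (pair count).
#' @export
distance_correlation_profile <- function(methylome, radius = 500L,
                                         binwidth = 10L,
                                         cph_strand = c("anchor", "both")) {
  cph_strand <- match.arg(cph_strand)
  anchors <- methylome[cclass == "CpG"]
  sites <- methylome[cclass == "CpH"]
  if (nrow(anchors) == 0L || nrow(sites) == 0L) stop("need CpG and CpH sites")
  pr <- pair_offsets(anchors, sites, radius, cph_strand)
  pr[, `:=`(a_level = anchors$level[aid], s_level = sites$level[sid],
            bin = (d + as.integer(radius)) %/% as.integer(binwidth))]
  nbins <- as.integer(2 * radius / binwidth)
  pr <- pr[bin >= 0L & bin < nbins]
  agg <- pr[, .(value = suppressWarnings(stats::cor(a_level, s_level)),
                n = .N), by = bin]
  grid <- data.table::data.table(bin = seq_len(nbins) - 1L)
  agg <- agg[grid, on = "bin"]
  agg[is.na(n), n := 0L]
  agg[, offset := bin * as.integer(binwidth) - as.integer(radius)]
  data.table::setorder(agg, offset)
  out <- agg[, .(offset, value, n)]
  new_distance_profile(out, "correlation", binwidth, radius)
}

#' Recover the mCpG-mCpH coupling-kernel width
#'
#' Contrasts the mean CpH level at each absolute distance bin between
#' methylated (level >= 0.8) and unmethylated (level < 0.2) CpG anchors.
#' This contrast is proportional to the distance-coupling kernel, so the
#' distance at which it falls to half its (smoothed) maximum estimates the
#' kernel's half-maximum width. The per-offset Pearson correlation profile
#' ([distance_correlation_profile()]) shows the same locality but its
#' amplitude also reflects the distance-dependent variance of CpH levels,
#' which inflates a half-max read-off; the level contrast is linear in the
#' kernel and is therefore used for width estimation.
#'
#' @param methylome integrated, context-annotated methylome (true
#'   methylomes from the simulator work as well).
#' @param radius maximum distance examined in bp (default 300).
#' @param binwidth absolute-distance bin width in bp (default 10).
#' @param cph_strand `"anchor"` (default) or `"both"`.
#' @return list with `width` (bp, linearly interpolated half-max crossing;
#'   `NA` when the contrast never drops below half) and `profile` (bin
#'   centers, contrast values, pair counts).
#' @export
coupling_width <- function(methylome, radius = 300L, binwidth = 10L,
                           cph_strand = c("anchor", "both")) {
  cph_strand <- match.arg(cph_strand)
  anch <- anchor_sets(methylome)
  sites <- methylome[cclass == "CpH"]
  if (nrow(anch$methylated) == 0L || nrow(anch$unmethylated) == 0L) {
    stop("need both methylated and unmethylated CpG anchors")
  }
  nbins <- as.integer(radius / binwidth)
  mean_by_bin <- function(a) {
    pr <- pair_offsets(a, sites, radius, cph_strand)
    pr[, `:=`(level = sites$level[sid], bin = abs(d) %/% as.integer(binwidth))]
    pr <- pr[bin < nbins]
    agg <- pr[, .(m = mean(level), n = .N), by = bin]
    agg[data.table::data.table(bin = seq_len(nbins) - 1L), on = "bin"]
  }
  mm <- mean_by_bin(anch$methylated)
  mu <- mean_by_bin(anch$unmethylated)
  contrast <- mm$m - mu$m
  centers <- (seq_len(nbins) - 0.5) * binwidth
  sm <- moving_average(contrast, 3L)
  peak <- which.max(sm)
  half <- sm[peak] / 2
  width <- NA_real_
  below <- which(seq_len(nbins) > peak & sm <= half)
  if (length(below)) {
    i <- below[1L]
    # linear interpolation between the last bin above half and this one
    x0 <- centers[i - 1L]; y0 <- sm[i - 1L]
    x1 <- centers[i]; y1 <- sm[i]
    width <- if (y0 == y1) x1 else x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
  }
  list(width = width,
       profile = data.table::data.table(center = centers, contrast = contrast,
                                        n = mm$n + mu$n))
}

#' Write a distance profile as TSV
#'
#' @param profile a `distance_profile`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path) {
  write_tsv_file(data.table::as.data.table(profile), path)
}
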