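# Seeded synthetic-data generator: reference genomes with CpG depletion,
# cell-type-mode true methylomes (bimodal CpG dyads, distance-kernel CpH
# deposition with context weights), expression and histone-peak tracks, and
# multi-aligner read-count tables with bisulfite non-conversion noise.

.MODE_DEFAULTS <- list(
  esc = list(amplitude = 0.20,
             context_weights = c(CAC = 0.15, CAT = 0.10, CAA = 0.30,
                                 CAG = 1.00, other = 0.05),
             kernel_width = 100, peak_offset = -4, peak_boost = 2,
             period = 0, period_strength = 0, nucleosome_period = 0,
             nucleosome_strength = 0, expression_coupling = 0.4),
  neuron = list(amplitude = 0.45,
                context_weights = c(CAC = 1.00, CAT = 0.30, CAA = 0.15,
                                    CAG = 0.15, other = 0.05),
                kernel_width = 100, peak_offset = 0, peak_boost = 0,
                period = 9, period_strength = 0.6, nucleosome_period = 0,
                nucleosome_strength = 0, expression_coupling = -0.3),
  somatic = list(amplitude = 0.01,
                 context_weights = c(CAC = 0.30, CAT = 0.20, CAA = 0.20,
                                     CAG = 0.30, other = 0.05),
                 kernel_width = 100, peak_offset = 0, peak_boost = 0,
                 period = 0, period_strength = 0, nucleosome_period = 0,
                 nucleosome_strength = 0, expression_coupling = 0),
  d1ko = list(amplitude = 0.25,
              context_weights = c(CAC = 0.15, CAT = 0.10, CAA = 0.30,
                                  CAG = 1.00, other = 0.05),
              kernel_width = 300, peak_offset = 0, peak_boost = 0,
              period = 0, period_strength = 0, nucleosome_period = 180,
              nucleosome_strength = 0.8, expression_coupling = 0.4),
  d3ko = list(amplitude = 0.002,
              context_weights = c(CAC = 0.15, CAT = 0.10, CAA = 0.30,
                                  CAG = 1.00, other = 0.05),
              kernel_width = 100, peak_offset = 0, peak_boost = 0,
              period = 0, period_strength = 0, nucleosome_period = 0,
              nucleosome_strength = 0, expression_coupling = 0),
  d3bko = list(amplitude = 0.15,
               context_weights = c(CAC = 0.60, CAT = 0.25, CAA = 0.05,
                                   CAG = 0.05, other = 0.05),
               kernel_width = 100, peak_offset = 0, peak_boost = 0,
               period = 9, period_strength = 0.6, nucleosome_period = 0,
               nucleosome_strength = 0, expression_coupling = 0),
  setd2ko = list(amplitude = 0.20,
                 context_weights = c(CAC = 0.15, CAT = 0.10, CAA = 0.30,
                                     CAG = 1.00, other = 0.05),
                 kernel_width = 100, peak_offset = -4, peak_boost = 2,
                 period = 0, period_strength = 0, nucleosome_period = 0,
                 nucleosome_strength = 0, expression_coupling = 0))

#' Simulation configuration
#'
#' Mode-resolved parameter set for the synthetic-data generator. Each mode
#' encodes one cell-type/knockout scenario: `esc` deposits CpH methylation
#' preferentially at CAG (weakly CAA) with a -4 bp peak ahead of methylated
#' CpGs and positive coupling of gene-body deposition to expression through
#' H3K36me3-like peaks; `neuron` prefers CAC with 9-bp periodic deposition
#' and negative expression coupling; `d1ko` adds a 180-bp nucleosome-scale
#' envelope; `d3ko` removes almost all CpH deposition; `d3bko` suppresses
#' CAG/CAA deposition (CAC remains) and erases the expression coupling;
#' `setd2ko` keeps ESC context preferences but uncouples gene bodies from
#' expression. Any default can be overridden by name.
#'
#' @param mode one of `esc`, `neuron`, `somatic`, `d1ko`, `d3ko`, `d3bko`,
#'   `setd2ko`.
#' @param seed master RNG seed; every generator stage derives its stream
#'   from it.
#' @param genome_length total genome length in bp.
#' @param gc_content genome GC fraction before CpG depletion.
#' @param cpg_depletion probability that the G of a nascent CpG dinucleotide
#'   is mutated away, emulating mammalian CpG depletion.
#' @param n_genes number of non-overlapping genes.
#' @param gene_length_range gene length range in bp (log-uniform).
#' @param mcpg_high_fraction fraction of CpG dyads drawn from the
#'   methylated mode.
#' @param hemi_fraction fraction of 1-kb segments whose CpG dyads are
#'   hemi-methylated (high on one randomly chosen strand).
#' @param background baseline CpH deposition propensity.
#' @param amplitude CpH deposition amplitude multiplying the distance
#'   kernel.
#' @param context_weights named deposition weights for CAC, CAT, CAA, CAG
#'   and other CpH contexts.
#' @param kernel_width half-maximum width (bp) of the distance-decay kernel
#'   around methylated CpG anchors.
#' @param peak_offset,peak_boost position (bp) and strength of a localized
#'   Gaussian deposition peak relative to the anchor.
#' @param peak_sigma width (bp) of the localized peak; the default 0.8 bp
#'   keeps the boost essentially confined to its single offset, matching
#'   the sharp single-position character of the feature it emulates.
#' @param period,period_strength period (bp) and depth of cosine
#'   modulation of deposition with distance.
#' @param nucleosome_period,nucleosome_strength nucleosome-scale cosine
#'   modulation.
#' @param expression_coupling target Spearman correlation between true
#'   gene-body CpH level and FPKM, planted through a Gaussian copula whose
#'   methylation-facing latent drives the histone-peak coverage.
#' @param ncr bisulfite non-conversion rate applied to read simulation.
#' @param depth_mean mean (Poisson) read depth per cytosine.
#' @param n_aligners number of aligners the reads are split across.
#' @param aligner_dropout per-site probability that an aligner reports no
#'   reads.
#' @param fpkm_meanlog,fpkm_sdlog log-normal expression parameters.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(mode = c("esc", "neuron", "somatic", "d1ko",
                                       "d3ko", "d3bko", "setd2ko"),
                              seed = 1L,
                              genome_length = 400000L,
                              gc_content = 0.42,
                              cpg_depletion = 0.9,
                              n_genes = 40L,
                              gene_length_range = c(1000, 20000),
                              mcpg_high_fraction = 0.75,
                              hemi_fraction = 0.05,
                              background = 2e-4,
                              amplitude = NULL,
                              context_weights = NULL,
                              kernel_width = NULL,
                              peak_offset = NULL, peak_boost = NULL,
                              peak_sigma = 0.8,
                              period = NULL, period_strength = NULL,
                              nucleosome_period = NULL,
                              nucleosome_strength = NULL,
                              expression_coupling = NULL,
                              ncr = 0.005,
                              depth_mean = 15,
                              n_aligners = 3L,
                              aligner_dropout = 0.15,
                              fpkm_meanlog = 1, fpkm_sdlog = 1.5) {
  mode <- match.arg(mode)
  md <- .MODE_DEFAULTS[[mode]]
  pick <- function(x, nm) if (is.null(x)) md[[nm]] else x
  cfg <- list(mode = mode, seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              gc_content = gc_content, cpg_depletion = cpg_depletion,
              n_genes = as.integer(n_genes),
              gene_length_range = gene_length_range,
              mcpg_high_fraction = mcpg_high_fraction,
              hemi_fraction = hemi_fraction,
              background = background,
              amplitude = pick(amplitude, "amplitude"),
              context_weights = pick(context_weights, "context_weights"),
              kernel_width = pick(kernel_width, "kernel_width"),
              peak_offset = pick(peak_offset, "peak_offset"),
              peak_boost = pick(peak_boost, "peak_boost"),
              peak_sigma = peak_sigma,
              period = pick(period, "period"),
              period_strength = pick(period_strength, "period_strength"),
              nucleosome_period = pick(nucleosome_period, "nucleosome_period"),
              nucleosome_strength = pick(nucleosome_strength,
                                         "nucleosome_strength"),
              expression_coupling = pick(expression_coupling,
                                         "expression_coupling"),
              ncr = ncr, depth_mean = depth_mean,
              n_aligners = as.integer(n_aligners),
              aligner_dropout = aligner_dropout,
              fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog)
  stopifnot(cfg$gc_content > 0, cfg$gc_content < 1,
            all(cfg$context_weights >= 0),
            cfg$ncr >= 0, cfg$ncr < 1,
            all(c("CAC", "CAT", "CAA", "CAG", "other") %in%
                  names(cfg$context_weights)))
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic reference genome and gene models
#'
#' Draws i.i.d. bases at the configured GC content, then depletes CpG
#' dinucleotides (the G of a fraction `cpg_depletion` of CG pairs is
#' replaced by A or T) so that CpG dyads are sparse, as in mammalian
#' genomes. Non-overlapping genes with log-uniform lengths are placed on
#' random strands.
#'
#' @param cfg a [simulation_config()].
#' @param seed RNG seed (defaults to the config's master seed).
#' @return list with `genome` (named character vector, single chromosome
#'   `chrS`) and `genes` (gene table in the [read_genes()] layout).
#' @export
generate_genome <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    L <- cfg$genome_length
    gc <- cfg$gc_content
    b <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    i <- which(b[-L] == "C" & b[-1L] == "G")
    if (length(i)) {
      mut <- i[stats::runif(length(i)) < cfg$cpg_depletion]
      if (length(mut)) {
        b[mut + 1L] <- sample(c("A", "T"), length(mut), replace = TRUE)
      }
    }
    genome <- c(chrS = paste(b, collapse = ""))

    n <- cfg$n_genes
    lr <- log(cfg$gene_length_range)
    lens <- as.integer(round(exp(stats::runif(n, lr[1], lr[2]))))
    if (sum(lens) + 10L * n > L) stop("genes cannot be placed")
    extra <- L - sum(lens)
    offsets <- floor(sort(stats::runif(n)) * extra)
    starts <- as.integer(offsets + cumsum(c(0L, lens[-n])))
    ends <- starts + lens
    strand <- sample(c("+", "-"), n, replace = TRUE)
    genes <- data.table::data.table(
      gene_id = sprintf("G%04d", seq_len(n)), chrom = "chrS",
      strand = strand,
      tss = ifelse(strand == "+", starts + 1L, ends),
      tts = ifelse(strand == "+", ends, starts + 1L),
      start = starts, end = ends, length = lens)
    list(genome = genome, genes = genes)
  })
}

#' Generate expression values and histone-like peaks for genes
#'
#' Per gene, a standard-normal expression latent sets the log-normal FPKM.
#' A second latent, correlated with the first so that the planted Spearman
#' correlation between deposition and expression equals
#' `expression_coupling` (Gaussian-copula relation `r = 2 sin(pi rho / 6)`),
#' drives the histone-peak coverage of the gene body through a logistic
#' link; gene-body CpH deposition is then driven by the peak coverage, not
#' by expression directly, so methylation correlates more tightly with the
#' peak overlap rate than with FPKM.
#'
#' @param genes gene table from [generate_genome()].
#' @param cfg a [simulation_config()].
#' @param seed RNG seed (defaults to master seed + 1).
#' @return list with `genes` (input plus `fpkm`, `overlap_rate`,
#'   `body_mult`), `expression` (`gene_id`, `fpkm`) and `peaks` (BED-style
#'   `chrom`, `start`, `end`).
#' @export
generate_expression_and_peaks <- function(genes, cfg, seed = cfg$seed + 1L) {
  stopifnot(nrow(genes) >= 1L)
  with_seed(seed, {
    n <- nrow(genes)
    u <- stats::rnorm(n)
    rho <- cfg$expression_coupling
    r <- 2 * sin(pi * rho / 6)
    v <- r * u + sqrt(max(1 - r^2, 0)) * stats::rnorm(n)
    fpkm <- exp(cfg$fpkm_meanlog + cfg$fpkm_sdlog * u)
    overlap <- stats::plogis(1.4 * v)
    g <- data.table::copy(genes)
    g[, `:=`(fpkm = fpkm, overlap_rate = overlap,
             body_mult = if (rho != 0) 0.1 + 2.2 * overlap else 1)]
    peak_len <- pmax(as.integer(round(overlap * g$length)), 1L)
    peak_start <- g$start +
      as.integer(floor(stats::runif(n) * (g$length - peak_len + 1L)))
    peaks <- data.table::data.table(chrom = g$chrom, start = peak_start,
                                    end = peak_start + peak_len)
    data.table::setorder(peaks, chrom, start)
    list(genes = g,
         expression = g[, .(gene_id, fpkm)],
         peaks = peaks)
  })
}

# Distance-decay deposition kernel; d is the signed strand-oriented offset
# from the nearest methylated CpG anchor (negative = 5' of the anchor).
kernel_value <- function(d, cfg) {
  K <- 2^(-(d / cfg$kernel_width)^2)
  if (cfg$peak_boost > 0) {
    K <- K * (1 + cfg$peak_boost *
                exp(-((d - cfg$peak_offset)^2) / (2 * cfg$peak_sigma^2)))
  }
  if (cfg$period > 0) {
    K <- K * pmax(1 + cfg$period_strength * cos(2 * pi * d / cfg$period), 0)
  }
  if (cfg$nucleosome_period > 0) {
    K <- K * pmax(1 + cfg$nucleosome_strength *
                    cos(2 * pi * d / cfg$nucleosome_period), 0)
  }
  K[!is.finite(d)] <- 0
  K
}

#' Generate a true methylome over a classified genome
#'
#' CpG dyads are bimodal: a `mcpg_high_fraction` of dyads draws both strand
#' levels from a high Beta mode (mean ~0.9), the rest from a low mode
#' (mean ~0.05); in `hemi_fraction` of 1-kb segments all dyads are
#' hemi-methylated (high on one randomly chosen strand). Each CpH site's
#' deposition propensity is `background + amplitude * K(d) * w(context) *
#' body_mult`, where `d` is the signed distance to the nearest methylated
#' CpG on the same strand, `K` the mode's kernel, `w` the context weight,
#' and `body_mult` the gene-body modulation from
#' [generate_expression_and_peaks()]. Sites fire as Bernoulli draws of the
#' propensity; firing sites get a Beta(2.2, 1.8) level (mean 0.55), others
#' zero.
#'
#' @param context context table from [classify_cytosines()].
#' @param cfg a [simulation_config()].
#' @param genes optional gene table carrying `body_mult` (from
#'   [generate_expression_and_peaks()]); without it no gene-body modulation
#'   is applied.
#' @param seed RNG seed (defaults to master seed + 2).
#' @return the context table with `level` (true methylation level),
#'   `propensity` and `methylated` columns added.
#' @export
generate_true_methylome <- function(context, cfg, genes = NULL,
                                    seed = cfg$seed + 2L) {
  truth <- data.table::copy(context)
  with_seed(seed, {
    is_cpg <- truth$cclass == "CpG"
    lev <- numeric(nrow(truth))
    prop <- numeric(nrow(truth))
    meth <- logical(nrow(truth))

    # --- CpG dyads -------------------------------------------------------
    cpg <- truth[is_cpg, .(chrom, pos, strand)]
    cpg[, dyad := ifelse(strand == "+", pos, pos - 1L)]
    dyads <- unique(cpg[, .(chrom, dyad)])
    dyads[, segment := dyad %/% 1000L]
    segs <- unique(dyads[, .(chrom, segment)])
    segs[, hemi := stats::runif(.N) < cfg$hemi_fraction]
    segs[, hemi_high := sample(c("+", "-"), .N, replace = TRUE)]
    dyads <- segs[dyads, on = c("chrom", "segment")]
    dyads[, high := stats::runif(.N) < cfg$mcpg_high_fraction]
    cpg <- dyads[cpg, on = c("chrom", "dyad")]
    strand_high <- ifelse(cpg$hemi, cpg$strand == cpg$hemi_high, cpg$high)
    n_cpg <- nrow(cpg)
    cpg_lev <- ifelse(strand_high,
                      stats::rbeta(n_cpg, 27, 3),
                      stats::rbeta(n_cpg, 1.5, 28.5))
    # map back in original row order of the CpG subset
    lev[is_cpg] <- cpg_lev
    prop[is_cpg] <- NA_real_
    meth[is_cpg] <- cpg_lev >= meth_cutoffs$mcpg

    # --- CpH deposition --------------------------------------------------
    cph_idx <- which(!is_cpg)
    w <- cfg$context_weights
    tri <- truth$trinuc[cph_idx]
    wsite <- ifelse(tri %in% c("CAC", "CAT", "CAA", "CAG"), w[tri], w["other"])

    # signed distance to nearest methylated CpG anchor on the same strand
    d <- rep(Inf, length(cph_idx))
    anchors <- truth[is_cpg][lev[is_cpg] >= meth_cutoffs$mcpg,
                             .(chrom, pos, strand)]
    cph <- truth[cph_idx, .(chrom, pos, strand)]
    for (ch in unique(cph$chrom)) {
      for (st in c("+", "-")) {
        si <- which(cph$chrom == ch & cph$strand == st)
        ap <- sort(anchors[chrom == ch & strand == st, pos])
        if (length(si) == 0L || length(ap) == 0L) next
        sp <- cph$pos[si]
        iv <- findInterval(sp, ap)
        dl <- sp - ap[pmax(iv, 1L)]
        dl[iv == 0L] <- Inf
        dr <- sp - ap[pmin(iv + 1L, length(ap))]
        dr[iv >= length(ap)] <- -Inf
        gd <- ifelse(abs(dl) <= abs(dr), dl, dr)
        d[si] <- if (st == "+") gd else -gd
      }
    }

    mult <- rep(1, length(cph_idx))
    if (!is.null(genes) && "body_mult" %in% names(genes)) {
      gsub <- genes[, .(chrom, start, end, body_mult)]
      sites <- data.table::data.table(chrom = cph$chrom, pos = cph$pos,
                                      row = seq_along(cph_idx))
      hit <- gsub[sites, on = .(chrom, start <= pos, end > pos),
                  nomatch = NULL, .(row = i.row, body_mult = x.body_mult)]
      mult[hit$row] <- hit$body_mult
    }

    q <- pmin(cfg$background + cfg$amplitude * kernel_value(d, cfg) *
                wsite * mult, 0.9)
    fired <- stats::runif(length(q)) < q
    m <- numeric(length(q))
    m[fired] <- stats::rbeta(sum(fired), 2.2, 1.8)
    lev[cph_idx] <- m
    prop[cph_idx] <- q
    meth[cph_idx] <- fired
  })
  truth[, `:=`(level = lev, propensity = prop, methylated = meth)]
  truth[]
}

#' Simulate bisulfite read counts for given true levels
#'
#' Per site: total depth `~ Poisson(depth_mean)` and methylated (observed
#' unconverted) reads `~ Binomial(depth, m + (1 - m) * ncr)`, where the
#' non-conversion rate acts symmetrically on all unmethylated molecules.
#'
#' @param m true methylation levels.
#' @param depth_mean mean read depth.
#' @param ncr non-conversion rate.
#' @param seed RNG seed.
#' @return a `data.table` with `depth` and `k` (methylated reads).
#' @export
simulate_read_counts <- function(m, depth_mean, ncr, seed) {
  with_seed(seed, {
    n <- stats::rpois(length(m), depth_mean)
    k <- stats::rbinom(length(m), n, m + (1 - m) * ncr)
    data.table::data.table(depth = n, k = k)
  })
}

#' Generate multi-aligner count tables from a true methylome
#'
#' Draws per-site totals and methylated reads with
#' [simulate_read_counts()], then splits the total reads across aligners
#' multinomially (sequential binomial splits) with independent per-aligner
#' dropout, and partitions the methylated reads hypergeometrically so the
#' split is consistent with the totals. Aligner labels are exchangeable.
#'
#' @param truth true methylome from [generate_true_methylome()].
#' @param cfg a [simulation_config()].
#' @param seed RNG seed (defaults to master seed + 3).
#' @return long multi-aligner count table (`chrom`, `pos`, `strand`,
#'   `aligner`, `t`, `M`), zero-read aligner entries omitted.
#' @export
generate_counts <- function(truth, cfg, seed = cfg$seed + 3L) {
  with_seed(seed, {
    N <- nrow(truth)
    n <- stats::rpois(N, cfg$depth_mean)
    k <- stats::rbinom(N, n, truth$level + (1 - truth$level) * cfg$ncr)
    A <- cfg$n_aligners
    active <- matrix(stats::runif(N * A) >= cfg$aligner_dropout, N, A)
    none <- !rowSums(active)
    if (any(none)) {
      active[cbind(which(none), sample.int(A, sum(none), replace = TRUE))] <- TRUE
    }
    wsum <- rowSums(active)
    t_rem <- n
    k_rem <- k
    parts <- vector("list", A)
    w_left <- wsum
    for (j in seq_len(A)) {
      pj <- ifelse(w_left > 0, active[, j] / w_left, 0)
      tj <- stats::rbinom(N, t_rem, pj)
      kj <- stats::rhyper(N, m = k_rem, n = t_rem - k_rem, k = tj)
      parts[[j]] <- data.table::data.table(
        chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
        aligner = sprintf("aligner%d", j), t = tj, M = kj)
      t_rem <- t_rem - tj
      k_rem <- k_rem - kj
      w_left <- w_left - active[, j]
    }
    out <- data.table::rbindlist(parts)[t > 0L]
    data.table::setorder(out, chrom, pos, strand, aligner)
    out[]
  })
}

#' Simulate a complete dataset
#'
#' Runs the whole generator (genome, genes, expression/peaks, true
#' methylome, multi-aligner counts) under the config's master seed and
#' optionally writes every artifact as plain text.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional output directory; created when missing. Writes
#'   `genome.fa`, per-aligner `aligner<j>.tsv.gz` reports (generic
#'   dialect), `genes.tsv`, `expression.tsv`, `peaks.bed`, and
#'   `truth.tsv.gz`.
#' @return list with `cfg`, `genome`, `context`, `genes` (with expression,
#'   overlap and modulation columns), `expression`, `peaks`, `truth`,
#'   `counts`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  gen <- generate_genome(cfg)
  context <- classify_cytosines(gen$genome)
  gx <- generate_expression_and_peaks(gen$genes, cfg)
  truth <- generate_true_methylome(context, cfg, gx$genes)
  counts <- generate_counts(truth, cfg)
  out <- list(cfg = cfg, genome = gen$genome, context = context,
              genes = gx$genes, expression = gx$expression,
              peaks = gx$peaks, truth = truth, counts = counts)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(gen$genome),
                                file.path(dir, "genome.fa"))
    for (al in unique(counts$aligner)) {
      rep_j <- counts[aligner == al,
                      .(chrom, pos = pos + 1L, strand, t, M)]
      write_tsv_file(rep_j, file.path(dir, paste0(al, ".tsv.gz")),
                     header = FALSE)
    }
    write_genes(gx$genes, file.path(dir, "genes.tsv"))
    write_tsv_file(gx$expression, file.path(dir, "expression.tsv"))
    write_tsv_file(gx$peaks, file.path(dir, "peaks.bed"), header = FALSE)
    tr <- truth[, .(chrom, pos = pos + 1L, strand, cclass, trinuc, symclass,
                    level = round(level, 6),
                    propensity = round(propensity, 6), methylated)]
    write_tsv_file(tr, file.path(dir, "truth.tsv.gz"))
  }
  out
}
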