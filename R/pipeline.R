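# End-to-end orchestration: configuration with auditable defaults, staged
# execution, and a machine-readable output manifest.

# Every tunable threshold with its default; a run config records both the
# defaults and any override so the effective values are auditable.
default_thresholds <- function() {
  list(min_depth = 5L, min_aligners = 2L,
       fdr_target = 0.01, call_threshold = 1e-5,
       block_size = 1000L, min_cpg = 10L, min_cph = 10L, hemi_diff = 0.5,
       profile_radius = 500L, profile_binwidth = 10L,
       proximal_radius = 100L, smooth_window = 10L,
       proximal_anchor_level = 0.5, hyper_mcph_level = 0.5,
       metagene_bins = 1000L, metagene_flank = 0.2, metagene_smooth = 30L,
       min_gene_len = 1000L, mcag_cut = 0.05, overlap_cut = 0.5)
}

#' Build a pipeline run configuration
#'
#' @param samples named list; each element describes one sample as
#'   `list(reports = <paths>, dialects = <one per report>, ncr = <rate>)`.
#' @param genome_fasta path to the reference FASTA.
#' @param out_dir output directory (created when missing).
#' @param genes,expression,peaks optional paths to a gene table,
#'   expression table and peak BED for the gene-analysis stage.
#' @param seed master seed for the FDR calibration's artificial methylome.
#' @param stages which stages to run, in dependency order; `call` is
#'   always required.
#' @param thresholds named overrides of [default_thresholds()].
#' @return list of class `run_config` with `thresholds` fully resolved and
#'   the defaults recorded beside the overrides.
#' @export
run_config <- function(samples, genome_fasta, out_dir,
                       genes = NULL, expression = NULL, peaks = NULL,
                       seed = 1L,
                       stages = c("call", "landscape", "context", "genes"),
                       thresholds = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(length(samples) >= 1L, !is.null(names(samples)))
  defaults <- default_thresholds()
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown)) stop("unknown threshold(s): ",
                            paste(unknown, collapse = ", "))
  eff <- utils::modifyList(defaults, thresholds)
  structure(list(samples = samples, genome_fasta = genome_fasta,
                 genes = genes, expression = expression, peaks = peaks,
                 out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, thresholds = eff,
                 threshold_defaults = defaults),
            class = "run_config")
}

run_stage <- function(name, detail, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed on %s: %s", name, detail,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order — methylation calling
#' (read, filter, integrate, calibrate, call), landscape profiling, context
#' and motif summaries, and gene-body analysis — writing every result as a
#' plain-text table under `out_dir` and finishing with a machine-readable
#' `manifest.json` that records the package version, the effective
#' configuration (with defaults), MD5 hashes of all inputs and outputs, and
#' the seed, so a run can be reproduced exactly.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  th <- cfg$thresholds
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(rel, writer) {
    path <- file.path(cfg$out_dir, rel)
    writer(path)
    outputs <<- c(outputs, rel)
    path
  }

  genome <- run_stage("reference", cfg$genome_fasta,
                      read_genome_fasta(cfg$genome_fasta))
  context <- run_stage("reference", cfg$genome_fasta,
                       classify_cytosines(genome))
  emit("context_index.tsv.gz", function(p) write_context_index(context, p))

  genes <- expr <- peaks <- NULL
  if (!is.null(cfg$genes)) genes <- read_genes(cfg$genes)
  if (!is.null(cfg$expression)) expr <- read_expression(cfg$expression)
  if (!is.null(cfg$peaks)) peaks <- read_peaks(cfg$peaks)

  methylomes <- list()
  calls <- list()
  for (sid in names(cfg$samples)) {
    sm <- cfg$samples[[sid]]
    called <- run_stage("call", sid, {
      tabs <- Map(function(path, dialect, j) {
        read_cytosine_report(path, dialect, paste0("aligner", j),
                             context = context)
      }, sm$reports, sm$dialects, seq_along(sm$reports))
      tab <- combine_aligner_tables(tabs)
      tab <- coverage_filter(tab, th$min_depth, th$min_aligners)
      icfg <- integration_config(sm$ncr)
      meth <- integrate_methylation(tab, icfg, context = context)
      calib <- calibrate_fdr(meth$meth_reads, meth$depth, sm$ncr,
                             fdr_target = th$fdr_target, seed = cfg$seed)
      res <- call_methylated(meth, sm$ncr, th$call_threshold)
      emit(sprintf("%s.methylome.tsv.gz", sid),
           function(p) write_methylome(res, p))
      emit(sprintf("%s.calibration.tsv", sid),
           function(p) write_calibration(calib, p))
      res
    })
    methylomes[[sid]] <- called
    calls[[sid]] <- called[called == TRUE & cclass == "CpH"]
  }

  if ("landscape" %in% cfg$stages) {
    stats_rows <- list()
    for (sid in names(methylomes)) {
      stats_rows[[sid]] <- run_stage("landscape", sid, {
        meth <- methylomes[[sid]]
        blocks <- bin_genome(meth, th$block_size)
        emit(sprintf("%s.blocks.tsv.gz", sid),
             function(p) write_tsv_file(blocks, p))
        pcc <- tryCatch(block_correlation(blocks, th$min_cpg, th$min_cph),
                        error = function(e) NA_real_)
        hemi <- tryCatch(hemi_strand_analysis(blocks, th$hemi_diff),
                         error = function(e) list(cis_mean = NA, trans_mean = NA,
                                                  p_value = NA, n_blocks = 0L))
        prob <- distance_probability_profile(meth, calls[[sid]],
                                             th$profile_radius,
                                             th$profile_binwidth)
        emit(sprintf("%s.probability_profile.tsv", sid),
             function(p) write_profile(prob, p))
        lev <- distance_level_profile(meth, "methylated", th$profile_radius)
        emit(sprintf("%s.level_profile.tsv", sid),
             function(p) write_profile(lev, p))
        smoothed <- sliding_window_profile(lev, th$smooth_window)
        emit(sprintf("%s.level_profile_smoothed.tsv", sid),
             function(p) write_profile(smoothed, p))
        per <- tryCatch(periodicity_score(lev, c(5, 15)),
                        error = function(e) list(best_lag = NA, score = NA))
        data.table::data.table(
          sample = sid, block_pcc = pcc, hemi_cis = hemi$cis_mean,
          hemi_trans = hemi$trans_mean, hemi_p = hemi$p_value,
          best_lag = per$best_lag, periodicity_score = per$score)
      })
    }
    emit("landscape_stats.tsv", function(p)
      write_tsv_file(data.table::rbindlist(stats_rows), p))
    if (length(methylomes) >= 2L) {
      run_stage("landscape", "sample clustering", {
        pat <- proximal_pattern_matrix(methylomes, radius = th$proximal_radius)
        emit("sample_pcc.tsv", function(p) {
          dt <- data.table::as.data.table(pat$pcc, keep.rownames = "sample")
          write_tsv_file(dt, p)
        })
        emit("sample_dendrogram.nwk", function(p)
          writeLines(pat$newick, p))
      })
    }
  }

  if ("context" %in% cfg$stages) {
    for (sid in names(methylomes)) {
      run_stage("context", sid, {
        meth <- methylomes[[sid]]
        for (scope in c("genome", "proximal")) {
          cs <- context_mean_levels(meth, scope, th$proximal_anchor_level,
                                    th$proximal_radius)
          emit(sprintf("%s.context_%s.tsv", sid, scope),
               function(p) write_context_summary(cs, p))
        }
        pfm <- tryCatch(
          motif_at_hypermethylated(meth, genome, th$hyper_mcph_level),
          error = function(e) NULL)
        if (!is.null(pfm)) {
          emit(sprintf("%s.motif_pfm.tsv", sid),
               function(p) write_pfm(pfm, p))
        }
      })
    }
  }

  if ("genes" %in% cfg$stages && !is.null(genes)) {
    for (sid in names(methylomes)) {
      run_stage("genes", sid, {
        meth <- methylomes[[sid]]
        summ <- gene_meth_summaries(meth, genes, expr, peaks,
                                    th$min_gene_len)
        emit(sprintf("%s.gene_summaries.tsv", sid),
             function(p) write_tsv_file(summ, p))
        if (!is.null(expr)) {
          rho <- tryCatch(as.numeric(expression_correlation(summ)),
                          error = function(e) NA_real_)
          emit(sprintf("%s.expression_correlation.tsv", sid), function(p)
            write_tsv_file(data.table::data.table(
              sample = sid, spearman_rho = rho), p))
          mg <- metagene_profile(meth, genes, expr,
                                 n_bins = th$metagene_bins,
                                 flank_frac = th$metagene_flank,
                                 smooth_window = th$metagene_smooth,
                                 min_len = th$min_gene_len)
          emit(sprintf("%s.metagene.tsv", sid),
               function(p) write_tsv_file(mg, p))
        }
        if (!is.null(peaks)) {
          scr <- screen_genes(summ, th$mcag_cut, th$overlap_cut,
                              th$min_gene_len)
          emit(sprintf("%s.screened_genes.tsv", sid), function(p)
            write_tsv_file(scr$genes, p))
        }
      })
    }
  }

  input_files <- c(genome_fasta = cfg$genome_fasta,
                   genes = cfg$genes, expression = cfg$expression,
                   peaks = cfg$peaks,
                   unlist(lapply(cfg$samples, `[[`, "reports")))
  manifest <- list(
    package = "mchscape",
    version = as.character(utils::packageVersion("mchscape")),
    seed = cfg$seed,
    stages = cfg$stages,
    config = list(samples = cfg$samples, genome_fasta = cfg$genome_fasta,
                  genes = cfg$genes, expression = cfg$expression,
                  peaks = cfg$peaks, out_dir = cfg$out_dir,
                  thresholds = cfg$thresholds,
                  threshold_defaults = cfg$threshold_defaults),
    inputs = as.list(tools::md5sum(input_files)),
    outputs = as.list(tools::md5sum(file.path(cfg$out_dir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
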