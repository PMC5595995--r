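# Reading and reconciling per-cytosine count tables from multiple
# bisulfite-read aligners, and reading/writing integrated methylomes.

#' Read a per-cytosine count report from one aligner
#'
#' Parses one of three tab-separated cytosine-report dialects into the long
#' multi-aligner count format. Positions are converted from the 1-based file
#' convention to the package's 0-based internal convention.
#'
#' Dialects:
#' \describe{
#'   \item{`generic`}{5 columns, no header: chrom, pos (1-based), strand,
#'     total reads, methylated (unconverted) reads.}
#'   \item{`cx`}{Bismark CX-like, no header: chrom, pos (1-based), strand,
#'     count methylated, count unmethylated, context class (CG/CHG/CHH),
#'     trinucleotide. Total reads = methylated + unmethylated.}
#'   \item{`methratio`}{methratio-like, optional header: chrom, pos
#'     (1-based), strand, context, ratio, eff_CT, C_count, CT_count. Uses
#'     C_count as methylated and CT_count as total.}
#' }
#'
#' Malformed rows (non-numeric counts, negative counts, methylated > total)
#' are dropped; their number is reported via a warning and the
#' `n_malformed` attribute. Rows with zero total reads are retained (they
#' carry coverage information for the aligner-count filter). When a context
#' index is supplied, `cx` trinucleotides are cross-checked against it and
#' mismatches counted in the `n_context_mismatch` attribute.
#'
#' @param path report file (plain or gzip).
#' @param dialect one of `"generic"`, `"cx"`, `"methratio"`.
#' @param aligner_id identifier of the aligner that produced the report.
#' @param context optional context table from [classify_cytosines()] used to
#'   cross-validate `cx` trinucleotide annotations.
#' @return a `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `aligner`, `t` (total reads), `M` (methylated reads), and attributes
#'   `n_malformed`, `n_context_mismatch`.
#' @export
read_cytosine_report <- function(path, dialect = c("generic", "cx", "methratio"),
                                 aligner_id, context = NULL) {
  dialect <- match.arg(dialect)
  raw <- read_tsv_file(path, header = FALSE, colClasses = "character")
  empty <- data.table::data.table(
    chrom = character(), pos = integer(), strand = character(),
    aligner = character(), t = integer(), M = integer())
  data.table::setattr(empty, "n_malformed", 0L)
  data.table::setattr(empty, "n_context_mismatch", 0L)
  if (nrow(raw) == 0L) return(empty)

  # methratio files may carry a header line
  if (dialect == "methratio" && suppressWarnings(is.na(as.integer(raw[[2]][1])))) {
    raw <- raw[-1L]
    if (nrow(raw) == 0L) return(empty)
  }

  need <- switch(dialect, generic = 5L, cx = 7L, methratio = 8L)
  if (ncol(raw) < need) {
    stop(sprintf("dialect '%s' needs %d columns, file has %d",
                 dialect, need, ncol(raw)))
  }

  pos1 <- suppressWarnings(as.integer(raw[[2]]))
  strand <- raw[[3]]
  if (dialect == "generic") {
    t <- suppressWarnings(as.integer(raw[[4]]))
    M <- suppressWarnings(as.integer(raw[[5]]))
  } else if (dialect == "cx") {
    M <- suppressWarnings(as.integer(raw[[4]]))
    un <- suppressWarnings(as.integer(raw[[5]]))
    t <- M + un
  } else {
    M <- suppressWarnings(as.integer(raw[[7]]))
    t <- suppressWarnings(as.integer(raw[[8]]))
  }

  bad <- is.na(pos1) | is.na(t) | is.na(M) | t < 0L | M < 0L | M > t |
    !(strand %in% c("+", "-"))
  n_bad <- sum(bad)
  if (n_bad > 0L) {
    warning(sprintf("%s: %d malformed row(s) rejected", basename(path), n_bad))
  }

  out <- data.table::data.table(
    chrom = raw[[1]][!bad], pos = pos1[!bad] - 1L, strand = strand[!bad],
    aligner = as.character(aligner_id), t = t[!bad], M = M[!bad])

  n_mismatch <- 0L
  if (dialect == "cx" && !is.null(context) && nrow(out) > 0L) {
    tri_file <- raw[[7]][!bad]
    key <- paste(out$chrom, out$pos, out$strand)
    ref <- stats::setNames(context$trinuc,
                           paste(context$chrom, context$pos, context$strand))
    tri_ref <- ref[key]
    n_mismatch <- sum(!is.na(tri_ref) & tri_ref != tri_file)
    if (n_mismatch > 0L) {
      warning(sprintf("%s: %d row(s) disagree with the reference context",
                      basename(path), n_mismatch))
    }
  }
  data.table::setattr(out, "n_malformed", n_bad)
  data.table::setattr(out, "n_context_mismatch", n_mismatch)
  out
}

#' Combine per-aligner reports into one multi-aligner table
#'
#' @param ... count tables from [read_cytosine_report()] (or a single list of
#'   them).
#' @return a long `data.table` with at most one row per (site, aligner).
#' @export
combine_aligner_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !data.table::is.data.table(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  out <- data.table::rbindlist(tabs)
  if (anyDuplicated(out, by = c("chrom", "pos", "strand", "aligner"))) {
    stop("duplicate (site, aligner) entries")
  }
  data.table::setorder(out, chrom, pos, strand, aligner)
  out[]
}

#' Coverage filter over a multi-aligner table
#'
#' Keeps cytosines whose pooled read depth across aligners reaches
#' `min_depth` and which are covered (t > 0) by at least `min_aligners`
#' aligners. The defaults read the covered-by-more-than-5-reads /
#' more-than-two-aligners rule inclusively (>= 5 reads, >= 2 aligners); the
#' strict literal reading is available by raising the parameters.
#'
#' @param table long multi-aligner count table.
#' @param min_depth minimum pooled depth (default 5).
#' @param min_aligners minimum number of covering aligners (default 2).
#' @return the filtered long table.
#' @export
coverage_filter <- function(table, min_depth = 5L, min_aligners = 2L) {
  stopifnot(min_depth >= 1L, min_aligners >= 1L)
  t <- NULL # NSE note
  agg <- table[, .(depth = sum(t), n_alig = sum(t > 0L)),
               by = .(chrom, pos, strand)]
  keep <- agg[depth >= min_depth & n_alig >= min_aligners,
              .(chrom, pos, strand)]
  table[keep, on = c("chrom", "pos", "strand")]
}

#' Write an integrated methylome
#'
#' Tab-separated with header, 1-based positions, levels rounded to 6
#' decimals: chrom, pos, strand, cclass, trinuc, level, depth, meth_reads,
#' n_aligners.
#'
#' @param methylome integrated methylome from [integrate_methylation()]
#'   (annotated with contexts).
#' @param path output path; `.gz` compresses.
#' @return the path, invisibly.
#' @export
write_methylome <- function(methylome, path) {
  cols <- c("chrom", "pos", "strand", "cclass", "trinuc", "level", "depth",
            "meth_reads", "n_aligners")
  miss <- setdiff(cols, names(methylome))
  if (length(miss)) stop("methylome lacks columns: ", paste(miss, collapse = ", "))
  out <- methylome[, cols, with = FALSE]
  out <- data.table::copy(out)
  out[, `:=`(pos = pos + 1L, level = round(level, 6))]
  write_tsv_file(out, path)
}

#' Read an integrated methylome written by [write_methylome()]
#'
#' @param path methylome table (plain or gzip).
#' @return a `data.table` in the internal 0-based convention with the
#'   symmetry class recomputed from the trinucleotide.
#' @export
read_methylome <- function(path) {
  dt <- read_tsv_file(path, header = TRUE)
  dt[, pos := as.integer(pos) - 1L]
  third <- substr(dt$trinuc, 3L, 3L)
  dt[, symclass := ifelse(cclass == "CpG", "CpG",
                          ifelse(third == "G", "CpHpG", "CpHpH"))]
  data.table::setorder(dt, chrom, pos, strand)
  dt[]
}
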