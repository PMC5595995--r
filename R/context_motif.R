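# Trinucleotide-context and symmetry-class methylation summaries, and
# consensus motif extraction at hyper-methylated CpH sites.

#' Context-resolved mean methylation levels
#'
#' Unweighted mean CpH methylation level per trinucleotide context (CAC,
#' CAT, CAA, CAG and pooled other CpH) and per symmetry class (CpHpG,
#' CpHpH), genome-wide or restricted to the mCpG-proximal scope (CpH sites
#' within +/-`window` bp of a CpG with level above `anchor_level`, either
#' strand).
#'
#' @param methylome integrated, context-annotated methylome.
#' @param scope `"genome"` or `"proximal"`.
#' @param anchor_level CpG level defining a proximal anchor (strict >,
#'   default 0.5).
#' @param window proximal window half-width in bp (default 100).
#' @return list of class `context_summary` with `scope`, `contexts` (a
#'   `data.table` context/mean_level/n_sites) and `symclass` (likewise);
#'   contexts with zero sites are absent.
#' @export
context_mean_levels <- function(methylome, scope = c("genome", "proximal"),
                                anchor_level = 0.5, window = 100L) {
  scope <- match.arg(scope)
  cph <- methylome[cclass == "CpH"]
  if (scope == "proximal") {
    anchors <- methylome[cclass == "CpG" & level > anchor_level]
    if (nrow(anchors) == 0L) stop("no proximal anchors above level ",
                                  anchor_level)
    keep <- logical(nrow(cph))
    for (ch in unique(cph$chrom)) {
      si <- which(cph$chrom == ch)
      ap <- sort(anchors$pos[anchors$chrom == ch])
      if (length(ap) == 0L) next
      iv <- findInterval(cph$pos[si], ap)
      d_left <- cph$pos[si] - ap[pmax(iv, 1L)]
      d_left[iv == 0L] <- Inf
      d_right <- ap[pmin(iv + 1L, length(ap))] - cph$pos[si]
      d_right[iv >= length(ap)] <- Inf
      keep[si] <- pmin(abs(d_left), d_right) <= window
    }
    cph <- cph[keep]
  }
  grp <- ifelse(cph$trinuc %in% c("CAC", "CAT", "CAA", "CAG"), cph$trinuc,
                "other")
  ctx <- cph[, .(mean_level = mean(level), n_sites = .N),
             by = .(context = grp)]
  ord <- c("CAC", "CAT", "CAA", "CAG", "other")
  ctx <- ctx[order(match(context, ord))]
  sym <- cph[, .(mean_level = mean(level), n_sites = .N),
             by = .(symclass = symclass)]
  data.table::setorder(sym, symclass)
  structure(list(scope = scope, contexts = ctx, symclass = sym),
            class = "context_summary")
}

#' @export
print.context_summary <- function(x, ...) {
  cat("Context summary (", x$scope, " scope)\n", sep = "")
  print(x$contexts)
  print(x$symclass)
  invisible(x)
}

#' Position frequency matrix at hyper-methylated CpHs
#'
#' Collects, for every CpH whose level exceeds `level_cut`, the sequence
#' window from 1 bp upstream to 4 bp downstream of the cytosine, read
#' 5'->3' on the site's strand, and tallies base counts per position.
#' Windows leaving the chromosome or containing N are dropped. The
#' consensus is the per-column argmax, ties broken in base order
#' A < C < G < T and flagged.
#'
#' @param methylome integrated, context-annotated methylome.
#' @param genome the reference genome (named character vector or
#'   `DNAStringSet`).
#' @param level_cut hyper-methylation level cutoff (strict >, default 0.5).
#' @param upstream,downstream window extent around the cytosine (defaults 1
#'   and 4, i.e. positions -1..+4).
#' @return list of class `pfm` with `counts` (4 x window matrix),
#'   `consensus` (string), `n_sites`, and `ties` (per-column logical).
#' @export
motif_at_hypermethylated <- function(methylome, genome, level_cut = 0.5,
                                     upstream = 1L, downstream = 4L) {
  seqs <- as_genome(genome)
  sites <- methylome[cclass == "CpH" & level > level_cut]
  if (nrow(sites) == 0L) stop("no CpH sites above level ", level_cut)
  wlen <- upstream + downstream + 1L
  wins <- character(0)
  for (ch in unique(sites$chrom)) {
    s <- sites[chrom == ch]
    sq <- seqs[[ch]]
    L <- nchar(sq)
    fwd <- s[strand == "+"]
    if (nrow(fwd) > 0L) {
      ok <- fwd$pos - upstream >= 0L & fwd$pos + downstream <= L - 1L
      if (any(ok)) {
        wins <- c(wins, substring(sq, fwd$pos[ok] - upstream + 1L,
                                  fwd$pos[ok] + downstream + 1L))
      }
    }
    rev <- s[strand == "-"]
    if (nrow(rev) > 0L) {
      ok <- rev$pos - downstream >= 0L & rev$pos + upstream <= L - 1L
      if (any(ok)) {
        wins <- c(wins, revcomp(substring(sq, rev$pos[ok] - downstream + 1L,
                                          rev$pos[ok] + upstream + 1L)))
      }
    }
  }
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  if (length(wins) == 0L) stop("no complete sequence windows")
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(wlen), function(i) {
    tab <- table(factor(substring(wins, i, i), levels = bases))
    as.integer(tab)
  }, integer(4))
  rownames(counts) <- bases
  colnames(counts) <- as.character(seq(-upstream, downstream))
  consensus <- paste(bases[apply(counts, 2, which.max)], collapse = "")
  ties <- apply(counts, 2, function(col) sum(col == max(col)) > 1L)
  structure(list(counts = counts, consensus = consensus,
                 n_sites = length(wins), ties = ties),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix over", x$n_sites, "hyper-methylated CpHs\n")
  print(x$counts)
  cat("consensus:", x$consensus,
      if (any(x$ties)) "(ties present)" else "", "\n")
  invisible(x)
}

#' Write a position frequency matrix as TSV
#'
#' 4 x window count matrix plus a trailing consensus line.
#'
#' @param pfm a `pfm` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("base", colnames(pfm$counts)), collapse = "\t"), con)
  for (b in rownames(pfm$counts)) {
    writeLines(paste(c(b, pfm$counts[b, ]), collapse = "\t"), con)
  }
  writeLines(paste0("consensus\t", pfm$consensus), con)
  invisible(path)
}

#' Write a context summary as TSV
#'
#' @param summary a `context_summary`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_context_summary <- function(summary, path) {
  ctx <- data.table::copy(summary$contexts)
  data.table::setnames(ctx, "context", "group")
  sym <- data.table::copy(summary$symclass)
  data.table::setnames(sym, "symclass", "group")
  out <- data.table::rbindlist(list(
    cbind(kind = "trinucleotide", ctx), cbind(kind = "symmetry", sym)))
  write_tsv_file(out, path)
}
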