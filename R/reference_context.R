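# Reference genome cytosine classification: CpG/CpH class, trinucleotide
# context and symmetry class for every cytosine on both strands.

#' Classify every cytosine of a genome by context
#'
#' Scans both strands of a reference genome and emits one record per cytosine:
#' its trinucleotide context read 5'->3' on the cytosine's own strand
#' (starting at the cytosine), its dinucleotide class (`CpG` when the next
#' base is G, otherwise `CpH`), and its symmetry class (`CpHpG` when a CpH is
#' followed by G, `CpHpH` when followed by A, C or T). Reverse-strand
#' cytosines appear as G on the forward strand and are anchored at the
#' forward-strand coordinate of that G. Cytosines whose trinucleotide window
#' runs off the chromosome end or contains an N are dropped, since their
#' context is undefined.
#'
#' @param genome a `Biostrings::DNAStringSet` or a named character vector of
#'   chromosome sequences over the alphabet A, C, G, T, N.
#' @return a `data.table` with columns `chrom`, `pos` (0-based forward-strand
#'   coordinate of the cytosine base), `strand` (`+`/`-`), `cclass`
#'   (`CpG`/`CpH`), `trinuc`, `symclass` (`CpG`/`CpHpG`/`CpHpH`), sorted by
#'   chromosome, position and strand.
#' @examples
#' classify_cytosines(c(chr1 = "TCAGT"))
#' @export
classify_cytosines <- function(genome) {
  seqs <- as_genome(genome)
  out <- vector("list", length(seqs))
  for (ci in seq_along(seqs)) {
    chrom <- names(seqs)[ci]
    b <- strsplit(seqs[[ci]], "", fixed = TRUE)[[1]]
    L <- length(b)
    if (L == 0L) next
    pieces <- list()

    # forward strand: C at i, context b[i..i+2]
    i <- which(b == "C")
    i <- i[i + 2L <= L]
    if (length(i)) {
      tri <- paste0(b[i], b[i + 1L], b[i + 2L])
      keep <- !grepl("N", tri, fixed = TRUE)
      if (any(keep)) {
        pieces$fwd <- data.table::data.table(
          chrom = chrom, pos = i[keep] - 1L, strand = "+", trinuc = tri[keep])
      }
    }

    # reverse strand: C is a G on the forward strand at j; the trinucleotide
    # on the reverse strand is the complement of b[j], b[j-1], b[j-2].
    j <- which(b == "G")
    j <- j[j - 2L >= 1L]
    if (length(j)) {
      tri <- paste0(.BASE_COMP[b[j]], .BASE_COMP[b[j - 1L]],
                    .BASE_COMP[b[j - 2L]])
      keep <- !is.na(tri) & !grepl("N", tri, fixed = TRUE)
      if (any(keep)) {
        pieces$rev <- data.table::data.table(
          chrom = chrom, pos = j[keep] - 1L, strand = "-", trinuc = tri[keep])
      }
    }
    if (length(pieces)) out[[ci]] <- data.table::rbindlist(pieces)
  }
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(
      chrom = character(), pos = integer(), strand = character(),
      cclass = character(), trinuc = character(), symclass = character())
    return(out)
  }
  second <- substr(out$trinuc, 2L, 2L)
  third <- substr(out$trinuc, 3L, 3L)
  out[, `:=`(
    cclass = ifelse(second == "G", "CpG", "CpH"),
    symclass = ifelse(second == "G", "CpG",
                      ifelse(third == "G", "CpHpG", "CpHpH")))]
  data.table::setcolorder(out, c("chrom", "pos", "strand", "cclass",
                                 "trinuc", "symclass"))
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Isolated CpG sites
#'
#' Returns CpG sites whose CpG dyad has no other CpG dyad within a given
#' radius, on either strand. Isolation is judged between dyads (CG
#' dinucleotide start coordinates): the opposite-strand partner of the same
#' dyad sits 1 bp away by construction and does not break isolation.
#'
#' @param sites context table from [classify_cytosines()].
#' @param radius isolation radius in bp (default 500); a neighbouring dyad
#'   at distance greater than `radius` does not break isolation.
#' @return the subset of CpG rows of `sites` that are isolated.
#' @export
isolated_cpg_subset <- function(sites, radius = 500) {
  stopifnot(radius > 0)
  cpg <- sites[sites$cclass == "CpG"]
  if (nrow(cpg) == 0L) return(cpg)
  cpg <- data.table::copy(cpg)
  # dyad anchor: forward coordinate of the C of the CG dinucleotide
  cpg[, dyad := ifelse(strand == "+", pos, pos - 1L)]
  dy <- unique(cpg[, .(chrom, dyad)])
  data.table::setorder(dy, chrom, dyad)
  gap_prev <- dy[, dyad - data.table::shift(dyad), by = chrom]$V1
  gap_next <- dy[, data.table::shift(dyad, type = "lead") - dyad, by = chrom]$V1
  gap_prev[is.na(gap_prev)] <- Inf
  gap_next[is.na(gap_next)] <- Inf
  iso <- dy[pmin(gap_prev, gap_next) > radius]
  res <- cpg[iso, on = c("chrom", "dyad"), nomatch = NULL]
  res[, dyad := NULL]
  data.table::setorder(res, chrom, pos, strand)
  res[]
}

#' Read a reference genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the named
#' uppercase character representation used throughout the package.
#'
#' @param path FASTA file (plain or gzip).
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_genome(seqs)
}

#' Write a context index as a tab-separated table
#'
#' Emits the cytosine-report convention: 1-based positions, one row per
#' (position, strand).
#'
#' @param sites context table from [classify_cytosines()].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return the path, invisibly.
#' @export
write_context_index <- function(sites, path) {
  out <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos + 1L, strand = sites$strand,
    cclass = sites$cclass, trinuc = sites$trinuc, symclass = sites$symclass)
  write_tsv_file(out, path)
}
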