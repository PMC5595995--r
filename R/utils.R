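# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation helpers do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centered moving average with truncated windows at the edges.
# Even window sizes are widened by one so the window is symmetric.
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  if (window > n) stop("window larger than profile")
  half <- (window - 1L) %/% 2L
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Complement lookup for single uppercase bases.
.BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Reverse complement of a vector of sequences (plain character).
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(.BASE_COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Ranks rescaled to (0, 1), average ties.
rank01 <- function(x) {
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

# Coerce a genome given as DNAStringSet or named character vector to a named
# uppercase character vector; validates names and alphabet coarsely.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) stop("empty reference")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("genome sequences must be named by chromosome")
  }
  seqs
}

# TSV reading that tolerates .gz without requiring R.utils.
read_tsv_file <- function(path, header = FALSE, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    txt <- readLines(con)
    if (length(txt) == 0L) return(data.table::data.table())
    data.table::fread(text = txt, sep = "\t", header = header, ...)
  } else {
    if (file.size(path) == 0L) return(data.table::data.table())
    data.table::fread(file = path, sep = "\t", header = header, ...)
  }
}

write_tsv_file <- function(dt, path, header = TRUE) {
  compress <- if (grepl("\\.gz$", path)) "gzip" else "none"
  data.table::fwrite(dt, path, sep = "\t", col.names = header,
                     compress = compress)
  invisible(path)
}
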