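Package: mchscape
Title: Non-CpG Methylation Landscapes from Whole-Genome Bisulfite
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising non-CpG (CpH) methylation around
    methylated CpGs from whole-genome bisulfite sequencing data.
    Reconciles per-cytosine count tables from multiple bisulfite-read
    aligners into depth-weighted methylation levels, calls methylated
    cytosines with a binomial test calibrated against a simulated null
    methylome to a target false discovery rate, computes distance-resolved
    and trinucleotide-context methylation profiles with periodicity
    detection, extracts consensus motifs at hyper-methylated CpH sites,
    and summarises gene-body methylation against expression and
    histone-peak overlap. A fully seeded synthetic-data generator
    reproduces the statistical structure these analyses assume, so the
    whole pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    data.table,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
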