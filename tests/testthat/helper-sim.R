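# Shared simulated datasets, built once per test run and reused across
# files. Each entry holds the config, the raw dataset and the integrated,
# context-annotated methylome.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (is.null(.sim_cache[[key]])) {
    ds <- simulate_dataset(cfg)
    meth <- integrate_methylation(coverage_filter(ds$counts),
                                  integration_config(cfg$ncr),
                                  context = ds$context)
    .sim_cache[[key]] <- list(cfg = cfg, ds = ds, meth = meth)
  }
  .sim_cache[[key]]
}

esc_sim <- function() {
  cached_sim("esc", simulation_config(
    "esc", seed = 101, genome_length = 400000L, n_genes = 40L,
    gene_length_range = c(1000, 6000)))
}

neuron_sim <- function() {
  cached_sim("neuron", simulation_config(
    "neuron", seed = 102, genome_length = 400000L, n_genes = 40L,
    gene_length_range = c(1000, 6000)))
}

d1ko_sim <- function() {
  cached_sim("d1ko", simulation_config(
    "d1ko", seed = 103, genome_length = 600000L, n_genes = 40L,
    gene_length_range = c(1000, 6000)))
}

# Large gene sets for correlation work: short genes keep the genome small.
d3bko_gene_sim <- function() {
  cached_sim("d3bko_genes", simulation_config(
    "d3bko", seed = 104, genome_length = 6500000L, n_genes = 2000L,
    gene_length_range = c(1500, 2500)))
}

esc_gene_sim <- function() {
  cached_sim("esc_genes", simulation_config(
    "esc", seed = 105, genome_length = 13000000L, n_genes = 2000L,
    gene_length_range = c(3000, 6000)))
}

# Four replicate samples (2 ESC-mode, 2 neuron-mode) for clustering.
replicate_methylomes <- function() {
  if (is.null(.sim_cache[["replicates"]])) {
    mk <- function(mode, s) {
      cfg <- simulation_config(mode, seed = s, genome_length = 150000L,
                               n_genes = 10L)
      ds <- simulate_dataset(cfg)
      integrate_methylation(coverage_filter(ds$counts),
                            integration_config(cfg$ncr),
                            context = ds$context)
    }
    .sim_cache[["replicates"]] <- list(
      esc_r1 = mk("esc", 111), esc_r2 = mk("esc", 112),
      neuron_r1 = mk("neuron", 113), neuron_r2 = mk("neuron", 114))
  }
  .sim_cache[["replicates"]]
}

# On-disk pipeline fixture: a small simulated dataset written as files,
# plus a run_config pointing at it.
pipeline_fixture <- function() {
  if (is.null(.sim_cache[["pipeline_fix"]])) {
    cfg <- simulation_config("esc", seed = 71, genome_length = 120000L,
                             n_genes = 12L, gene_length_range = c(1000, 5000))
    dir <- file.path(tempdir(), "mchscape-pipeline-fixture")
    ds <- simulate_dataset(cfg, dir)
    .sim_cache[["pipeline_fix"]] <- list(cfg = cfg, dir = dir, ds = ds)
  }
  .sim_cache[["pipeline_fix"]]
}

fixture_config <- function(out_dir, ...) {
  fx <- pipeline_fixture()
  run_config(
    samples = list(S1 = list(
      reports = file.path(fx$dir, paste0("aligner", 1:3, ".tsv.gz")),
      dialects = rep("generic", 3), ncr = fx$cfg$ncr)),
    genome_fasta = file.path(fx$dir, "genome.fa"),
    out_dir = out_dir,
    genes = file.path(fx$dir, "genes.tsv"),
    expression = file.path(fx$dir, "expression.tsv"),
    peaks = file.path(fx$dir, "peaks.bed"),
    seed = 5L, ...)
}

# Small hand-rolled methylome table for oracle comparisons: random sites on
# one chromosome with random levels, no generator involvement.
random_methylome <- function(n = 600L, chrom_len = 20000L, seed = 1L) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n)) - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cclass <- sample(c("CpG", "CpH"), n, replace = TRUE, prob = c(0.3, 0.7))
  trinuc <- ifelse(cclass == "CpG", "CGA",
                   sample(c("CAC", "CAT", "CAA", "CAG", "CCT", "CTG"),
                          n, replace = TRUE))
  data.table::data.table(
    chrom = "chr1", pos = pos, strand = strand, cclass = cclass,
    trinuc = trinuc,
    symclass = ifelse(cclass == "CpG", "CpG",
                      ifelse(substr(trinuc, 3, 3) == "G", "CpHpG", "CpHpH")),
    level = round(stats::runif(n), 3),
    depth = sample(5:30, n, replace = TRUE))
}
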