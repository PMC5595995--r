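---
title: "Methods: calling and profiling non-CpG methylation with mchscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and profiling non-CpG methylation with mchscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, conventions and
design choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates, strands and contexts

All genomic positions are 0-based internally; file readers and writers use
the 1-based cytosine-report convention. A reverse-strand cytosine appears
as a G on the forward strand and is anchored at the forward coordinate of
that G, so each (position, strand) pair is one row — the convention of
Bismark-style cytosine reports. Trinucleotide contexts are read 5'→3' on
the cytosine's own strand starting at the cytosine; a site whose 3-mer
window leaves the chromosome or contains an N is dropped rather than
imputed, because its context is undefined. CpG palindromes yield two
distinct sites, one per strand — the hemi-methylation analysis requires
per-strand CpG levels, so they are never merged.

Isolated-CpG selection (`isolated_cpg_subset()`) is evaluated between CpG
*dyads* (CG dinucleotide start coordinates), counting dyads on either
strand as neighbours. A site-level reading would be vacuous: the
opposite-strand partner of every complete dyad lies 1 bp away. The
isolation radius (default 500 bp) is strict — a neighbour exactly at the
radius does not break isolation, one inside it does.

## Multi-aligner integration and the coverage filter

Counts from up to three aligners are pooled per site; the integrated level
is the read-depth weighted average minus the bisulfite non-conversion
rate, clamped at zero. Clamping introduces a small positive bias at truly
unmethylated sites; it is retained because a methylation level is a
proportion and downstream cutoffs assume `[0, 1]`.

The coverage rule — "more than 5 reads, more than two aligners" — is
ambiguous between inclusive and strict readings. The defaults are
inclusive (pooled depth ≥ 5 and ≥ 2 covering aligners), which keeps the
filter meaningful when only two aligner reports are available; both
parameters are exposed, so the strict reading (≥ 6, all three) is one
argument away. Depth is pooled across aligners because the integration
formula pools reads; an aligner absent at a site simply contributes zero.

The non-conversion rate is a required per-sample input. When a
fully-unmethylated control contig (for example spiked lambda DNA) is
present, `estimate_non_conversion()` returns its pooled methylated-read
fraction as a convenience estimator. Rates above 0.05 trigger a warning;
rates at or above 0.1 are rejected as evidence of a failed conversion.

## Calling and FDR calibration

The caller tests each site's pooled counts `(k, n)` against
`X ~ Binomial(n, p)` with `p` the non-conversion rate and reports the
upper tail `Pr(X ≥ k)`. The procedure's written form is a point
probability `Pr(X = k)`, but a point probability cannot be thresholded
meaningfully across depths; the inclusive upper tail is the standard
conservative reading of "probability that k methylated reads occur", and
is what the test suite's brute-force summation oracle checks. "p-value
under the threshold" is implemented as a strict inequality.

The threshold is calibrated against an artificial methylome: per-site
depths are kept and methylated counts are redrawn as pure non-conversion
noise. The empirical FDR at threshold `t` is (artificial calls at `t`) /
(real calls at `t`) — the only ratio of the two call counts that behaves
like an FDR — reported as `NaN` when there are no real calls. One
artificial replicate per seed is the default; `n_reps` averages several.
The calibration is bit-reproducible given its seed.

Downstream status cutoffs live in `meth_cutoffs`: methylated CpG at level
≥ 0.8, unmethylated CpG below 0.2, hyper-methylated CpH above 0.5. The
distance-*probability* profile counts CpH sites by their binomial call;
the hyper-methylation *motif* uses the 0.5 level cutoff. These two
definitions are deliberately different — the former needs depth-aware
confidence at low levels, the latter selects the strongly methylated tail.

## Distance profiles and periodicity

Profile offsets are strand-oriented: negative offsets are 5' of the
anchor cytosine on the anchor's strand. A strand-agnostic convention
would average the ESC-mode −4 bp peak with its mirror image and cancel
it. The level profile pairs anchors with CpHs on the anchor's strand by
default (both-strand mode available); the probability profile defaults to
both strands, since "a bin contains a methylated CpH" is a statement
about the locus, not a strand. "Blocks containing more than one mCpH"
is implemented as ≥ 1 occupied (the natural "contains" reading); the
literal > 1 is available through `min_mcph`.

Sliding-window smoothing uses a centered moving average; even window
sizes are widened by one unit to stay symmetric and edge windows are
truncated rather than dropped. The published window sizes (10 for
anchor profiles, 30 for metagene profiles) are interpreted in profile
units (bins), because the metagene axis has no fixed bp scale after
normalisation; both are parameters.

Periodicity is the argmax of the mean-detrended autocorrelation over a
lag range (5–15 bp for helical-pitch scale, 100–300 bp for nucleosome
scale), with missing offsets handled by pairwise-complete correlation. An
optional circular-shift permutation null (the 95th percentile of the
maxima of shifted profiles) guards against reading structure into noise.

## Block statistics and hemi-methylation

1-kb blocks carry unweighted means of site levels by class and strand;
the block correlation uses blocks with strictly more than 10 CpGs and 10
CpHs and at least 3 qualifying blocks. Blocks whose between-strand CpG
difference exceeds 0.5 enter the hemi-methylation contrast; the strand
with the higher CpG level is "cis", and the paired cis/trans CpH means
are tested with a Wilcoxon signed-rank test (paired by block, as the
block is the sampling unit). Genic stratification assigns a block to
promoter (TSS ± 5000 bp) or intragenic (TSS..TTS) when more than 500 bp
of the block is covered, promoter taking precedence.

Sample clustering uses Pearson correlation of mCpG-proximal (±100 bp)
per-offset mean CpH levels (or per-block means), distance 1 − PCC and
average linkage. The linkage is a documented default — the source
procedure does not name one — and is configurable.

## Metagene mapping

Each gene body plus 20%-of-length flanks maps onto 1000 bins by
`bin = floor(u · 1000)` (clamped into 1..1000) where `u` is the position's
fraction of the extended axis in strand orientation. The body boundaries
then land on bins 142 and 857 for *every* gene length: `floor(0.2/1.4 ·
1000) = 142` and `floor(1.2/1.4 · 1000) = 857` exactly. Minus-strand
bases enter through their 5'-facing edge (`pos + 1`) so the mapping is
the exact mirror of the plus strand; mapping minus-strand bases by their
own coordinate would shift short genes' boundaries by one bin. Expression
groups are FPKM quantiles with inclusive boundaries (top 20%: `fpkm ≥`
the 0.8 quantile), ties kept.

## The gene screen

`screen_genes()` keeps genes with mean gene-body CAG level strictly above
0.05, histone overlap rate strictly above 0.5, length strictly above
1000 bp, and identifiers not starting with `LOC` or `Rik`. "mCAG level"
is the mean integrated level over CAG-context sites in the body — not a
called-site fraction — consistent with how per-context means are defined
elsewhere in the package. Whether the 0.05 cutoff corresponds to a "top
3%" tail depends on the methylome; the screen therefore reports the
cutoff's empirical quantile instead of imposing a second cutoff.
Enrichment analysis of the resulting list is out of scope; the output is
a ranked table suitable for external tools.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions of the analyses.

* **Genome**: i.i.d. bases at GC 0.42, then CpG depletion (the G of 90%
  of CG dinucleotides mutated to A/T), giving the sparse CpG dyads of a
  mammalian genome — without depletion, anchors would tile the genome and
  distance structure would be invisible. Genes are non-overlapping,
  log-uniform in length (1–20 kb by default), on random strands.
* **CpG dyads** are bimodal: 75% draw both strand levels from a high Beta
  mode (mean ≈ 0.9), the rest from a low mode (mean ≈ 0.05); 5% of 1-kb
  segments are hemi-methylated, all their dyads high on one randomly
  chosen strand. Hemi-methylation is planted regionally because the
  block-level contrast requires whole blocks, not scattered dyads, to be
  strand-asymmetric.
* **CpH deposition**: each CpH's firing propensity is
  `background + amplitude · K(d) · w(context) · body_mult`, with `d` the
  signed distance to the nearest methylated CpG on the same strand and
  `K` a squared-exponential kernel with half-maximum at `kernel_width`
  (100 bp). Mode-specific factors multiply `K`: a Gaussian boost at
  −4 bp (σ = 0.8 bp, ESC modes — the emulated feature is a sharp
  single-offset peak, so the boost is confined to its offset), a 9-bp
  cosine (neuron), a 180-bp cosine (DNMT1-knockout). Context weights
  favour CAG ≫ CAA > CAC (ESC-like) or CAC ≫ CAT (neuron-like);
  the DNMT3b-knockout mode suppresses CAG/CAA. Sites fire as Bernoulli
  draws and firing sites get a Beta(2.2, 1.8) level: the mixture creates
  the hyper-methylated minority of sites that motif extraction needs,
  emulating cell-population bimodality.
* **Expression coupling**: a per-gene normal latent sets log-normal FPKM;
  a second latent, Gaussian-copula-correlated so that the planted
  Spearman ρ equals `expression_coupling` (+0.4 ESC, −0.3 neuron, 0 for
  the knockout modes), drives histone-peak coverage through a logistic
  link, and gene-body deposition is modulated by that coverage
  (`0.1 + 2.2 · overlap`), not by expression directly. Methylation is
  therefore more tightly rank-correlated with the overlap rate than with
  FPKM, by construction. Because gene-level deposition is sampled
  (Bernoulli firing plus kernel averaging), the measured gene-body ρ is
  attenuated by roughly 15% relative to the planted latent value; the
  recovery experiments use 2000 genes so this attenuation, not sampling
  error, dominates.
* **Reads**: per-site depth is Poisson (mean 15), methylated reads are
  Binomial at `m + (1 − m) · ncr` with ncr = 0.005 — non-conversion acts
  on every unmethylated molecule regardless of context, keeping the
  caller's null exact. Totals are split across three aligners by
  sequential binomial draws with 15% per-aligner dropout, and methylated
  reads are partitioned hypergeometrically so the split is consistent;
  aligner labels are exchangeable, which is what makes the integration's
  splitting invariance testable.

What the generator does *not* emulate: alignment and mapping error,
sequence-dependent coverage bias, overdispersed (beta-binomial) counts,
chromosome-scale heterogeneity (compartments, CpG islands), and any
read-level structure. Passing tests therefore demonstrate that the
analysis chain recovers planted structure under its own statistical
assumptions — not that those assumptions hold in any particular real
dataset.

## Estimating the coupling-kernel width

The per-offset Pearson correlation between anchor CpG level and CpH level
(`distance_correlation_profile()`) shows the locality of the coupling,
but its amplitude divides by the CpH level's standard deviation, which
itself grows near anchors (variance of a rare Bernoulli-Beta mixture
scales with its propensity). Reading the kernel's half-max off that curve
therefore overestimates the width by roughly √2. `coupling_width()`
instead contrasts the mean CpH level at each absolute distance between
methylated and unmethylated anchors — a quantity linear in the kernel —
smooths it over 3 bins and interpolates the half-maximum crossing
linearly. The width-recovery experiments run it on the periodic
(neuron-like) mode, whose kernel has no localized boost; a boost inflates
the near-anchor maximum and drags the apparent half-max inward.

## Problem sizes and numerical conventions

The test suite and acceptance script use 150–600 kb genomes for the mode
contrasts, a 2 Mb genome for width recovery, 6.5–13 Mb genomes with 2000
genes for the correlation work, and one million sites for the FDR
experiment; these sizes put each planted feature several standard errors
above its sampling noise while keeping a full run in minutes on one CPU.
Other conventions: PFM consensus ties break in fixed base order
A < C < G < T and are flagged; means over empty site classes are `NA`,
never 0; correlations of constant vectors warn and return `NaN`;
`calibrate_fdr` leaves the chosen threshold absent when no grid point
meets the target; every stochastic step takes an explicit seed and the
pipeline manifest records the effective configuration, so reruns are
byte-identical.

## Known limitations

No beta-binomial overdispersion in calling; no per-strand merging of CpG
calls; no CpG-island or repeat annotation; no read-level (FASTQ/BAM)
processing — the package starts from per-cytosine count tables; the
permutation null for periodicity is a guard, not a calibrated test; and
the generator's independence assumptions (sites, reads, aligner splits)
are idealisations chosen to make every analysis property testable.
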