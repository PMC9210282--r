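---
title: "Gene-anchored haplotype graph imputation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-anchored haplotype graph imputation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplographr)
library(dplyr)
```

## The problem

Large-genome crops such as allohexaploid bread wheat make dense genotyping
expensive: the genome is huge, mostly repetitive, and most informative
variation sits in and around genes. A practical haplotype graph addresses
this by storing the haplotypes of a founder panel per *reference range* — a
gene-anchored genomic interval — and imputing a new sample's genotypes from
very low-coverage reads by decoding the most probable path of known
haplotypes through those ranges. `haplographr` implements that framework at
package scale: graph construction from gVCF-style calls, k-mer read
mapping, hidden-Markov-model path decoding, the matching accuracy protocol,
panel diversity summaries, and a seeded synthetic-data generator that
supplies every input the pipeline needs.

## Graph construction

**Reference ranges.** Gene models are extended by `flank_bp` (default
500 bp) on each side, clamped to the chromosome, and merged when extended
intervals overlap or sit within `merge_gap_bp` (default 500 bp). The result
is a sorted, disjoint set of *informative* ranges; intergenic sequence is
deliberately not stored, because in a repeat-rich genome reads from it
cannot be placed reliably. Reads landing outside informative ranges are
ignored downstream. Coordinates are 0-based half-open internally; VCF I/O
is 1-based; BED is 0-based.

**Raw haplotypes.** Each panel taxon contributes one raw haplotype per
range, read from its gVCF-style records: the called allele where a variant
record covers a site, the reference allele inside a reference block
(`END`-tagged), missing elsewhere. Heterozygous source calls are stored as
missing — the intended panels are inbred lines, where residual
heterozygous calls are more likely artifacts than genuine heterozygosity.

**Consensus collapsing.** Within a range, pairwise divergence is the count
of sites where two haplotypes are both genotyped and differ, divided by the
*full range length* in bp. The full-length denominator (rather than the
genotyped-site count) matches the interpretation of the divergence
threshold as "fewer than 1 variant per 10,000 bp": `mxdiv = 1e-4` over a
10 kb range admits exactly the pairs with zero differences. Average-linkage
agglomerative clustering merges the closest cluster pair while their mean
divergence is strictly below `mxdiv`; identical haplotypes (divergence 0)
always merge, so `mxdiv = 0` collapses exact duplicates only. The linkage
rule itself is a design choice of this package — the upstream framework
leaves it to the implementation — and it is fixed as unweighted pair-average
over the original pairwise matrix, verified in the tests against a
from-scratch re-computation. Consensus alleles are per-site majorities over
non-missing members with ties resolved to the reference allele; haplotype
ids are dense integers ordered by descending member count, then
lexicographic member names, which makes every downstream tie-break
deterministic. `min_taxa = 1` (the default) retains singleton haplotypes,
keeping rare haplotypes — including wild-relative introgressions —
imputable.

## Read mapping

The original pipeline aligns reads to the consensus sequences with an
external aligner. Here a self-contained k-mer pseudo-mapper plays that
role: consensus sequences (the reference edited with each haplotype's
alleles) are indexed by canonical k-mers (k = 21, strand-collapsed; k-mers
are compared through an exact base-4 numeric encoding equivalent to
lexicographic order). Per read, k-mer hits are collected; a read touching
more than one range is discarded as non-unique, mirroring a
uniquely-mapped-reads policy; otherwise it is assigned to its range, and
the haplotypes achieving the maximal hit count form its *consistent set*
(ties keep all tied haplotypes, mirroring multi-mapping semantics). Paired
mates are processed as two reads; if both map they must agree on the range
or the pair is discarded, and a mate without hits is discarded
individually. This contract is a stated substitute for full alignment, not
a reconstruction of it: it uses no base qualities and no gapped alignment,
which is adequate at the simulated error rates but would understate mapping
noise on real data (see Limitations).

## The imputation HMM

States at range $r$ are the consensus haplotypes of $r$; the decoded path
picks one per range. The model pieces are deliberately simple and exposed
as `hmm_params()`:

* **Emission.** With $n$ reads assigned to a range and $c_h$ of them
  consistent with haplotype $h$,
  $\log P = c_h \log(1-\varepsilon) + (n - c_h) \log \varepsilon$ with
  read-mismatch probability $\varepsilon$ (default 0.01). A range with
  fewer than `min_reads` reads (default 0 — i.e. any range without reads)
  emits 0 for every state, so it is still traversed and every catalogued
  site is imputed regardless of coverage.
* **Transition.** Successors sharing at least one member taxon get weight
  $1-s$; disjoint successors share $s$ uniformly (`switch_p`, default
  0.001); each row is renormalized. Taxon continuity is what lets sparse
  evidence propagate across empty ranges.
* **Decoding.** Uniform initial distribution, per-chromosome independence,
  log-domain Viterbi with ties broken toward the lowest haplotype id; a
  forward pass provides the total likelihood as a diagnostic. Both are
  verified against exhaustive path enumeration on random toy graphs.

The upstream framework's exact emission and transition formulas are not
published; these contracts are this package's own, with the parameters
surfaced rather than hard-coded. Paths are single (inbred assumption) and
emitted genotypes homozygous; a missing consensus allele yields a missing
genotype call.

## Evaluation protocol

Concordance joins imputed and truth calls on (chromosome, position, ref,
alt) — allele identity, not just position, to avoid ref/alt swap artifacts
— drops sites missing on either side, and reports matches over overlap.
Stratified accuracy re-scores within minor-allele-frequency bins (0–0.1
through 0.4–0.5 plus the pooled >0.1 stratum, frequencies taken from the
graph database) and within genome groups; empty strata are reported as
undefined rather than zero. Supporting arithmetic is exact: read counts for
a coverage level are `round(coverage * target / (read_len * 2))` for paired
data (validated against the published 5,667 / 56,667 / 283,333 pair counts
for a 170 Mb target), and the GBS target size is retained sites times read
length (1.96 M sites x 100 bp = 196 Mb). Truth sets can be pre-filtered
with the published rule (MAF >= 0.015, missing fraction strictly below
10%). Down-sampling is uniform without replacement, order-preserving,
pair-aware and byte-reproducible per seed.

## Diversity and LD summaries

Windows are defined by SNP count (2000 sites stepping 1000 by default), as
in the source protocol, while nucleotide diversity is reported per bp of
the window's spanned positions — the window definition mixes site counts
with per-bp diversity, and the spanned-bp denominator is the explicit
reconciliation chosen here. Per-site diversity uses the unbiased
$2p(1-p)\,n/(n-1)$ with per-site non-missing counts, which equals explicit
pair enumeration. Tajima's D uses the standard constants with $n$ = panel
size; with missing data the same per-site pair-average definition feeds the
statistic, which is an approximation (the classical derivation assumes
complete data). LD is the squared Pearson correlation of allele codes over
pairwise-complete samples (PLINK-compatible); decay curves bin pairs by
distance (100 kb bins on the synthetic scale, configurable), the initial
value is the first bin's mean, and the half-decay distance is the midpoint
of the first bin at or below half of it. Marker pruning removes the later
site of any within-window pair with $r^2 \ge 0.6$ (50-site windows, step
10), matching the published thinning rule.

## The synthetic study

The generator emulates the roles of the source study's datasets at desk
scale, with all randomness behind one master seed. Defaults — chosen once
as realistic study conditions:

* **Genome**: 2 chromosomes x 200 kb, 30 gene islands each (1–3 kb), genes
  GC-rich (60%) as is typical for grass gene space; 40% of each intergenic
  stretch is tiled from a 3-motif repeat library, giving the ambiguous
  background that makes intergenic reads unplaceable. Chromosomes carry
  genome-group labels (A, D).
* **Founder panel**: 6 accessions; substitutions sprinkled in gene space at
  0.005/bp (A-like groups) and 0.002/bp (D-like), reproducing the
  higher-diversity A/B versus depauperate D contrast. The last founder
  ("donor") carries a 10x-divergence haplotype over a chr1 interval,
  standing in for a wild-relative introgression. Mutation sprinkling is
  deliberately simpler than a coalescent model — sufficient for
  haplotype-structure tests, but it produces founder-private variants and
  no realistic allele-frequency spectrum or LD decay, so panel-level
  spectra are qualitative only. Alternate alleles are a deterministic
  function of position, keeping sites bi-allelic panel-wide.
* **RILs**: biparental families; per line and chromosome, Poisson(2)
  crossovers with uniform breakpoints; 6 selfing generations leave
  residual heterozygosity $2^{-6}$, masked to missing in the truth — the
  same treatment heterozygous calls receive at ingestion. The
  parental-origin painting is recorded as truth.
* **Reads**: capture-like (paired 2x150 bp fragments starting uniformly
  within reference ranges), GBS-like (single 100 bp reads anchored at
  PstI sites retained within 250 bp of an MspI site, running into the
  PstI–MspI fragment; digestion is applied with the repeat fraction
  excluded, emulating methylation-sensitive PstI), and skim-like (paired,
  uniform genome-wide including repeats). Per-base substitution errors at
  0.002; read counts follow the same coverage arithmetic as the evaluation
  module, from each protocol's own target size.

## What the benchmarks show — and do not show

The packaged acceptance checks run the full loop: build the graph from the
simulated founders, impute 20-line RIL families at 0.1x capture-like
coverage over 3 seeds, and require mean concordance at or above 0.95; they
also require accuracy non-decreasing in coverage (0.01x / 0.1x / 0.5x over
5 seeds), the capture >= GBS >= skim protocol ordering at an identical
sequencing budget in bases, and a strict accuracy gain on an introgressed
interval when the donor haplotype is present in the graph versus removed.
These are property-based stand-ins for the published wheat numbers, not
reproductions of them: the real accuracies require the real exome/GBS data.

Two desk-scale caveats matter when reading the protocol comparison. First,
a 400 kb genome that exercises the pipeline must be far more gene-dense
(~37% within ranges) than wheat (~1%), which inflates skim's informative
read fraction. Second, the pseudo-mapper turns repeat ambiguity into read
*loss* (multi-range discard) rather than erroneous evidence, removing the
mis-mapping noise that penalizes skim-seq hardest on real polyploid data.
Both effects compress the GBS-vs-skim margin to well under a point here,
whereas the real-data gap is about three points; the ordering direction is
preserved under the equal-bases budget, which is the comparison a
complexity-reduction assay is designed for.

Problem sizes throughout (2 chromosomes, 60 ranges, ~3,500 sites, families
of 5–20 lines, 3–5 seeds per property) were chosen as the smallest study
that exercises every code path with stable Monte-Carlo margins.

## Numerical and degenerate-input choices

All HMM arithmetic is in log space; normalizations use log-sum-exp, so
chromosomes with $10^5$ ranges and $10^3$ reads per range stay finite.
Read-count rounding is half-up (`floor(x + 0.5)`), validated against all
three published pair counts. Missing-data conventions: all-missing sites
stay missing in consensus; all-missing strata are undefined; zero-overlap
concordance is an explicit error rather than a zero. Degenerate inputs
(empty ranges, empty read sets, haplotypes shorter than k, chromosomes
without ranges) either warn and degrade gracefully or abort with a message,
as exercised in the test suite.

## Limitations

Bi-allelic SNPs and small indels only; no diploid/heterozygous path pairs
or posterior genotype dosages; no recombination-map-informed transitions;
no base-quality use; the simulator makes no claim to realistic wheat
demography, LD structure, or homoeolog cross-mapping beyond the repeat
background. The graph stores informative (gene-anchored) ranges only —
whether intergenic ranges should be stored at all is left open upstream,
and they are deliberately omitted here.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- sim_config(seed = 1)
ref <- simulate_reference(cfg)
founders <- simulate_founders(ref)
panel <- build_panel_graph(ref, founders)
glance(panel$graph)

rils <- simulate_rils(founders$founder01, founders$founder02,
                      panel_sites(founders, names(ref$chrom_lengths)),
                      ref, names_ab = c("founder01", "founder02"))
impute_family(panel, ref, rils, cfg, lines = "ril001", coverage = 0.1)
```
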