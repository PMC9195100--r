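---
title: "Tiled-bin WGBS differential methylation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiled-bin WGBS differential methylation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methTiler)
```

# The analysis problem

Whole-genome bisulfite sequencing (WGBS) reads out cytosine methylation at
single-base resolution: unmethylated cytosines are converted to uracil
(sequenced as T), methylated cytosines are protected. After alignment and
per-cytosine counting, the data for one sample are, at every cytosine,
a pair (methylated reads, total reads). methTiler starts from exactly this
per-cytosine count table (the CGmap-style text format) and carries out the
downstream statistics for a paired treatment/control design in a plant
genome, where methylation occurs in three sequence contexts — CG, CHG and
CHH (H = A, C or T) — that are maintained by distinct pathways and must be
analysed separately.

The stages are:

1. **Non-conversion estimation.** The chloroplast genome is essentially
   unmethylated, so its pooled methylated-read fraction estimates the rate
   `r` at which unmethylated cytosines escape conversion.
   `estimateNonconversion()` returns `sum(meth) / sum(total)` over the
   organelle's cytosines; typical WGBS libraries give `r < 0.005`
   (conversion > 99.5%).
2. **5-mC calling.** At a site with `n` reads of which `m` support
   methylation, the null hypothesis "all signal is non-conversion noise"
   gives `m ~ Binomial(n, r)`. `callMC()` computes the exact upper-tail
   probability `P(X >= m)` and calls the site methylated at a raw p-value
   cutoff of 0.001. The test is one-sided because under this error model an
   excess of unconverted reads can only indicate methylation. Sites under
   the depth floor (default 5 reads) are *unassayed*, not unmethylated, and
   are excluded from every denominator. No FDR correction is applied at
   this stage — the raw 0.001 cutoff defines the call, and FDR control
   belongs to the differential stages.
3. **DmC and DMR detection.** Differential testing uses two-sided Fisher's
   exact tests on the 2x2 read-count table `[[meth_t, unmeth_t],
   [meth_c, unmeth_c]]`: per cytosine for DmCs, and per fixed 100-bp bin
   (counts pooled over the bin's cytosines of one context) for DMRs.
   Benjamini-Hochberg q-values are computed within each context. A bin is
   a DMR when q < 0.05, the absolute level difference is at least 0.20,
   the level ratio is at least 2-fold, and the bin contains at least 3
   DmCs.
4. **Genic territories.** Each DmC/DMR is allocated to one of eleven
   gene-relative territories (tiered promoters <1 kb / 1-2 kb / 2-3 kb
   upstream of the TSS, 5' UTR, first/other exons, first/other introns,
   3' UTR, 1 kb downstream, distal intergenic).
5. **Integration with expression.** Genes are classified up/down/ns from
   replicate FPKM values (2-fold change and p < 0.05); DMR direction and
   DEG direction are joined into hypo_up / hypo_down / hyper_up /
   hyper_down / uncorrelated categories; metagene methylation profiles are
   drawn by expression stratum; qPCR validation data are reduced with the
   2^-ddCt formula.

# Statistical choices and their rationale

## Fisher's exact test, two-sided rule, and bit-exact antisymmetry

`fisherTest2x2()` enumerates the full hypergeometric support with fixed
margins: every table whose probability does not exceed the observed
table's probability contributes to the two-sided p. A relative tie
tolerance of 1e-7 makes mathematically tied tables (e.g. in symmetric
margins) count despite floating-point jitter — the same convention
`stats::fisher.test` uses, and the unit tests check exact agreement with
both `fisher.test` and a from-scratch log-factorial enumeration. The
function is implemented vectorised (rather than looping `fisher.test`)
because the per-cytosine DmC stage tests several hundred thousand sites.
Tables are first canonicalised to a fixed row orientation; since the
two-sided p is mathematically invariant under swapping the rows, this
makes the invariance hold *bit-exactly*, so exchanging treatment and
control provably flips every DMR's direction while reproducing identical
p- and q-values.

## Reading of the bin filters

"Covered by five reads" is interpreted as *mean per-cytosine depth >= 5 in
each sample*: a per-bin-total reading would be vacuous at 25x coverage,
and a per-site-minimum reading is available via `callDmCs(minDepth=)`.
The bin level is the pooled (read-weighted) level `sum(meth)/sum(total)`,
not the mean of per-site levels, so the effect size and the Fisher table
describe the same quantity. The 2-fold criterion is applied to the ratio
of the two pooled bin levels with an epsilon floor of 0.01 on the
denominator (a fold on counts or odds would be an equally defensible
reading; the level-ratio reading keeps all three thresholds on one scale).
The >= 3-DmC rule is applied as a post-filter on otherwise-passing bins.
Ties and ordering are resolved genomically so output files are
byte-deterministic.

## The per-site DmC test is a surrogate

Upstream toolchains describe per-site testing via F-tests and logistic
regression; with a single library per condition and no covariates, the
information available at one site is exactly the 2x2 read-count table, so
methTiler uses the same exact test per site, with BH control within
context and a 0.20 minimum level difference. This is a deliberate,
documented surrogate, not a claim about what any particular external
pipeline computes.

## Territory precedence

A position near compact genes can fall into several candidate territories
(e.g. one gene's promoter and a neighbour's exon). Candidates are ranked
genic-features-first (UTRs, exons, introns) over promoters over
downstream, with nearest-TSS as tie-break and gene id as a final
deterministic tie-break; anything hitting no candidate is distal
intergenic, so every feature gets exactly one label and fractions sum
to 1. DMR intervals enter by midpoint, which keeps the distribution a
partition (an any-overlap mode would double-count). When a gene carries
several DMRs in one context, the *integration* stage instead ranks
promoter tiers first, reflecting promoter methylation as the primary
regulatory signal.

## DEG classification

The expression matrix arrives as replicate-level FPKM. `classifyDEG()`
tests log2(FPKM + 1) with a Welch two-sample t-test and requires both
p < 0.05 and a 2-fold change of pseudocounted means. The pseudocount of 1
stabilises logs of lowly expressed genes; with three replicates the Welch
test is deliberately simple and is labelled a surrogate for a full RNA-seq
differential pipeline, which sits outside this package's scope (read
alignment and transcript quantification are upstream inputs here).

# The synthetic data generator

`simulationParams()` + `simulateGenome()` + `simulateMethylomePair()` +
`simulateExpression()` produce a complete study with known ground truth.
The generator emulates the statistical structure of a real paired WGBS
experiment:

* **Coverage**: per-site depth ~ NegBinom(mean = 25, size = 5),
  independent across sites — the "~25x" design coverage with realistic
  overdispersion. Sites drawing depth 0 are simply absent, as in real
  per-cytosine tables.
* **Non-conversion**: observed methylated reads ~ Binomial(depth,
  level + (1 - level) * r) with r = 0.005. Methylated cytosines are
  treated as fully protected (conversion failure of methylated C = 0);
  only the single non-conversion rate of unmethylated C is modelled.
* **Baseline levels**: per-context two-component beta mixtures — CG
  bimodal (mass near 0 and near 0.9), CHG intermediate, CHH low. The
  default weights (CG 0.24, CHG 0.15, CHH 0.06 high-component) were set
  once, from the per-component call probabilities under the 25x / 0.005
  error model, so that the genome-wide methylated-cytosine fraction lands
  in the low-to-mid teens of percent, the range reported for rice — a
  soft calibration of the defaults, not an asserted output. CG sites are
  strand-symmetric (both cytosines of a CpG share one true level, as
  maintenance methylation makes them in real genomes); CHG/CHH are drawn
  independently per strand.
* **Spiked DMRs**: 100 bin-aligned 100-bp regions receive a true level
  shift of |delta| = 0.4 (signs alternating). Inside a spiked region the
  control baseline is *redrawn* uniformly so that base + delta stays
  within [0.05, 0.95]; the treatment level is then exactly base + delta.
  This makes the spike's true effect equal to delta by construction
  instead of being silently clipped when the baseline leaves no headroom —
  the ground truth would otherwise not mean what it says.
* **Expression linkage**: 30% of genes are "linked": their proximal
  promoter ([TSS-200, TSS)) is spiked with delta = -0.5, and their
  treatment-mean log2 expression shifts by -slope * delta = +1.0 (slope
  2), so promoter hypomethylation raises expression. Replicate noise is
  log-normal with sd 0.25 on the log2 scale. Unlinked genes have zero
  expected shift.
* **Organelle surrogate**: one chromosome (`chrC`) is truly unmethylated
  everywhere and carries no genes; it exists to exercise the
  conversion-rate estimator exactly as a chloroplast does.

What the generator does **not** emulate: read-level errors, mapping bias,
PCR duplicates, M-bias along reads, sequence-dependent coverage,
transposable-element structure, or correlated methylation beyond the CpG
pair. Tests passing on this generator therefore validate the *statistics*
of the pipeline (calibration of the exact tests, FDR behaviour, coordinate
arithmetic, direction bookkeeping), not robustness to alignment artefacts.

Determinism: every generator function derives its own sub-seed from
`seed`, so one seed fixes the entire study byte-for-byte, which the test
suite asserts on the written FASTA/GFF3/CGmap/BED/TSV outputs.

# Numerical and degenerate-input conventions

* All internal containers are `GRanges` (1-based inclusive); CGmap and
  GFF3 enter 1-based, BED leaves 0-based half-open. Bin starts follow the
  floor rule (a site at 1-based position 101 is in the bin covering
  [100, 200) in 0-based terms).
* A 2x2 table with any zero margin has a single achievable configuration:
  p = 1 by convention (the enumeration yields this naturally).
* `m = 0` methylated reads give a binomial tail of exactly 1.
* Zero-coverage sites are dropped at ingest with a logged count; sites
  below the assay depth are flagged unassayed and excluded from
  denominators rather than counted as unmethylated.
* The fold ratio uses an epsilon floor of 0.01 so fully unmethylated bins
  cannot produce infinite folds.
* Contig-edge cytosines whose triplet is truncated are classified only
  when resolvable (a terminal `CG` still is CG); otherwise they are
  excluded from context-resolved analyses.
* Chromosome name matching across FASTA/GFF3/CGmap is exact-string.
  Mismatched chromosome sets between two samples warn and proceed on the
  intersection.

# Problem sizes used in validation

The shipped validation (test suite and `scripts/acceptance.R`) runs the
generator at three scales chosen to exercise every code path while staying
desk-sized: a ~50 kb toy annotation for exhaustive per-base territory
oracles, a 300 kb study for pipeline-level properties, and a 1 Mb study
(25x, 100 spikes, |delta| = 0.4) for DMR recall and empirical FDR. At the
1 Mb scale the pipeline tests roughly 440,000 cytosines and 30,000
filtered (bin, context) units in well under a minute.

# Known limitations

* Single library per condition at the methylome level: the exact-test
  framework measures read-sampling noise, not biological replicate
  variance. Replicate-aware dispersion modelling is out of scope.
* The DEG surrogate is a t-test on log FPKM, not a count-model fit.
* Only the quoted eleven-territory scheme is implemented; alternative
  3-way promoter/body/intergenic summaries can be derived from it by
  merging labels.
* Percent-correlated integration summaries depend strongly on the
  denominator convention; `correlateDmrDeg()` documents its denominator
  (all genes in the DEG table by default) and lets the caller override it.
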