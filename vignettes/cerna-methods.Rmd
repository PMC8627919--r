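---
title: "Methods: ceRNA network analysis with cernakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network analysis with cernakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernakit)
```

# The analysis

`cernakit` implements a complete competing-endogenous-RNA (ceRNA) analysis
for a bulk two-group RNA-seq design — typically a small knockout-vs-wild-type
comparison with three animals per group. The premise of a ceRNA analysis is
that a lncRNA and an mRNA which share binding sites for the same miRNA can
titrate that miRNA away from each other, which couples their expression: the
observable signature is a lncRNA–miRNA–mRNA triple in which the lncRNA and
mRNA are strongly *positively* co-expressed, the lncRNA carries a predicted
site for the miRNA, and the miRNA targets the mRNA.

The pipeline runs in protocol order:

1. **Sample QC** — pairwise Pearson correlation between samples and PCA on
   gene-wise centered log2 normalized expression.
2. **Differential expression** — median-of-ratios normalization, a
   negative-binomial Wald test per gene, and the screen *p* < 0.05 with
   |log2FC| > 1 (fold change > 2), split into differential mRNAs (DEMs) and
   lncRNAs (DELs).
3. **Co-expression** — Pearson correlation of every DEL–DEM pair over all
   six samples, screened at |r| > 0.8 and *p* < 0.05; the top 500 pairs by
   *p* form the co-expression network.
4. **Enrichment** — hypergeometric over-representation of the DEMs in
   GO/KEGG-style term sets with Benjamini–Hochberg control (count ≥ 3,
   adjusted *p* < 0.05), reused per-lncRNA on each DEL's co-expressed mRNAs
   (guilt-by-association annotation).
5. **Cis targets** — coding genes within 100 kb of a DEL on the same
   chromosome, intersected with the passing co-expression pairs.
6. **Trans targets** — co-expressed pairs on *different* chromosomes whose
   transcripts form a strong RNA–RNA duplex (≥ 10 directly paired bases,
   energy ≤ −50); the 200 lowest-energy pairs form the trans network.
7. **miRNA sites** — every miRNA aligned against every DEL transcript with
   the duplex engine; pairs with score ≥ 140 and energy ≤ −20 are kept.
   miRNA→mRNA pairs come from a curated interaction table when available,
   otherwise from an exact seed match (miRNA positions 2–8, reverse
   complemented, in the 3′ third of the transcript).
8. **ceRNA network** — triples assembled from the three relation tables with
   positive co-expression r > 0.8, narrowed to r > 0.95, built into a typed
   undirected graph, and ranked by node degree (top 5 per class).

Every threshold above is a `cerna_config()` default; a single literal test
asserts each one.

# Statistical models and their assumptions

## Normalization

Size factors use the median-of-ratios estimator: for sample *j*,
`sf_j = median_g( count_gj / geomean_g )` over the genes expressed in every
sample, rescaled to geometric mean 1. This assumes most genes are not
differentially expressed, so the median ratio tracks library depth rather
than biology.

## The negative-binomial Wald test

Counts are modelled per gene with mean *m* and variance *m* + φ*m*², the
standard NB2 parameterization. The per-gene dispersion φ is estimated by the
method of moments within each group — φ̂ = (v − m)/m² — pooled across the two
groups and floored at 0 (a Poisson fallback for underdispersed genes). The
Wald statistic on the log2 difference of group means uses the delta-method
variance `(m + φm²)/(n·(m ln2)²)` and is referred to a Student *t*
distribution with *n*₁ + *n*₂ − 2 degrees of freedom.

The *t* reference is the one deliberate small-sample choice in the package:
with three replicates per group, a plug-in Wald statistic referred to a
standard normal rejects ~11% of null genes at the 5% level, because the
moment estimate of φ is noisy at two degrees of freedom. The *t*(4)
reference absorbs that noise; on 2,000 simulated null genes the type-I error
is 0.03–0.05 across seeds. This is a simple, fully specified estimator — it
does not attempt the dispersion shrinkage of the DESeq family, and per-gene
power at *n* = 3 is accordingly conservative for weakly expressed genes.

Genes with all-zero counts get *p* = 1 and a flag; a zero mean in one group
only is floored at half a normalized count and flagged. The test is a pure
function of normalized counts, so rescaling a sample's counts rescales its
size factor and (up to the small mean-dependence left by the global
geometric-mean constraint) leaves *p*-values unchanged.

## Screens and boundaries

All of the protocol's screens are strict or inclusive exactly as printed:
*p* < 0.05 and |log2FC| > 1 strict; |r| > 0.8 and *p* < 0.05 strict;
count ≥ 3 inclusive with adjusted *p* < 0.05 strict; score ≥ 140 and
energy ≤ −20 inclusive; ≥ 10 paired bases and energy ≤ −50 inclusive;
r > 0.95 strict. The DE screen uses the *raw* *p*-value — the BH-adjusted
value is reported alongside for transparency but does not gate the call.
"Top 500 / top 200 / top 5" selections specify deterministic tie-breaks
(descending |r|, descending paired bases, then lexicographic ids) so output
is byte-reproducible.

## Correlation p-values at n = 6

Edge significance uses the *t* transform `t = r√(n−2)/√(1−r²)` with
*n* − 2 degrees of freedom. At *n* = 6 this is compared in the tests with
the exhaustive 720-permutation null: the permutation distribution is
discrete and conditional on the observed values, so agreement is bounded
(max |Δp| < 0.15, mean < 0.03 over random pairs) rather than exact. Note
that at *n* = 6 the conjunction |r| > 0.8 AND *p* < 0.05 is equivalent to
*p* < 0.05 alone (*p* < 0.05 ⇔ |r| > 0.8114), so the screen passes almost
exactly 5% of truly unrelated pairs — by construction, not by accident.

# The duplex engine

The RNA–RNA interaction engine is a Smith–Waterman-style local alignment of
a query against the reverse orientation of a target, scored by
complementarity: Watson–Crick pairs +5, G:U wobble +1, mismatch −3, affine
gaps −9/−4, and pair scores inside the query seed region (positions 2–8
from the 5′ end) scaled ×4 — the scoring tradition of miRNA target
scanners. A perfect 22-nt complement therefore scores
7·(5·4) + 15·5 = 215.

Energy is an additive estimate over the aligned duplex: each stack of two
adjacent pairs contributes an entry of a reduced nearest-neighbor table
(−1.1/−2.1/−3.3 for Watson–Crick stacks by G:C content; −0.5/−1.0 when a
G:U wobble is involved), each interior loop contributes +4, and the total
is capped at 0. This is an explicit, documented stand-in for the
thermodynamics of dedicated tools — the published −20 and −50 cutoffs are
reused on this engine's scale, and no claim is made that the scales are
numerically identical to the native scales of those tools.

Two regimes share the engine and differ only in thresholds:

* **miRNA sites** (short query): the reported alignment *is* the site
  duplex, and its whole-alignment energy is screened (score ≥ 140,
  energy ≤ −20). Whole-duplex energy is what keeps dinucleotide-shuffled
  controls out: a shuffled miRNA that still reaches score 140 against a
  planted site region accumulates mismatches and loops that push its energy
  above the cutoff. The measured control call rate is ≈ 3.7%.
* **Trans lncRNA–mRNA binding** (long vs long): the best-scoring local
  alignment of two ~500-nt random-background molecules is a patchwork of
  short stacks separated by loops, whose summed energy tends to 0 and would
  bury any genuine hybridization core. The screen therefore evaluates the
  *minimum-energy contiguous segment* of the alignment (a linear scan over
  the stack/loop event sequence) and applies both rules — ≥ 10 paired bases
  in that core and core energy ≤ −50 — to it. Ranking for the trans network
  uses the core energy.

# The synthetic-data generator

The generator produces a complete study — counts, sample sheet, annotation,
transcript and miRNA sequences, a curated miRNA→mRNA table, GMT term sets —
with a ground-truth manifest, so every downstream screen has a planted
signal and a background to be measured against.

Defaults describe a desk-scale version of the motivating design: 2,000
coding genes and 200 lncRNAs in 3 + 3 samples; NB counts with φ = 0.05 and
baseline means 20–500 (log-uniform); 10% of features differentially
expressed with |log2FC| = 2 and random sign; five co-expression blocks of
20 features (5 lncRNAs + 15 mRNAs) driven by a shared per-sample latent
factor on the log2-mean scale; 19 chromosomes with 30% of lncRNAs placed
within 100 kb of a coding partner; 20 miRNAs of 20–23 nt with a quarter of
lncRNAs carrying a planted site. One integer seed drives everything through
a fixed splitting scheme (seed, +1, +2, +3 for counts, annotation,
sequences, term sets), so identical configurations are byte-identical.

Choices that deserve justification:

* **Latent factor sd = 3 (log2).** Co-expression is planted by *mechanism*
  (a shared factor added to log-means before count noise), not by copying
  values, so the planted correlation must survive both NB noise and the
  large sampling variance of a six-sample Pearson r (Fisher se ≈ 0.58).
  With sd = 3 the population correlation of block pairs is ≈ 0.98, which
  keeps roughly 97–99% of them above the 0.8 screen at *n* = 6; a weaker
  factor (e.g. sd = 1.5, population r ≈ 0.95) loses 10–15% of genuinely
  co-regulated pairs to sampling noise alone. The value is deliberately at
  the strong end of co-regulation so that recovery tests measure the
  pipeline, not the luck of six samples.
* **Site planting by perfect complement.** Planted sites are full reverse
  complements of the miRNA written into the transcript at non-overlapping
  positions. A perfect ≥ 20-nt complement scores ≥ 205 and has energy
  ≤ −20.9 even in the worst all-A/U composition, so site recovery is
  guaranteed by construction rather than probabilistic.
* **Planted ceRNA triples.** One block lncRNA is designated the hub and
  receives sites for three miRNAs, each wired to two of its block mRNAs in
  the curated table; other site-bearing block lncRNAs get one miRNA and up
  to two mRNAs. The hub is therefore the top-degree lncRNA of the assembled
  network by design.
* **What "background" means for the false-positive rate.** Planted
  structure contaminates more pairs than it names: two same-sign DE genes
  are genuinely correlated across the pooled six samples (group structure),
  and even a single DE gene's mean-shifted profile has a wider-tailed
  correlation null (measured ≈ 6.7% pass rate against null partners,
  versus 5.0% nominal). The background rate is therefore measured over
  pairs with *no planted structure on either member* — not DE, not in any
  block — where the screen passes at its nominal ≈ 5%.

What the generator does **not** emulate: read-level artifacts (no FASTQ,
alignment or rRNA-depletion modelling), GC or length biases, outlier
samples, batch effects, correlated dispersion, overlapping gene models, or
realistic genome geometry. Passing recovery tests therefore demonstrates
that the pipeline's screens find the structures they define under clean NB
sampling — they say nothing about robustness to the technical artifacts of
real libraries.

# Numerical and degenerate-input policy

* Dispersion floored at 0; Wald variances floored at 1e−8; correlation
  `1 − r²` floored at machine epsilon, and p-values kept in (0, 1].
* Zero-variance genes are skipped in correlation with a warning; constant
  samples yield NA correlations with a warning.
* PCA component signs are fixed (largest-magnitude loading positive) so
  scores are reproducible across BLAS implementations.
* All ranked selections define total orders (documented tie-breaks), and
  the pipeline writes plain TSV/SIF/GraphML with stable column orders —
  two runs on the same study are byte-identical, which a test asserts
  file-by-file.
* A study in which no gene passes the DE screen runs to completion with
  empty-but-valid outputs and a warning.

# Problem sizes used in testing

The test-suite and the acceptance script run entirely on generated data:
the default 2,200-feature study for recovery checks (≈ 375 planted
co-expression pairs, 52 planted sites, 54 planted triples, ≈ 274k
background pairs), 2,000 simulated null genes for calibration, 500 genes
for power, 520 dinucleotide-shuffled controls for site specificity, and a
300-feature study for the end-to-end and determinism tests. Oracle tests
enumerate the hypergeometric tail for every universe size up to 25, all
720 orderings for the permutation null, and dense dynamic-programming
alignment for sequences up to 12 nt.

# Known limitations

* The DE test is a deliberately simple method-of-moments estimator; it
  shares no code with, and will not numerically reproduce, shrinkage-based
  tools.
* The duplex energy scale is a reduced nearest-neighbor model; energies are
  comparable within this engine only.
* Guilt-by-association annotation inherits every caveat of co-expression:
  with six samples an |r| > 0.8 edge is weak evidence on its own, and the
  per-lncRNA term lists are hypotheses, not assignments.
* The pipeline assumes a two-group design with ≥ 2 (by default 3)
  replicates per group; multi-factor designs and batch correction are out
  of scope.

# A worked run

```{r, eval = FALSE}
library(cernakit)

study <- simulate_cerna_study(simulation_config(rng_seed = 1))
result <- run_cerna_pipeline(study, out_dir = "cerna_out")

glance(result$de)       # genes tested, up/down counts
glance(result$network)  # typed node and edge counts
result$degree           # top-5 hubs per node class
autoplot(result$qc)     # PCA map
autoplot(result$de)     # volcano plot
autoplot(result$network)
```
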