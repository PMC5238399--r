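---
title: "Models and design choices in droughtdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in droughtdeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtdeg)
```

# The experimental design

Four single tag-count libraries are compared: a drought-resistant
cultivar under PEG-6000 osmotic stress (R) and well-watered (RT), and a
drought-sensitive cultivar under the same two conditions (S, ST). Four
ordered comparisons are tested — RT-R, S-R, ST-RT and ST-S — each
reported as a log2 expression ratio in a fixed orientation:
`log2(R/RT)`, `log2(R/S)`, `log2(S/ST)` and `log2(RT/ST)`. There are no
replicates: each condition is one library, which dictates the count-level
exact test below and rules out variance-component methods.

# The exact test for two tag-count libraries

## Model

The count `x` of a gene in a library is modelled as Poisson; the library
total `N` is in the millions and each gene occupies a negligible fraction
of it. For two libraries with totals `N1`, `N2` and an equal underlying
expression rate, the probability of observing `y` tags in library 2 given
`x` tags in library 1 is

$$p(y \mid x) \;=\; \Big(\frac{N_2}{N_1}\Big)^{y}\,
\frac{(x+y)!}{x!\,y!\,\big(1+N_2/N_1\big)^{x+y+1}},$$

equivalently a negative-binomial law with size `x + 1` and success
probability `N1/(N1 + N2)`. `ac_term_probability()` evaluates it in log
space through `lgamma`, so counts of 10^4 and beyond are exact to double
precision.

## Two-sided p-value and its tail convention

`deg_pvalue()` doubles the smaller of the two one-sided
equal-expression tails, each a *finite* sum of conditional terms:

$$p \;=\; \min\Big\{1,\; 2\min\big\{\textstyle\sum_{j\le y} p(j\mid x;N_1,N_2),\;
\sum_{j\le x} p(j\mid y;N_2,N_1)\big\}\Big\}.$$

The two sums are the cumulative equal-expression probabilities seen from
either library's orientation. By a binomial-tail identity of the
conditional law they add to exactly 1, which has two consequences we rely
on: the p-value is **exactly exchangeable** under swapping `(x, N1)` with
`(y, N2)` (verified to 1e-12 in the tests), and no infinite upper-tail
truncation is ever needed — the orientation whose tail is infinite is
simply evaluated from the other side. This convention differs from
doubling the *inclusive* upper tail by at most the point mass
`p(y|x)`, which is negligible at realistic counts; the inclusive-upper
variant is not exchangeable between libraries, which is why we do not use
it. Null calibration was checked by simulation: at 10^4 genes with
identical Poisson rates the raw rejection rate stays within three
binomial standard errors of the nominal level at both 0.05 and 0.01.

## Thresholds

A gene is called differentially expressed when its Benjamini–Hochberg
FDR (computed over all genes of the comparison — the multiplicity family
is the full gene list) is at most **0.001** and its absolute log2 RPKM
ratio is at least **1**. The FDR boundary is inclusive (`<=`); at double
precision the distinction from a strict inequality is immaterial but it
is fixed here once. RPKM is `10^9 C/(N L)`; the gene length `L` is
treated as an opaque positive integer supplied with the counts (whether
it is transcript or union-exon length is a property of the upstream
annotation, not of this package). Ratios use a pseudocount:
`ratio = (RPKM_a + c)/(RPKM_b + c)` with `c = 0.001` RPKM, so zero-count
genes yield finite extreme ratios (a gene of ~20 RPKM against zero gives
|log2| near 14) instead of infinities.

# Classification

## First round: Venn regions and categories

DEGs lacking any KEGG pathway annotation are removed **before** the Venn
partition — the filter-then-partition order matters for region sizes and
is fixed here. The remaining per-comparison DEG sets are partitioned
into the 15 disjoint membership regions. Because ST-RT contrasts the two
untreated controls rather than drought against control, every region
containing ST-RT is excluded from the drought analysis, leaving seven
subgroups that map onto three categories:

| Masks | Category |
|---|---|
| {RT-R}, {RT-R, S-R} | RDR (resistant-specific) |
| {ST-S}, {S-R, ST-S} | SDR (sensitive-specific) |
| {S-R}, {RT-R, ST-S}, {RT-R, S-R, ST-S} | CDR (common) |

## Second round: crucial genes

Each subgroup has its own inclusive fold-change rule on the ratios of its
member comparisons (`crucial_cutoffs()`): singleton masks require an
absolute ratio of at least 5; the two-group masks accept either a large
single ratio or a large between-comparison difference (2 for
{RT-R, S-R}; 5 for {S-R, ST-S}; 1, with single cutoffs of 3, for
{RT-R, ST-S}); the three-group mask accepts any ratio of at least 2. All
cutoffs are configurable; raising any of them can only shrink the
crucial set (tested). A gene whose mask names a ratio that is missing
from the input is an error, not a silent fail — that situation can only
arise from broken plumbing upstream.

# Enrichment

One-sided hypergeometric over-representation against the
whole-transcriptome background (`P(X >= k)` for `k` of `n` query genes
annotated among `K` of `N_bg`). The correction family is the set of
terms carried by at least one query gene — the node-wise correction of
classic GO term finders — and the corrected value is Bonferroni,
`min(1, m p_raw)`, reported as `p_corrected` rather than "FDR" to avoid
conflation with the Benjamini–Hochberg quantity used in DEG calling.
Under-representation is out of scope. The significance threshold
defaults to 0.05 on the corrected value.

# Annotation networks

The tripartite graph has gene, biological-process and pathway layers
with inter-layer edges only: gene–term edges follow the annotation
tables; a process–pathway edge exists exactly when at least one gene
carries both terms. A one-mode projection onto a layer connects two
nodes with weight equal to the number of shared linking-layer
neighbours; the projection via genes of the process/pathway layers
coincides with projecting the direct process–pathway edges weighted by
co-annotating genes, which is why a single construction rule serves all
six networks (named `<linking>-<node>`, e.g. `pathway-gene` for genes
linked by shared pathways). Projections are simple weighted graphs:
no self-loops, no multi-edges, isolated nodes retained — isolation is a
finding (a gene sharing no pathway with any other), not an artefact to
drop.

Two mean-degree conventions circulate for such networks — the average
unweighted degree `2E/N` and the edge-per-node ratio `E/N` — and
published figures for the same network are sometimes self-consistent
only under one or the other. `network_stats()` therefore always reports
both side by side and never guesses which one a reader expects.

The degree-distribution slope is the least-squares fit of
`log10(frequency)` on `log10(degree)` over non-empty positive-degree
bins, matching how binned degree histograms are usually read on log-log
axes; it is *not* a maximum-likelihood power-law estimate and is not
meant to adjudicate scale-freeness. Fewer than three usable bins return
`NA` rather than an error, since downstream reporting should degrade
gracefully on tiny networks.

# Clustering

Average linkage (UPGMA) throughout, with three distance options:
`1 - r` for Pearson and Spearman correlation, or Euclidean distance.
Ties are broken deterministically by smallest original index (the
behaviour of `stats::hclust`). Two input constructions are provided:
the expression dendrogram uses `log2(RPKM + 0.001)` (the pseudocount
decides the otherwise-undefined zeros), and the chromosome-location
dendrogram bins the five-digit position codes per chromosome with a
configurable width, default 1000 position-code units — the bin width is
a free choice and 1000 keeps the 22 chromosome rows comparable at the
observed position range (tens of thousands of units).

# The synthetic generator

`simulate_experiment()` draws Poisson counts with per-sample rates
`baseline x template x N_s/10^6`. Defaults: 2000 genes; library totals
10^6 (a deliberate down-scale of deep runs of ~6.6x10^7 reads — the
test's power at the planted effects is preserved while simulations stay
fast); baselines log-normal(meanlog log 30, sdlog 1); an annotation
universe of 128 pathways and 1200 biological processes (the magnitudes
of the real annotation); 30% of genes pathway-unannotated, driving the
annotation filter.

Planted genes fall into the seven analysed masks plus an
ST-RT-contaminated mask (whose genes must end EXCLUDED). For
multi-comparison masks the template multiplies the affected sample by
`2^delta` with `delta` drawn above the mask's crucial cutoff plus a
margin of one. Singleton masks need care: the four ratios satisfy
`log2(R/RT) = log2(R/S) + log2(S/ST) + log2(ST/RT)` identically, so a
gene with high counts everywhere cannot be strongly differential in
exactly one comparison — one of the others must cross the threshold
too. Real singleton-region genes arise where the off-comparisons are
*underpowered*: the expressed side has moderate counts and the remaining
libraries a few counts, while the pseudocounted ratio of the active
comparison is still extreme. The singleton templates reproduce exactly
that regime (expressed side ~22–32 expected counts; off-samples at
0/5/12, or 9 for the S-R pattern), with the active direction "down" in
the treated numerator — the direction that dominates such regions in
practice. Template count levels were fixed once by pilot simulation:
over 10 pilot seeds, crucial-gene recovery had sensitivity 0.956–0.989
and specificity 1.0.

Planted enrichment adds a few terms that each crucial gene carries with
probability 0.5 against an ambient annotation density of 2 pathways and
5 processes per gene; planted crucial genes always receive at least one
pathway so the annotation filter cannot silently delete the planted
classes.

What the generator does **not** emulate: biological overdispersion
(counts are exactly Poisson, matching the single-library model — there
are no replicates for a dispersion parameter to describe), correlated
annotation structure (terms are drawn independently, unlike real
ontologies with nested terms), chromosome-level clustering of DEGs, and
mapping artefacts. Passing recovery tests therefore validates the
pipeline's logic and power under its own model, not robustness to
overdispersed real libraries.

# Problem sizes used by the test-suite

The suite runs the recovery experiment at 1200 genes over 20 seeds, the
null-calibration check at 10^4 genes, brute-force projection oracles at
up to 30 genes and 10 terms, and exhaustive hypergeometric enumeration
up to a background of 12 — sizes at which the oracles are exact and the
whole suite completes in well under a minute per property. These are
the package's chosen validation scales; all thresholds and generator
parameters above were fixed before freezing the expected values.

# Known limitations

* The exact test inherits the Poisson single-library model; with
  biological replicates a dispersion-aware method should replace it.
* Bonferroni over tested terms is conservative when terms overlap
  heavily (as real ontologies do).
* The log-log least-squares slope is a descriptive statistic of the
  binned histogram, biased as an estimator of a true power-law exponent.
* The pseudocounted extreme ratios (|log2| ~ 10–14 for zero counts) are
  reporting conventions, not unbiased fold-change estimates.
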