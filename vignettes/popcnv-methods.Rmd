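---
title: "Methods: population-scale CNV landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scale CNV landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcnv)
```

This vignette documents the models and procedures behind each stage of the
pipeline, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the synthetic-data validation does and
does not demonstrate.

## Coordinates and domain model

All internal coordinates are 1-based inclusive, the convention in which
array CNV callers report positions (the start and end of a call being the
positions of its first and last supporting probe). BED input/output converts
to and from 0-based half-open at the boundary, and the length of an interval
is always `end - start + 1`. Chromosome names are normalized to the `chr`
prefix. Copy states above 3 are preserved as read — arrays can resolve a
4-copy state — but every classification collapses states to {0, 1, 3+},
because dosage response saturates and cross-sample comparisons at higher
states are unreliable.

A *call* is a departure from the expected baseline: 2 copies on autosomes,
and on the X chromosome 1 in males, 2 in females. A male X call with state 2
is therefore an amplification. Constructing a call at its baseline state is
an error, which catches a common upstream bookkeeping mistake.

## Probe suitability

Array targets are digested with *Nsp*I (`RCATGY`) and *Sty*I (`CCWWGG`)
before hybridization, so a probe whose 25-mer target or its near flanks
contain either palindromic site queries a fragment that may be destroyed.
The screen runs on `flank5 + probe + flank3` with flanks of up to 12 bp, so
sites straddling the probe boundary are caught; both sites are palindromic,
so scanning one strand suffices. When reference flanks are unavailable the
screen covers the probe alone and the filter report records that it was
partial.

Probes whose 25 bp genomic targets overlap compete for the same template;
both members of every overlapping pair are removed (a chain of mutual
overlaps disappears entirely). Strand is ignored: sense and antisense probes
target the same duplex locus.

Inter-probe-distance summaries would be dominated by probe deserts, so gaps
are computed within chromosomes only, gaps strictly greater than the third
quartile of the pooled gap distribution are discarded, and the median of the
rest is reported. Quartiles use linear interpolation between order
statistics (`stats::quantile` type 7); the literature this procedure comes
from does not state a quartile method, so the common default is used and
the choice is documented here. "Beyond the third quartile" is read
literally as strictly greater, which discards at most 25 % of gaps.

## Quality control

Sample gates are strict inequalities, exactly as usually written: log-R-
ratio standard deviation < 0.35 and B-allele-frequency drift < 0.01. Call
gates are inclusive ranges: length in [500 bp, 1 Mb], at least 3 supporting
markers, and marker density at least 0.00013 markers/bp (about one probe
per 7700 bp); whether the density gate is `>` or `>=` is not specified in
the source procedure, so the inclusive reading was chosen. Removals are
attributed to the first failing rule in the fixed order length → markers →
density so reports are deterministic; filtering is idempotent.

## Recurrence and regions

Two calls overlap reciprocally at fraction *f* when their shared length is
at least *f* of **both** lengths (the `bedtools -r` semantic). The
recurrence graph joins every pair of calls with reciprocal overlap ≥ 0.40,
including same-sample pairs; candidate pairs come from a per-chromosome
interval-overlap query, which the test suite checks against an all-pairs
brute force. Calls are sorted by (chrom, start, end, sample id) before
construction so component labels are stable.

A call is *recurrent* iff it has at least one partner anywhere in the full
panel; uniqueness is never re-evaluated within subgroups, so a call whose
only partner sits in another classification group remains recurrent in
every subgroup tabulation. Regions are connected components with ≥ 2
members — transitivity is intended, so a region's span may exceed any single
member.

Boundary concordance of a region is defined here as the mean pairwise
reciprocal overlap of its members. The concept comes from earlier CNV
work where the exact formula is not printed; this operationalization was
chosen because it satisfies the two published constraints — members with
identical boundaries give exactly 1, and diffuse regions fall below the
0.75 complexity threshold — and both the formula's threshold and the graph
fraction are exposed as arguments.

## Feature enrichment

The statistic is the number of calls sharing ≥ 1 bp with a track. The null
reshuffles calls 1000 times within their chromosomes, preserving chromosome
assignment and the exact multiset of lengths; shuffled calls are placed
independently and may overlap one another or real calls — the simplest null
consistent with "chromosome and size preserving". The 95 % interval is the
ascending sorted null at 1-based ranks 25 and 975 (scaled as
`round(0.025 n)` / `round(0.975 n)` for other permutation counts), and the
verdict is strict: a value equal to a bound is not significant. Under the
null the two tails together fire in about 5 % of runs; the calibration test
checks this over 100 seeded replicates.

Each permutation draws from its own derived RNG substream
(`seed + permutation index`), so the null is reproducible and independent
of evaluation order. Breakpoint context windows of width 500/1000/2000 bp
are centered on each call's start and end; calls short enough for their two
windows to overlap (length ≤ window) are dropped so the two breakpoints are
assessed independently, and windows are clipped (not discarded) at
chromosome ends.

## Gene overlap and subspecies-private regions

Call–gene relations partition every ≥ 1 bp overlap into encompasses-gene /
inside-gene / partial, with identical intervals resolving to
encompasses-gene. "Complete overlap" gene lists (for export to external
ontology tools, which are out of scope here) keep the first two relations
only. Pseudogenes carrying a protein-coding biotype are retained; Ensembl
biotype strings collapse via a fixed mapping (`*_pseudogene` → pseudogene,
`*RNA*` → rna, `antisense`, everything else → other).

A region is *private* to a wild-caught subspecies when at least six distinct
wild-caught samples of that subspecies carry member calls (membership =
same 40 % reciprocal-overlap component) and no wild-caught sample of the
other subspecies has **any** call overlapping the region span by ≥ 1 bp.
The asymmetric rule — membership for presence, 1 bp for absence — is
deliberate: presence claims require the event, absence claims must be
robust to partial or poorly-resolved calls. The same 1 bp criterion reports
whether classical or wild-derived samples touch each private region.

## Distances, trees, ordination

SNP distance between two samples is the fraction of loci, among those where
both have a genotype call, at which the genotypes differ (AB differs from
both homozygotes). Shared no-calls are not differences, and loci with a
no-call in either sample leave the denominator. The normalization by
co-called loci is a design choice (the source procedure does not state
one); it makes the SNP and CNV distances dimensionless fractions on [0, 1]
and hence comparable in a Mantel test.

CNV distance projects each sample's calls onto the probe map: every
autosomal probe carries state 2 unless inside one of the sample's calls, in
which case it carries the collapsed state; the distance is the fraction of
probes with differing states. X probes are excluded — sex would confound
the baseline. When overlapping same-sample calls disagree at a probe, the
most extreme departure from 2 wins, ties resolving to the deletion, and a
warning is logged.

Trees use classical Saitou–Nei neighbor joining (`ape::nj`) with sample ids
sorted before agglomeration for deterministic tie-breaking. This deviates
from the BioNJ variant used in the original workflow; on clean distance
matrices the two agree on topology, classical NJ recovers additive
distances exactly (which the tests verify against randomly generated
trees), and the choice is confined to one function. Classical MDS wraps
`stats::cmdscale` with a fixed sign convention (largest-magnitude loading
positive per axis) so embeddings are reproducible. The Mantel statistic is
the Pearson correlation of the strictly-lower-triangle entries; the test is
one-sided for positive association, `p = (1 + #{r* ≥ r}) / (1 + n_perm)`,
matching the directional claim it is used to support. An optional filter
excludes samples above the 95th call-count percentile before distance
analysis (off by default).

## Deletion false-discovery estimation

SNP genotypes inside a true deletion must be homozygous (hemizygous DNA
cannot yield AB), so a deletion call in which strictly more than 10 % of
the called genotypes are heterozygous is flagged as a putative false
positive. No-calls are excluded from the denominator — they are not
genotype calls. Both state-0 and state-1 deletions are tested;
amplifications never are. Calls containing no called SNP probe are
untestable and recorded as such. Because it is unstated whether the
published rate pooled calls or averaged per sample, the report carries both
the pooled rate and the mean of per-sample rates.

## Synthetic panels: what they emulate

`simulate_panel()` generates the complete input set from a seeded
configuration. The defaults encode the study conditions the pipeline is
meant for, at desk scale:

* **Genome/probes**: 3 autosomes of 20 Mb plus an X; exponential inter-probe
  gaps with a 1 kb median (the real array's 319 bp median scaled with the
  genome), 75 % SNP probes.
* **Calls**: log-normal lengths with deletion/amplification medians of
  20,091 and 36,708 bp (`sdlog` 0.6, reproducing the strong right skew of
  observed length distributions), group-dependent deletion probabilities
  (0.457 classical, 0.692 wild-derived, 0.745 wild-caught) chosen to land
  the published deletion/amplification ratios (0.84 / 2.25 / 2.92), more
  unique calls per wild sample than per classical sample, and planted
  recurrent regions with group-specific carrier frequencies, a subset
  private to each wild-caught subspecies.
* **Geometry**: members of one planted region are jittered within ±18 % of
  the region length, which keeps every pairwise reciprocal overlap above
  0.45 — a deliberate margin over the 0.40 threshold so recovery tests do
  not sit on a floating-point edge; unique calls and region zones are
  placed mutually disjoint. Every emitted call passes the QC gates by
  construction.
* **Genotypes**: probes carry a common base allele, per-group divergence
  (2–30 %) and individual flips (2 %) give group structure; baseline AB and
  no-call rates are 1 % and 2 % (the observed per-sample ranges). Inside
  true deletions genotypes are forced homozygous with 10 % no-call; inside
  the planted 25 % of false-positive deletions genotypes follow
  Hardy–Weinberg at a per-probe minor-allele frequency uniform on
  [0.05, 0.5], producing the heterozygote excess the FDR rule detects.
* **Feature track**: interval density inside the event loci is exactly
  `feature_factor` (default 2) times the density outside, with background
  intervals rejection-sampled into the complement.

`demo_panel()` scales this to ~51 samples and ~900 calls so an
end-to-end run takes seconds. The problem sizes used throughout the test
suite (panels of 20–50 samples, 1000-instance oracle comparisons, 100-seed
calibration, 1000-shuffle nulls) were chosen to make each statistical check
well-powered while keeping a full validation run in minutes.

What passing tests show: the interval arithmetic, clustering, counting and
rate estimation are correct (they match brute-force oracles and recover
planted truth exactly or within sampling error), and the statistical
procedures are calibrated under their nulls. What they do not show: the
generator does not model probe-level intensity noise, mosaicism, boundary
uncertainty correlated with probe density, linkage between SNPs, or
reference bias in diverse samples — so recovery rates on synthetic panels
are upper bounds, not field performance estimates.

## Known limitations

* Boundary concordance is an operational stand-in for a formula that was
  never printed; regions near the 0.75 threshold can change class under a
  different definition.
* The recurrence graph treats transitive chains as one region; a long
  low-overlap chain can produce a span much larger than any member.
* The FDR rule is one-directional: it catches false deletions with normal
  heterozygosity but cannot catch false amplifications, and it is blind in
  probe deserts.
* CNV distance depends on the probe map; two panels genotyped on different
  maps are not directly comparable.
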