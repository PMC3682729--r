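---
title: "Comparative enhancer evolution: models, parameters and design choices"
author: "enhancerEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative enhancer evolution: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerEvo)
```

# The analysis

`enhancerEvo` compares a set of tissue-specific enhancers in a query
species against the homologous set in a reference species, and asks three
questions: which enhancers are functionally conserved, what happened to
the ones that are not, and what are the consequences — for gene
expression, selection pressure and biological function — of gaining or
losing an enhancer in one lineage.

## Cross-mapping and the class model

The central classification proceeds in two lift-over passes over UCSC
chain files.

1. Reference enhancers are lifted into query coordinates. A query enhancer
   overlapping (by at least `overlap_rule` bases, default 1) at least one
   lifted reference enhancer is **shared** — conserved in *function*,
   which is the relevant notion here; the rest are **lineage-specific**.
   Reference enhancers whose lifted position overlaps no query enhancer
   are **reference-specific** by the same functional criterion (their
   sequence may well be conserved).
2. Lineage-specific query enhancers are lifted the other way. Enhancers
   with no orthologous sequence are **class III**. For the rest, the ChIP
   read density of the reference orthologue is compared to the mean
   density over evolutionarily conserved regions (ECRs): above background
   is **class I** (equivocal — plausibly a weak reference enhancer missed
   by the peak caller), at or below background is **class II** (sequence
   conserved, function lost or never gained). Class I is excluded from the
   downstream functional contrasts for exactly the reason it exists:
   it mixes true lineage-specific elements with shared elements that fell
   under the experimental cutoff.

The mapper mirrors liftOver semantics: the highest-scoring chain
overlapping the interval is selected, source bases inside aligned blocks
are counted, and the interval maps iff the aligned fraction reaches
`min_match`. The default `min_match = 0.95` follows the external tool's
documented default, since no parameters are stated for the original
lift-overs. An interval straddling two chains with no single chain
reaching `min_match` is reported `unmapped(split)`: we deliberately mirror
single-chain semantics rather than stitching chains, which keeps the
contract simple and testable base-by-base. Minus-strand targets are
normalized to plus-strand coordinates on output.

## Regulatory loci

A locus is anchored on an enhancer. For an intergenic enhancer it spans
from the start of the upstream flanking gene to the end of the downstream
flanking gene; for an intronic enhancer it spans from the end of the
previous gene to the start of the next gene (host gene plus both flanking
intergenic intervals). Three choices deserve note:

- *Intronic* means overlapping any gene body. No exon model is in scope,
  and none is needed for locus construction.
- An enhancer at a chromosome end with only one flanking gene gets its
  locus clipped to `[0, chrom_size]`, keeping lengths defined.
- Two enhancers are co-locus **iff their locus boundaries are identical**
  (same flanking-gene pair or same host gene). The alternative — overlap
  of locus intervals — would chain adjacent loci into larger clusters and
  make "the locus of" ill-defined; identical boundaries matches the
  flanking-gene construction directly.

The clustering simulation samples `draws_per_class` (default 500)
enhancers per class per replicate over `replicates` (default 1000)
replicates. A focal enhancer counts as clustered with class X iff at
least `min_others` (default 1) sampled enhancers of class X other than
itself share its locus. The source phrase "more than two heart enhancers
located in the same locus" is ambiguous between ≥ 2 and ≥ 3; we read it
as focal + at least one other (≥ 2), which matches the pairwise framing
of clustering *with* a class, and expose `min_others` so the stricter
reading is one argument away.

TSS distances are measured from the enhancer midpoint (symmetric and
standard; the source does not specify an anchor). Reporting bins are
<10 kb / 10–50 kb / >50 kb for TSS distance and <200 kb / 200–500 kb /
>500 kb for locus length.

## Expression

The heart-specificity score is
`log2(mean_heart + offset) − log2(mean_nonheart + offset)` with
`offset = 16`, the small arbitrary constant that stabilizes low readings
on processed expression arrays; means are arithmetic across samples and
taken before the offset. Log base 2 is a display choice — any base shifts
all scores by a constant factor and leaves the top-*n* ranking invariant.
The top `n = 1000` genes by score are "highly expressed heart genes";
boundary ties are broken by gene identifier so the set is deterministic.
An enhancer counts as located in a high-expression locus iff at least one
member gene of its locus is in the top set; classes are contrasted with a
two-sided Fisher's exact test.

Cross-species profile agreement is the squared Pearson correlation over
log-transformed (same offset) expression of homolog pairs, undefined
below 3 pairs. Squared Pearson on the log scale is the conventional
reading of an R² between expression profiles; the raw scale is available
via `log = FALSE`.

## Selection

Variants are polarized by the ancestral allele: `daf = af` when the
ancestral allele equals the reference allele, `1 − af` when it equals the
alternate. Records with a missing ancestral state, or one matching
neither allele, are **skipped and counted** rather than folded — folding
a minor-allele spectrum would inflate precisely the DAF ≤ 5% class the
analysis keys on. Multi-allelic records are split into bi-allelic records
first. The low-frequency cutoff is DAF ≤ 0.05, the conventional boundary
between low-frequency and common variants.

The MK machinery takes the chimp-comparison inputs as precomputed
per-region counts (`d` nucleotide differences, `π` heterozygous sites)
and forms `D = d − π`, floored at 0 with a warning: on noisy input the
difference can go negative, and a negative count of fixed differences is
not meaningful. The neutrality index `(Pe/De)/(Pn/Dn)` is reported at
full precision and rounded to 2 decimals only in rendered tables;
percentages render at 1 decimal.

`fisher_exact_2x2()` sums hypergeometric probabilities no larger than the
observed table's, with all terms computed via `lgamma` in log space; it
is exact (not approximated) for the ~10⁵–10⁶-scale counts the MK tables
produce, and is cross-checked in the tests against exhaustive enumeration
on every table with margins up to 30 and against `stats::fisher.test`.
Two-sided tests are used throughout (the sources do not state sidedness;
two-sided is the conservative default).

## Function

GO annotations are a flat term–gene table; no DAG propagation. Cardiac
terms are those whose *name* contains "heart", "cardiac" or "cardio"
(case-insensitive substring — "pericardium" does not match). The
enrichment unit is the gene: each enhancer contributes its single nearest
gene by TSS distance (ties broken lexicographically), nearest genes are
deduplicated within a test set, and the test set is contrasted against
the rest of the background under the hypergeometric
(draws-without-replacement) model, Bonferroni-corrected over the terms
that have at least one annotated background gene. Metaprofiles average
track signal in equal bins across `[midpoint − window, midpoint +
window)` with absent track positions reading as zero.

## Compensation of singleton loss

Singletons — enhancers alone in their locus — are where losing the
element cannot be buffered by a redundant neighbour. For each singleton
the reference-side locus is built around the lifted enhancer position and
searched for reference-specific enhancers. A class III singleton cannot
be lifted (no orthologous sequence), so its locus travels through the
orthology of its flanking genes instead: the homologs of the locus genes
are located in the reference annotation and the anchor is the midpoint of
their span. Singletons whose locus cannot be lifted either way are
excluded from the denominator and reported. Distances to the nearest
compensating enhancer are measured between midpoints.

# The synthetic-data generator

The generator exists so that every stage has a testable input with known
truth. Its defaults *are* the study conditions of the motivating
analysis: 5042 query and 6564 reference enhancers; a shared fraction of
1066/5042 ≈ 0.211; the lineage-specific split 3114/417/445 into classes
I/II/III; five heart and ten non-heart expression samples; a 98%
out-group presence rate for class III regions; clustering simulation at
500 draws × 1000 replicates; DAF cutoff 0.05; offset 16; top-1000
ranking.

Values the sources do not state were fixed once at what a practitioner
would call realistic, and are not revisited: a 100 Mb four-chromosome
genome (large enough for ~5000 enhancers at realistic spacing, small
enough to simulate in seconds), gene lengths 5–30 kb, enhancer lengths
0.6–1.4 kb, polymorphic-site rate 0.008/bp and heterozygous-site rate
0.005/bp, divergence 0.012/bp (primate-scale), 5% missing ancestral
alleles, clustering bias 0.3, log-normal expression with σ(log) = 1 and
15% multiplicative sample noise.

The reference genome is modelled as the query genome minus planted
deletions (each class III enhancer sits inside one) plus small
reference-only insertions and short mutual gaps, with one chain split per
chromosome and a low-score off-diagonal minus-strand decoy chain per
direction — enough structure to exercise every branch of the mapper's
gap logic and its chain-selection order. Alignment discontinuities are
kept at least 3 kb from every enhancer so planted labels are exact:
plant-and-recover tests demand ≥ 99% agreement, and the generator is
constructed so the true figure is ~100%, making any classifier regression
visible.

Two generator parameters extend the configured distributions beyond the
stated study conditions, both because a single knob could not plant the
needed contrast:

- `constrained_divergence_factor` (default 0.6) suppresses divergence
  `d` in constrained regions. The DAF shape parameters alone shift the
  site-frequency spectrum but leave `P` and `D` rates untouched, so no
  choice of them can plant NI > 1; reduced divergence under constraint is
  the standard population-genetic expectation and yields NI ≈ 3 at the
  default rates.
- `frac_class3_outgroup` (default 0.98) fixes the fraction of class III
  regions present in the synthetic out-group, planting the ancestral-
  deletion structure the out-group analysis recovers.

DAF is drawn from Beta(0.3, 1.2) in neutral regions — a heavy
low-frequency shape typical of site-frequency spectra — and Beta(0.2,
1.8) in constrained regions, shifting extra mass below 5%. The ancestral
allele matches the reference or alternate allele with equal probability,
so the VCF `AF` field alone carries no regime signal and polarization is
actually exercised.

What the generator does **not** emulate: linkage disequilibrium,
GO DAG topology (a flat term–gene map), raw reads or peak calling,
realistic chain fragmentation (tens of chains per chromosome rather than
thousands), sequence content beyond what GC summaries need, and
biological correlation between the planted structures (each is planted
independently). Passing plant-and-recover tests therefore demonstrates
that the machinery is correct and calibrated on data with the stated
statistical structure — not that the pipeline's biological conclusions
transfer to any particular real dataset.

# Determinism and numerics

All generator randomness flows from one integer seed through fixed
per-operation offsets (`withr::with_seed`; no global RNG state leaks),
so an identical configuration yields a byte-identical fixture bundle and
an identical pipeline report. Stochastic analysis stages (the clustering
simulation) take explicit seeds. Degenerate inputs have defined
behaviour: empty gene sets flag whole-chromosome loci; enhancers on
chromosomes without genes report missing TSS distances; mapped
orthologues without density data count as density 0 with a warning;
zero MK denominators report an undefined index with a reason rather than
NaN; `D` floors at 0; Bonferroni never lowers a p-value.

Problem sizes in the test-suite and acceptance runs are the package's
own verification choices: plant-and-recover at the full study scale
(5042 enhancers), mapper-vs-oracle on 10⁴ random intervals of 20–120 bp
(short intervals keep the per-base oracle honest and fast), MK
calibration on ~1.2 × 10⁵ synthetic sites, Fisher enumeration over all
~2.5 × 10⁵ tables with row margins ≤ 30, and 30 seeded replicates for
the family-wise type-I check.

# Known limitations

- Chain selection is single-best; split intervals are never stitched.
  Real liftOver additionally supports multiple output policies.
- The class I/II threshold is a hard comparison against the mean ECR
  density; no length normalization beyond reads-per-base is applied
  (none is specified by the sources), and the density unit is
  reads-per-base by construction of the lookup.
- Compensation for class III relies on flanking-gene orthology; loci
  whose genes lack homologs are excluded rather than imputed, which can
  bias the denominator when homology maps are sparse.
- GO enrichment treats annotations as given; no propagation, no
  evidence-code filtering.
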