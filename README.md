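# enhancerEvo

Comparative evolution of tissue-specific enhancers between two species.

Tissue-specific enhancers (e.g. P300 ChIP-Seq heart enhancers) are often
lineage-specific: the element exists in one species with no functional
orthologue in the other. `enhancerEvo` implements the full comparative
analysis for a "query" species contrasted against a "reference" species:

- **Cross-mapping and classification.** Reference enhancers are lifted into
  query coordinates through UCSC chain files (a liftOver-style mapper is
  built in); query enhancers overlapping a lifted reference enhancer are
  *shared* (functionally conserved), the rest *lineage-specific*.
  Lineage-specific enhancers are partitioned into **class I** (orthologous
  sequence present, reference ChIP read density above the conserved-region
  background — equivocal), **class II** (sequence conserved, no reference
  signal) and **class III** (no orthologous sequence at all). Out-group
  chain sets decide whether class III sequences are ancestral (deleted in
  the reference lineage) or novel insertions.
- **Regulatory loci and clustering.** Each enhancer's locus is the two
  flanking genes plus the intergenic interval (intergenic enhancers) or the
  host gene plus both flanking intergenic intervals (intronic enhancers). A
  seeded resampling simulation quantifies how often enhancers of one class
  cluster with each class in the same locus.
- **Expression impact.** Genes are ranked by the heart-specificity score
  `log2(mean_heart + 16) − log2(mean_nonheart + 16)`; the fraction of each
  enhancer class located in loci of the top-1000 heart genes is compared by
  Fisher's exact test. Cross-species expression-profile agreement is
  summarized as the squared Pearson correlation (R²) over homolog pairs.
- **Selection pressure.** Variants are polarized by ancestral allele to
  derived allele frequencies (DAF); the fraction of low-frequency variants
  (DAF ≤ 5%) per region class is contrasted with a pseudogene neutral
  reference. The McDonald–Kreitman test compares polymorphism *P* with
  fixed differences *D* = *d* − *π*; the neutrality index
  NI = (*P*e/*D*e)/(*P*n/*D*n) exceeds 1 under negative selection.
  Fisher's exact test is implemented in log space and exact for counts up
  to ~10⁶.
- **Function.** Cardiac GO terms ("heart"/"cardiac"/"cardio" in the name)
  are tested for enrichment among the nearest genes of each enhancer class
  (hypergeometric test, Bonferroni correction), and histone-mark signal is
  summarized as metaprofiles around enhancer midpoints.
- **Compensation.** For singleton enhancers (alone in their locus), the
  orthologous reference locus is checked for reference-specific enhancers
  that could buffer the loss of the element.

A first-class synthetic-data module generates complete seeded fixture
bundles (annotation, enhancer sets, chain files with planted deletions,
VCF with neutral vs constrained DAF spectra, expression tables with
planted heart genes, GO annotations, signal tracks) with known ground
truth, so the entire pipeline is testable without any external download.

## Worked example

Generate a small synthetic bundle and run the full pipeline:

```r
library(enhancerEvo)

cfg <- sim_config(seed = 1, n_chromosomes = 2, chrom_length = 3e6,
                  n_genes = 200, n_enhancers_query = 400,
                  n_enhancers_reference = 520, n_pseudogenes = 150,
                  n_ecr = 120, n_go_terms = 100, n_cpg_islands = 80,
                  n_planted_heart_genes = 60)
bundle_dir <- tempfile("bundle")
write_fixture_bundle(cfg, bundle_dir)
report <- run_pipeline(bundle_dir, pipeline_config(replicates = 200, top_n = 60))

report$classify$summary$pct_lineage_specific
#> [1] 79
report$loci$clustering[, 1:3]
#>   focal_class pct_clustered_with_shared pct_clustered_with_lineage
#> 1      shared                 47.058824                   30.58824
#> 2     lineage                  8.571429                   52.06349
report$selection$mk_table[, c("class_label", "neutrality_index", "regime")]
#>   class_label neutrality_index   regime
#> 1      shared         4.688984 negative
#> 2      class2         2.431731 negative
#> 3      class3         2.235704 negative
#> 4 pseudogenes         1.000000  neutral
```

79% of the 400 query enhancers are lineage-specific (the generator plants
a shared fraction of ~0.21); enhancers cluster preferentially with their
own class (planted assortative placement); all enhancer classes show
NI > 1 against the pseudogene reference because the generator suppresses
divergence in constrained regions.

The statistics also run directly on published count tables — for example
the MK test on a polymorphism/fixed-difference table against a pseudogene
reference:

```r
mk <- mk_test(12893, 10148, 349789, 442395)
round(mk$neutrality_index, 2)
#> [1] 1.61
mk$regime
#> [1] "negative"
```

`scripts/run_pipeline.R` is a thin command-line wrapper:

```sh
Rscript scripts/run_pipeline.R --bundle <dir> --outdir results --seed 1 [--stages classify,selection]
```

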