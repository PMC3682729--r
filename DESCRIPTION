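Package: enhancerEvo
Title: Comparative Evolution of Tissue-Specific Enhancers Between Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies enhancers of a query species as functionally shared
    with, or specific to, a lineage relative to a reference species using
    UCSC chain-file interval lift-over, and partitions lineage-specific
    enhancers into three classes by sequence conservation and orthologous
    ChIP-Seq signal. Quantifies locus-based enhancer clustering by stochastic
    simulation, enrichment of enhancer classes in loci of highly expressed
    tissue genes, selection pressure via the derived allele frequency
    spectrum and the McDonald-Kreitman neutrality index against a pseudogene
    neutral reference, cardiac Gene Ontology term enrichment with Bonferroni
    correction, and compensation of singleton enhancer loss by
    species-specific enhancers in orthologous loci. Ships a seeded
    synthetic-data generator that plants ground-truth structure (shared
    fraction, class labels, chain deletions, selection regimes, heart-high
    genes) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
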