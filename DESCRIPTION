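Package: crossvar
Title: Comparative Variant Analysis Between Closely Related Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative small- and structural-variant analysis
    between two closely related genomes, as used in cross-species studies of
    recently diverged taxa. Provides quality filtering and typing of called
    variants, functional-region classification (promoter, UTR, coding, splice
    site, intron, flanks) with genome-coverage normalisation, codon-level
    effect prediction, within/between-comparison variant-sharing
    classification, per-gene mutation-load accumulation with quantile-based
    candidate gene selection, and topology-aware GO term enrichment (classic
    Fisher, weight and elim decorrelation). A self-contained simulator
    generates genomes, gene models, ontologies and variant call sets with
    planted signal so the full pipeline is testable without external data.
    Assembly contiguity statistics (N50/L50, contig breaking at N runs) and
    k-mer-spectrum genome-size estimation are included for assembly QC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
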