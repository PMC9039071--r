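Package: tadakit
Title: Targeted DamID Binding and Chromatin Accessibility Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of Targeted DamID (TaDa) and chromatin
    accessibility (CaTaDa) sequencing experiments: the genome is tiled into
    fragments delimited by GATC motifs, aligned read positions are counted
    and RPM-normalized, Dam-fusion over Dam-only log2 ratio profiles are
    quantile-normalized across replicates, averaged and backtransformed,
    broad peaks are called with a Poisson model and filtered for replicate
    consistency at stringent FDR, binding patterns across constructs and
    cell types are clustered by silhouette-optimized k-means, peaks are
    annotated to the nearest protein-coding TSS, and peak-gene associations
    are tested for enrichment among differentially expressed genes with
    exact binomial and hypergeometric models. A synthetic-data generator
    plants binding archetypes, accessibility states and differential
    expression with known ground truth so that every pipeline stage can be
    validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    limma,
    cluster,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
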