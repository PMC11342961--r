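Package: highevoR
Title: De Novo Mutation Identification, Rate Estimation, and Regulatory
    Enrichment for Deaminase-Based Germline Mutagenesis Screens
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mutation-accumulation experiments in which
    a transcription factor fused to a cytosine deaminase induces heritable
    C-to-T and G-to-A mutations near the factor's binding sites. The package
    identifies de novo candidate variants as private variants in a joint
    multi-sample call, applies quality, coverage, replicate-rescue and
    sample-exclusion filters, estimates per-base per-generation mutation
    rates over callable sites, summarises mutation spectra with exact
    contingency tests, and tests proximity enrichment of induced mutations
    around motif clusters and regulatory intervals by background resampling
    with Benjamini-Hochberg correction. A forward simulator generates
    genomes, depth tracks and joint variant tables with the statistical
    structure the analysis assumes, so the whole pipeline is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    vcfR,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'enrichment.R'
    'rate-spectrum.R'
    'private-variants.R'
    'variant-io.R'
    'synthetic-data.R'
    'pipeline-cli.R'
    'utils.R'
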