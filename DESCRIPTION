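Package: snptrace
Title: Population-Diagnostic SNP Panels for Wildlife Traceability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing PCR-ready, population-diagnostic SNP
    marker panels from multi-sample variant data, for forensic assignment
    of wildlife samples to their source population. Implements variant
    hard and frequency filtering, identity-by-state kinship, genotype PCA,
    Patterson's D and f4-ratio gene-flow screening, gene-tree concordance
    screening by Robinson-Foulds distance, homozygous-allele-frequency
    (HAF) scans for population-specific fixed sites, amplicon extraction
    and constraint-based primer design, panel-based population assignment,
    and mitochondrial haplotype-network construction. A synthetic-data
    generator plants known population structure and diagnostic sites so
    the whole pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
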