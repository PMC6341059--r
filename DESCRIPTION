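Package: chromarch
Title: Comparative Chromatin Architecture Analysis from Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the three-dimensional genome organization of
    two cell types from binned Hi-C contact maps and matched RNA-seq counts.
    Implements iterative-correction (ICE) matrix balancing, an
    equal-occupancy distance-decay background with binomial significance
    calling of cis and trans bin-pair interactions, A/B compartment
    eigenvector calling with between-condition switch classification,
    TopDom-style TAD boundary detection with majority-vote compartment
    assignment, promoter-to-TES gene-loop detection, tissue-enriched gene
    designation, interchromosomal overlap and permutation statistics, and
    geometric analysis of 3D genome-structure populations (radial shells,
    trans-neighbor compartment composition). Seeded synthetic-data
    generators emulate the statistical structure of real Hi-C, expression,
    and structure-population data so the full pipeline can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    DESeq2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
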