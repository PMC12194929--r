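Package: regcircuit
Title: Binding-Site-Based Regulatory Circuit Mapping for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to map sigma factors, sigma54-dependent enhancer-binding
    proteins (bEBPs), two-component systems, transcriptional units, and
    binding-site-based regulatory circuits across bacterial genomes.
    Provides Pfam-domain-architecture classification of sigma factor
    families, reciprocal-best-hit ortholog grouping, operon inference from
    intergenic distances, position weight matrix construction and scanning
    with exact p-values under Markov backgrounds, ZOOPS
    expectation-maximization motif discovery, Schneider-Stephens
    information content, and assembly of regulator-to-operon networks.
    A synthetic-genome generator plants operon structure, domain
    architectures, orthologs, and binding sites so that every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
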