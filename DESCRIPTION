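Package: pankiwi
Title: Pan-Genome Partitioning, Variant Landscapes and Distance
    Phylogenetics for Kiwifruit Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analytics for multi-assembly plant pan-genomes,
    built around the Actinidia (kiwifruit) study design: occupancy-based
    classification of gene families into core, softcore, dispensable and
    cloud compartments; Weir-Cockerham FST in sliding windows with
    percentile-threshold calling of highly differentiated regions;
    structural-variant hotspot scanning, genic-context annotation and
    group-favored SV screens; p-distance matrices and neighbor-joining
    trees from genotype cohorts; and physical clustering of resistance
    gene analogs including head-to-head paired NLR detection. A
    synthetic-data generator with known ground truth (Balding-Nichols
    SNP cohorts, group-structured SV genotypes, planted RGA clusters)
    makes every stage testable without external genome data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
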