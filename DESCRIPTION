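Package: repeatscape
Title: Repeat Discovery, Copy-Number Estimation and Assembly-Collapse
    Detection from Shotgun Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the repetitive fraction of large plant genomes
    from low-pass shotgun reads and a draft assembly. Simulates genomes with
    planted tandem satellites, rDNA-like arrays, telomeric arrays and
    dispersed LTR-like elements together with copy-collapsed assemblies;
    clusters reads into repeat families by sequence similarity; annotates
    representative contigs (tandem periodicity, terminal-repeat structure,
    reference-library matching); estimates each family's copy number both by
    alignment of the contig to the assembly and by mapping a 1x-coverage read
    sample, under identity/coverage hit filters; classifies genomic
    distributions (dispersed versus non-dispersed, distal-end enrichment,
    colocalization); scores presence/absence patterns across accessions; and
    quantifies assembly underestimation of tandem repeats as a read/assembly
    fold change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
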