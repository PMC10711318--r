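Package: pankmer
Title: Gene-Cluster-Centric k-mers for Bacterial Genome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates gene-cluster-centric canonical k-mer variants for
    bacterial genome-wide association studies. Starting from a Roary or
    panaroo style gene presence/absence matrix and per-strain GFF3
    annotations with sequence, each gene cluster is scanned for canonical
    k-mers (optionally including upstream promoter and downstream flanking
    sequence), every k-mer is tied to its cluster of origin with
    base-resolution absolute and start-codon-relative coordinates, and
    unique presence/absence patterns are hashed so that association tools
    such as pyseer can test each pattern once (via the Rtab format).
    Includes k-mer duplication statistics across clusters, Bonferroni
    filtering and back-mapping of association results, a low-footprint
    two-pass mode, per-cluster association heatmaps and nucleotide panels,
    and a seeded synthetic pangenome simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stringi,
    cli,
    jsonlite,
    ggplot2,
    rlang,
    parallel,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
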