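Package: proxibin
Title: Proximity-Ligation Metagenome Binning with Iterated Louvain Core Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds coverage-normalized contact networks between assembly
    contigs from proximity-ligation (meta3C/Hi-C) read-pair alignments,
    partitions them by iterated Louvain community detection, pools contigs
    that co-cluster across runs into core communities, recursively
    deconvolves contaminated communities, and scores the resulting bins for
    completeness and contamination with MIMAG quality tiers. Includes a
    ground-truthed synthetic community generator so the whole pipeline is
    testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
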