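Package: genorepo
Title: Versioned Genome Repositories and Comparative Pan-Genome Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless toolkit for managing collections of microbial
    genomes in a versioned, metadata-rich folder structure, and for
    running common comparative-genomics analyses on top of it:
    annotation coverage matrices across genome sets, gene-trait
    matching via exact association tests with Benjamini-Hochberg
    correction, oligonucleotide-signature distance matrices with UPGMA
    dendrograms, taxonomy-based trees, pathway-map coverage coloring,
    and shared-gene-content (flower plot) statistics. Includes a
    deterministic synthetic-repository generator and a command-line
    interface, so every analysis is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
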