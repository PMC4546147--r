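Package: phagemod
Title: Modular Genome Architecture and Typing of Campylobacter Group II Phages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the comparative genomics of large Campylobacter group II
    (CP220-like) bacteriophages whose genomes are built from a few large modules
    separated by long bipartite repeat regions. Detects repeat units anchored on
    a degenerate 13-nt core motif, assembles them into bipartite repeat regions
    with per-arm orientation, segments genomes into modules, computes k-mer dot
    plots and module-level architecture signatures with inversion detection,
    simulates restriction digests (VspI/SmiI) and long-primer PCR typing assays,
    orders assembly contigs across repeat-region gaps from junction amplicons,
    and combines architecture, marker-gene (gp047, tRNA) and host-range evidence
    into phage subgroup calls. Includes a synthetic genome generator that plants
    the full modular architecture with a machine-readable truth record, so every
    stage of the pipeline is testable without downloading genome accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
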