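Package: chimerafuse
Title: Chimeric RNA Design and Breakpoint Analysis for RNA-Driven Gene Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational side of RNA-driven gene fusion
    experiments. Discovers imperfect sense-sense complementary "genomic
    stems" between the introns of two genes with a local aligner, designs
    two-arm antisense (and matched sense) chimeric RNAs that form a
    three-way junction at the stem, models the rearranged fusion allele
    and its spliced fusion transcript, infers genomic breakpoints,
    microhomology and untemplated insertions from junction-spanning
    reads at single-base resolution, and provides an in-silico PCR engine
    with nested and multiplex tiling primer schemes for breakpoint
    scanning. Includes a deterministic synthetic two-gene genome
    generator emulating the JAZF1/SUZ12 intron-size asymmetry so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    methods,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
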