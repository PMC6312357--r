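Package: ecckit
Title: Annotation, Classification and Interaction Analysis of Plant CNL
    N-Terminal (Extended Coiled-Coil) Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale analysis of the N-terminal extended
    coiled-coil (ECC) region of plant CC-type NLR immune receptors (CNLs).
    Locates the sequence features that define the ECC architecture
    (Kyte-Doolittle hydropathy, alpha-helix blocks, coiled-coil heptad
    register, the EDVID motif, the pre-P-loop and Walker-A P-loop motifs,
    the charged linker motif, CC-END and the CCVX variable segment),
    classifies receptors into architecture groups A-E via structure-word
    profiles and neighbor-joining trees, calls interactions from replicated
    yeast two-hybrid screens and computes network statistics, designs
    chimera/deletion/point-mutant panels anchored at annotated features,
    and maps a single QTL in an F2 population with a permutation-based
    genome-wide LOD threshold. A synthetic-data generator produces
    group-structured ECC panels, Y2H screens and F2 populations with
    ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    phangorn,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
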