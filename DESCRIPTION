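Package: helixfuse
Title: Terminal-Helix Geometry Screening and GPCR ICL3 Fusion-Tag Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines protein structures for candidate cryo-EM fusion tags by
    screening for near-antiparallel N- and C-terminal alpha-helices with a
    target end-to-end separation, designs chimeric GPCR constructs that
    replace intracellular loop 3 (ICL3) with a tag over a matrix of entry
    and exit junctions, and triages predicted fusion models for junction
    helical continuity, per-residue confidence, superposition to a reference
    receptor conformation, and inter-domain steric clashes. Includes a
    synthetic-structure generator with analytically known geometry so the
    whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
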