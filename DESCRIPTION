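Package: erd
Title: Evolutionary RNA Design with Sequence and Energy Constraints
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inverse RNA folding by component-level evolutionary search.
    Given a target secondary structure in dot-bracket notation, the package
    designs RNA sequences whose minimum-free-energy structure matches the
    target, optionally subject to per-position IUPAC sequence constraints and
    a free-energy interval over the target structure. Natural-looking
    sub-sequences are drawn from fragment pools built by folding and
    decomposing a sequence corpus; large targets are split hierarchically at
    multi-loops. Includes evaluation metrics (success counts, expected times,
    energy distances, Needleman-Wunsch similarity, nucleotide and base-pair
    distributions), readers and writers for dot-bracket, FASTA and CT
    formats, and a synthetic corpus generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
SystemRequirements: ViennaRNA (RNAfold, RNAeval on the PATH) for the
    thermodynamic engine; the toy engine has no external requirements.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
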