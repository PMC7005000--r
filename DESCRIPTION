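Package: tnseqsi
Title: Survival-Index Analysis and Simulation of Tn-Seq Selection Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for transposon insertion sequencing (Tn-seq) selection
    screens in bacteria. Converts transposon-junction reads or external
    alignments into per-site read counts, aggregates counts onto genes and
    derived intergenic regions, and computes length-normalised abundances
    (Dval) and per-feature survival indices (SI = treated Dval / control
    Dval) across biological replicates, with a minimum-insertion-site
    filter and ranked reporting. Includes a generative simulator of a
    saturated mini-Tn10 library passing through growth, bactericidal
    selection, colony-plating bottlenecks and multinomial sequencing, so
    that every pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    digest,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
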