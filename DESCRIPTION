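Package: transat
Title: Phylogenetic Detection of Conserved RNA Helices in Fixed Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects evolutionarily conserved RNA helices, including
    transient, alternative and pseudoknot-forming ones, in a fixed multiple
    sequence alignment with a matching phylogenetic tree. Candidate helices
    are enumerated per ungapped sequence, projected onto alignment columns,
    and scored by a length-normalised log-likelihood ratio contrasting a
    16-state base-paired substitution model against a 4-state unpaired model
    (Felsenstein pruning). Statistical significance is assessed with
    empirical p-values against a null distribution of scores obtained from
    conservation-binned column-shuffled alignments. Ships a simulator that
    evolves structured alignments down balanced binary trees under the same
    models, and the helix- and base-pair-level evaluation protocol
    (sensitivity, FPR, PPV, F-measure, MCC) with arc-diagram export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
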