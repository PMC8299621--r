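Package: cleavefeat
Title: Modeling Site-Level RNA Cleavage Efficiency from Degradome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing endonucleolytic RNA cleavage efficiency from
    degradome sequencing (TREseq/PARE) 5'-end count data. Computes site-level
    cleavage scores normalized to capped-read RNA abundance, builds an
    exhaustive sliding-window feature space (nucleotide/codon/amino-acid
    frequencies, secondary-structure stability, ribosome occupancy) around
    cleavage sites and over whole transcripts, prunes it by Spearman
    rank-correlation rules, and selects features with L1 (LASSO) and L2
    (Ridge) penalized linear regression under cross-validated penalty
    strength. A synthetic degradome generator with planted effects makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
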