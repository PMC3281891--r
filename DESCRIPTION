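Package: pqfam
Title: Remote-Homology Discovery of Seven-Transmembrane Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Iterative profile-based homology search for diverse
    polytopic membrane-protein families such as the PQ-loop proteins.
    Builds position-specific profiles from multiple alignments, scores
    sequences and profiles with affine-gap local dynamic programming,
    calibrates E-values with a maximum-likelihood Gumbel fit, and applies
    a dual acceptance criterion (significance plus full coverage of all
    transmembrane segments of the query). Includes consensus
    transmembrane-topology prediction from hydropathy, detection of
    internal N-half/C-half duplication, column conservation and motif
    analysis, neighbor-joining phylogenies, and a synthetic
    membrane-protein family generator with complete ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
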