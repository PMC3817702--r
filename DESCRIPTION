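Package: MRsearch
Title: Automated Molecular-Replacement Search Engine with a Synthetic
    Crystal Backend
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision engine for automated molecular replacement:
    extension-cycle search with branch pruning, translation-function
    Z-score based clear-solution categorization, alternative-model
    rescoring by superposition, amalgamation of clear sibling solutions,
    noncrystallographic point-group assembly detection and completion,
    and space-group arbitration over enantiomorph or point-group
    ambiguity.  The scoring backend is pluggable; a bundled synthetic
    toy-crystal generator with a maximum-likelihood-style mock scorer
    makes the full pipeline testable at desk scale without diffraction
    data or external crystallography binaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    bio3d,
    Biostrings,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
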