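Package: inappfitch
Title: Parsimony Analysis of Morphological Characters with Inapplicable
    States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scoring and ancestral-state reconstruction for discrete
    morphological characters that contain inapplicable states ("-"), as
    arise from reductively coded character hierarchies (e.g. "tail colour"
    when some taxa lack tails).  Implements a four-pass, single-character
    modification of Fitch parsimony in which the tree score is the number
    of state transformations plus the number of additional regions of
    character applicability, alongside the two traditional treatments
    (inapplicable-as-missing and inapplicable-as-extra-state), a
    brute-force labelling oracle for small trees, a parsimony-ratchet
    heuristic tree search, three-way comparison of optimal tree sets,
    NEXUS/TNT/Newick input and output, and a synthetic generator of
    reductively coded character hierarchies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    ggplot2,
    generics,
    jsonlite,
    optparse,
    stats,
    tibble,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
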