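Package: acidbridge
Title: Salt-Bridge Guided Design of Acid-Stable Peroxidase Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for engineering acid-stable lignin
    peroxidase variants by homologous salt-bridge grafting. Detects salt
    bridges on protein structures and conformational ensembles with a
    pH-aware geometric criterion, assigns protonation states with a
    mean-field titration model, maps donor bridges onto an acceptor
    scaffold through sequence alignment and rigid superposition, scores
    candidate mutations with a pH-dependent folding free-energy term, and
    fits the downstream stability (first-order inactivation half-life)
    and Michaelis-Menten (Hanes-Woolf) kinetics used to validate
    variants. Includes synthetic generators for toy structures, MD-like
    jittered ensembles and kinetics tables with known ground truth, so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
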