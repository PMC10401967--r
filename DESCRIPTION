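Package: kinactive
Title: Structural Criteria for the Active Conformation of Protein Kinase
    Domains and Assessment of Predicted Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies typical protein kinase domain structures by the
    geometric criteria of the catalytically active state: the DFGin spatial
    state of the DFG-Phe residue, the BLAminus dihedral state of the XDFG
    motif, the beta3-Lys/C-helix-Glu salt bridge, and the placement of the
    N- and C-terminal segments of the activation loop (ActLoopNT and
    ActLoopCT backbone contacts). Also measures the regulatory spine, ranks
    AlphaFold2 models of kinases by the minimum pLDDT over the activation
    loop, computes activation-loop backbone RMSD after C-terminal-domain
    superposition, and implements sequence and template curation rules
    (ortholog-hit filtering, greedy identity clustering, active-template
    selection, MSA truncation). A synthetic-fixture generator builds
    kinase-like coordinate sets with prescribed geometry so the whole
    pipeline is testable without downloading structures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
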