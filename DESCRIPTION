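Package: mgrna
Title: Validation, Classification and Motif Screening of Magnesium Sites
    in RNA Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies, validates and classifies Mg2+ binding sites in
    RNA-containing crystal structures (PDB or mmCIF). Implements a
    chemically constrained two-step inner-sphere ligand search with
    crystallographic symmetry support, three bond-valence based site
    quality scores (Qv, Qs, Qe), water-mediated outer-sphere moiety
    assignment, a hierarchical RNA-inner/RNA-outer site typing scheme,
    normalized interaction frequencies, and screening for thirteen
    Mg2+-binding motifs. Includes a deterministic synthetic-structure
    generator used for end-to-end validation of every rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
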