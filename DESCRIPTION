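Package: bfrcage
Title: Pore Subtype and Symmetry Analysis of Heteromeric Bacterioferritin Nanocages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 24-subunit ferritin-family nanocages built
    from two subunit types. Provides an exact combinatorial model of the
    octahedral (432) cage that enumerates dimer-type arrangements and their
    pore-composition spectra, geometric detection of dimers, symmetry frames,
    and the 38 ion channels (24 B-pores, six 4-fold pores, eight 3-fold pores)
    from atomic coordinates, typed dimer-interface contact analysis (salt
    bridges and pi-cation pairs), and a deterministic synthetic cage generator
    so that every geometric stage can be validated against the combinatorial
    oracle without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
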