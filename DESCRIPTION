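Package: circsponge
Title: Design and In Silico Validation of Circular miRNA Sponges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design circular RNA miRNA sponges: generation of
    bulged tandem microRNA binding sites (MBS) with central mismatch
    bulges that resist AGO2-mediated cleavage, assembly of restriction
    site-flanked DNA inserts for directional cloning between ALU arms of
    a circularizing expression vector, a sequence-level model of the
    back-spliced circular transcript with junction-aware views, scanners
    for canonical seed-match site classes (6mer, 7mer-A1, 7mer-m8, 8mer),
    full bulged sites and restriction sites on linear or circular
    sequences, positional miRNA:site duplex pairing reports, GenBank and
    FASTA input/output for annotated constructs, seeded decoy-miRNA panel
    generation for off-target checks, and the closed-form assay formulas
    (2^-ddCt relative expression, spheroid volume) used alongside sponge
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    yaml,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
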