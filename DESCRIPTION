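Package: morphcheck
Title: Steric and Topological Obstructions in Protein Structure Morphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyzes the linear interpolation (morph) between two aligned
    and superimposed protein backbone curves. Quantifies steric overlap
    against native alpha-carbon distance constraints, finds all transversal
    self-intersections of the swept piecewise-linear curve, decides which of
    them can be removed by three-dimensional analogues of Reidemeister moves
    of types 1 and 2 or by terminus contractions within a user-set
    neighborhood of the morph, and reports a smallest set of essential
    self-intersections together with a self-avoiding morph-length estimate.
    Includes gap-aware reparameterization of TM-align style alignments,
    RMSD/GDT-TS/TM scoring, curve smoothening, and deterministic synthetic
    fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
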