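Package: ntckit
Title: Dinucleotide Conformer Assignment, Refinement Restraints and
    Density Validation for DNA Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies DNA dinucleotide steps into backbone conformer
    (NtC) classes from their torsional and pseudo-bond geometry, scores
    the agreement with a confal-style 0-100 score, and turns eligible
    assignments into torsion restraint files for crystallographic
    refinement in Phenix-style and REFMAC-style dialects.  Validates
    models against electron-density maps by per-dinucleotide real-space
    correlation coefficients classified on the RSCC versus r.m.s.d.
    plane, and provides crystal-geometry analyses (symmetry-expanded
    contacts, cross-strand C1' distances, base-pair parameters, cation
    coordination).  A synthetic fixture generator builds ideal A- and
    B-form duplexes, perturbed variants, reference conformer libraries
    and model-derived density maps so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
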