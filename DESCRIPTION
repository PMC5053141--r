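Package: lrrefine
Title: Homologue-Based External Restraints and Protocol Selection for
    Low-Resolution Macromolecular Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for preparing and orchestrating restrained refinement of
    low-resolution crystallographic models. Assesses and ranks homologous
    reference chains by sequence identity, coverage and the sum of global and
    fragment-based local backbone r.m.s.d.; generates external interatomic
    distance restraints from homologues, backbone hydrogen-bond restraints and
    jelly-body-style self-restraints, serialized in the REFMAC external
    restraint keyword format; enumerates candidate refinement protocols and
    ranks their outcomes with a Q-score combining R-free with the MolProbity
    score percentile. A pluggable refinement backend with a built-in toy
    restrained minimizer allows the whole pipeline to run on synthetic
    structures without crystallographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
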