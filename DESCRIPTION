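Package: gclkit
Title: Common-Label Analysis of Kinase Conformational Changes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing G protein-coupled receptor kinase (GRK)
    structures through a common residue labeling scheme (GCL). Reads and
    filters PDB structures, maps residues to three-part common labels,
    classifies closed/open conformational states by the ionic-lock distance
    between the RH.H4H5 loop and the KD.HK helix, scores long-range
    heavy-atom contacts, computes Average Contact Scores and
    Conformational-Change scores at residue and secondary-structure-element
    level, assembles common-tendency change networks across subfamilies,
    scores alignment-column conservation on the 0-11 physicochemical scale
    with Mann-Whitney group comparison, and computes relative
    solvent-accessible surface area by state. Includes a synthetic
    structure-family generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralPrediction, Proteomics, Network, MultipleSequenceAlignment
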