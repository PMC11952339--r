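Package: EnsembleMetrics
Title: Evaluation of Protein Conformational Ensembles and Thermal Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and diagnostics for comparing protein conformational
    ensembles: side-chain torsion divergence (chiJSD), secondary-structure
    element preservation (SSEP), soft native-contact foldedness (Q) and the
    folded-state fraction (FSF), Calpha fluctuation profiles and their
    correlation, radius of gyration, contact maps, distance-PCA free-energy
    landscapes, apparent melting temperatures from sigmoid fits of
    foldedness-versus-temperature series, stereochemical integrity counters
    (heavy-atom clashes, peptide-bond length violations), and a restrained
    clash-relaxation protocol. Includes seeded generators of synthetic
    polypeptide ensembles with known ground truth for testing every score.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
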