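Package: quenchscape
Title: Conformational Landscapes and Pigment Couplings in Light-Harvesting
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis of pigment-protein complexes such as the
    minor light-harvesting antenna CP29. Builds conformational landscapes from
    molecular-dynamics ensembles by principal component analysis of circularly
    embedded backbone and sidechain dihedrals (dPCA), groups frames into
    conformational states by hierarchical clustering and ranks the residues
    that discriminate them, computes inter-helical torsion collective
    variables and carotenoid conjugated-chain dihedrals with s-cis/s-trans
    conformer classification, evaluates chlorophyll-carotenoid Coulomb
    couplings from transition atomic charges together with a rigid-sphere
    overlap parameter, and estimates charge-transfer quenching rates with
    classical Marcus theory. A synthetic-ensemble generator with planted
    ground truth makes every stage testable without trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
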