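Package: ppargscreen
Title: Sequential Pharmacophore and Field-Similarity Virtual Screening
    for PPARgamma Partial Agonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage virtual-screening cascade for retrieving
    PPARgamma-partial-agonist-like ligands from compound libraries:
    exclusion by a full-agonist "antipharmacophore", partial-agonist
    pharmacophore matching with receptor-based excluded volumes,
    fixed-pose re-matching of externally produced docking poses, and a
    shape / electrostatic field-similarity filter against known
    partial-agonist query poses. Includes enrichment-factor,
    sensitivity and specificity validation arithmetic for labeled
    active/decoy sets, atom-environment fingerprint clustering with
    Kelley-criterion level selection, drug-likeness filtering, conformer
    ensemble generation, and a synthetic benchmark generator with
    planted pharmacophore signal so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel command-line tools (obabel, obenergy) for
    conformer generation and partial-charge assignment
Config/testthat/edition: 3
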