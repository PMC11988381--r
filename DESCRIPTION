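Package: edcscreen
Title: Post-Docking Analysis of Endocrine-Disrupting Chemicals Against
    Human Nuclear Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for virtual-screening results of persistent
    endocrine-disrupting chemicals (PFAS, plastic chemicals, phthalates,
    PBDEs, bisphenols, fluorinated pesticides) docked against seven human
    nuclear receptors. Computes structural descriptors from SMILES
    (fluorinated carbon chain length, functional-group taxonomy, molecular
    weight, logP, topological polar surface area), stratifies docking
    scores into strong/moderate/weak binding classes against
    reference-ligand means, profiles receptor residues contacting docked
    poses within a distance cutoff, fits chain-length/affinity trends,
    ranks top binders and their cross-receptor prevalence, and validates
    docking via symmetry-corrected pose RMSD and agreement with
    experimental potencies. Ships a seeded synthetic-data generator so
    every stage is testable without a docking campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
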