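Package: hadmet
Title: Comparative Untargeted Metabolomics of Hydroxyanthracene-Containing Herbal Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing the untargeted LC-MS/MS
    metabolite profiles of anthraquinone-containing botanical drugs (Cascara,
    Frangula, Rhubarb, Senna). Reads Compound-Discoverer-style feature tables,
    applies a five-rule annotation screen (database confirmation, ppm mass
    accuracy, retention-time window, minimum peak area, MS2 availability) with
    MSI confidence-level assignment, classifies annotated compounds into a
    pathway/superclass/class natural-product hierarchy with per-level Graph
    Isomorphism Networks trained on molecular graphs built from SMILES,
    scores expert concordance of the assignments, and computes cross-species
    comparative statistics: four-set Venn membership regions, superclass
    distribution tables, PCA on the autoscaled abundance matrix, hierarchical
    clustering, and superclass-by-replicate heatmap matrices. A synthetic-data
    module generates every pipeline input with a known ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    ChemmineR
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
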