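Package: imdspatial
Title: Spatial Quantification of T-Cell and Metabolite Responses Around
    Implantable Microdevices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in situ drug-perturbation studies using
    implantable microdevices in tumors. Builds concentric sub-ROI geometry
    around drug-release reservoirs, quantifies marker-positive T-cell density
    responses as log2 fold changes against same-tumor empty-reservoir
    controls, links immune hotspots to spatial metabolomics through
    marker-guided paired-ROI differential abundance with hypergeometric
    pathway over-representation, and classifies spatial-transcriptomics ROIs
    by CD8 infiltration with geometric-mean normalized differential
    expression. Includes a synthetic-data generator that emulates all four
    input modalities with planted effect sizes, so every stage is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
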