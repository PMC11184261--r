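Package: nephrostrat
Title: Whole-Blood Transcriptome Stratification and In Silico Druggability
    for Active Lupus Nephritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for molecular stratification of active lupus
    nephritis from whole-blood RNA-seq: covariate-adjusted differential
    expression against matched healthy controls, weighted coexpression module
    discovery with a discovery/replication design, per-patient module
    dysregulation z-scores, Ward clustering into lo/im/hi interferon
    subgroups, serology association, regulator and drug-gene annotation, and
    mechanistic pathway signal propagation with in silico target inhibition
    and responder-proportion testing. Includes a fully synthetic cohort
    generator with planted module effects so every stage is testable without
    access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
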