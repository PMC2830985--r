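Package: stromatch
Title: Receptor-Ligand Matching Between Hematopoietic Populations and Stromal Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers candidate cell-cell communication pathways between a
    hematopoietic cell population and a stromal feeder cell from bulk
    microarray expression profiles. A curated receptor-ligand pair database
    is matched bidirectionally against differential-expression-gated,
    presence-call-filtered gene lists, mirroring the genomics-based
    interaction screens used to study B-lymphocyte development on OP9
    stroma. Includes classification of pairs as ubiquitous or
    stage-restricted along a developmental series, a supportive versus
    non-supportive stroma candidate screen, a co-culture response gene
    filter, delta-delta-Ct qPCR quantification, and a synthetic-data
    generator with planted interactions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    readr,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
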