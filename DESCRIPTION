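Package: relapsekit
Title: Somatic Mutation Filtering, Clonal Evolution and Chimerism Analysis for
    Leukemia Relapse After Allogeneic Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic analysis of acute lymphoblastic leukemia relapse
    following allogeneic hematopoietic stem cell transplantation. Implements
    candidate somatic mutation selection from matched diagnosis/remission/relapse
    call tables with donor exclusion, blast-adjusted variant allele frequencies
    and clonal evolution pattern classification (subclone survival, common
    progenitor, second malignancy), short tandem repeat peak-height chimerism
    estimation, and cohort-level mutation enrichment statistics including a
    two-sided Fisher exact test. A synthetic cohort generator with known ground
    truth (clone trees, blast-diluted binomial read counts, contaminant variants,
    STR mixtures) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
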