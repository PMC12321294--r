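Package: beaconcnv
Title: Beacon v2 Client with CNV Frequency and Survival Analysis Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A protocol-faithful client for GA4GH Beacon v2 REST endpoints with
    downstream copy-number and survival analytics. Queries individuals,
    biosamples, analyses and genomic variants across one or many beacon
    domains (with CURIE ontology filters combined by AND), flattens the nested
    JSON responses into harmonized tibbles through declarative YAML mapping
    configurations, reads and writes '.seg' and '.pgxseg' copy-number segment
    files, computes cohort CNV gain/loss frequencies over genome bins and
    per-sample CNV genome fractions, and estimates Kaplan-Meier survival
    curves with log-rank group comparison. A bundled synthetic-cohort
    generator and local mock beacon server make every component testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    IRanges,
    jsonlite,
    parallel,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    callr,
    httpuv,
    patchwork,
    readr,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
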