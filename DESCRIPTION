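Package: primorisk
Title: Dietary Risk Assessment of Pesticide Residues in Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning multiresidue pesticide monitoring results for a
    single food commodity into a dietary risk assessment in the style of the
    EFSA PRIMo (Pesticide Residue Intake Model) calculator. Provides residue
    summary statistics with limit-of-quantification censoring, compliance
    scoring against EU maximum residue limits (MRLs), acute exposure via the
    International Estimated Short-Term Intake (IESTI) compared to acute
    reference doses (ARfD), chronic exposure via the National Estimated Daily
    Intake (NEDI) compared to acceptable daily intakes (ADI), a per-sample
    cumulative hazard index, and a seeded synthetic-campaign generator for
    testing pipelines without raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
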