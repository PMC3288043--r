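Package: mirscreen
Title: Screening and Assay Statistics for Treatment-Responsive MicroRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for identifying microRNAs that respond to a
    targeted therapy in receptor-positive but not receptor-negative cell
    lines: quantile normalization of raw array intensities, a log2
    expression floor, per-line treated/control fold changes, exclusion of
    microRNAs that also move in receptor-negative lines, and a relative
    fold change (RFC) statistic aggregated across positive lines by
    geometric mean. Companion assay statistics cover delta-delta-Cq
    relative quantification, WST-1 viability inhibition, propidium-iodide
    cell-cycle mixture fitting, Annexin-V apoptosis fractions,
    dual-luciferase repression estimates and the pooled-variance t test.
    A seed-site scanner locates 6mer/7mer/8mer microRNA sites on 3'UTRs
    and builds site-disrupting mutant constructs. Synthetic-data
    generators with planted ground truth make every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
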