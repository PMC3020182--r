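Package: controlqc
Title: Layered Control-Based Quality Control for Expression Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality assessment of probeset-level expression microarray data
    using the built-in spike-in and endogenous control probesets. Partitions
    control probesets into four classes (spike-in hybridization controls,
    spike-in polyA+ controls, internal RNA degradation controls and
    endogenous "housekeeping" controls), normalizes hybridizations by
    quantile or 75th-percentile brightness scaling, screens probeset
    precision with mean/SD tables, fits a mean-centered principal component
    model per control class with venetian-blinds cross-validated component
    selection (RMSEC/RMSECV), and flags technically aberrant hybridizations
    via Q residuals, Hotelling T-squared, spike-in concentration-response
    correlation and 3'/5' degradation ratios. Includes a synthetic-data
    generator that emulates control-intensity structure with planted
    technical anomalies so the whole pipeline is testable without array
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
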