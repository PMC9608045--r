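Package: ddisignal
Title: Detection of Multiple Drug-Drug Interaction Signals from
    Spontaneous Reporting Data by Recursive Partitioning
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects signals of multiple (three or more drug) drug-drug
    interactions in spontaneous adverse-event reporting data laid out as
    linked DEMO/DRUG/REAC tables. Implements index-drug case extraction
    with drug-timing rules relative to adverse-event onset, recursive
    partitioning of cases on binary concomitant-drug indicators by a
    likelihood-ratio (G-squared) splitting criterion with a minimum node
    size, node-wise exact binomial tests of each stratum's reporting rate
    against the initial rate, and Benjamini-Hochberg false-discovery-rate
    control. Includes a synthetic report generator with planted
    interaction effects for validation and power studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
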