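Package: notgate
Title: NOT-Gate CAR T-Cell Target and iCAR Partner Discovery
Version: 0.1.0
Authors@R:
    person("notgate", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates a tumour cell-surface proteome, a healthy-tissue
    proteome matrix and CRISPR gene-dependency (Chronos) scores to nominate
    essential, rankable principal CAR T-cell targets and the inhibitory-CAR
    (iCAR) partners that restore tissue specificity through NOT-gate logic.
    Implements seven eligibility rules for principal and iCAR candidates, a
    vector score combining surface expression with essentiality, tissue
    co-expression coverage analysis for iCAR partner discovery, NOT-gate
    combination accounting, a deterministic synthetic-fixture generator with
    planted ground truth, and a command-line pipeline with reproducible
    tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
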