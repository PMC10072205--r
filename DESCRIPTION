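Package: careflowr
Title: Process Mining of Cancer Treatment Sequences with Survival Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds clean per-patient event logs from oncological treatment-line
    tables, discovers CareFlow-Miner-style treatment trees (prefix trees of
    treatment sequences with per-node patient sets, branch fractions and
    threshold pruning), computes per-node outcome statistics (best overall
    response, recurrence for adjuvant lines, anchored Kaplan-Meier overall
    survival), and supports node-based cohort algebra with anchored OS/PFS
    comparison (log-rank test, Cox hazard ratio, landmark survival rates).
    Ships a synthetic real-world-data generator with exported ground truth so
    the whole pipeline is testable without patient data, and a command-line
    interface for scripted runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
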