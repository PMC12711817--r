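Package: qbdchain
Title: Permissioned Ledger Simulation of a Quality-by-Design Clinical Trial Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, in-process simulator of a permissioned dual-ledger
    blockchain supporting a Plan-Do-Check-Act (PDCA) participant-safety pipeline
    for clinical trials. Provides a hash-chained, tamper-evident block store with
    deterministic world-state replay; a simulated network of peers, certificate
    authorities, channels and endorsement policies with the full
    propose-endorse-order-commit transaction lifecycle; planning units that
    commit stratified safe domains for critical safety factors to a trial
    ledger; conduct units that record pre- and post-administration measurements
    for enrolled participants on a patient ledger; risk assessment of
    post-administration values against safe domains, root-cause subgroup rule
    induction over flagged participants, and safety control strategies fed back
    into the next planning cycle. Ships a 30-participant pilot-trial fixture and
    a seeded synthetic cohort generator with injectable unsafe-subgroup
    patterns and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    openssl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
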