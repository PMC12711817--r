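# qbdchain

A desk-scale simulator of a permissioned, dual-ledger blockchain supporting a
Quality-by-Design (QbD) participant-safety pipeline for clinical trials. It is
aimed at clinical-trial informaticians and quality engineers who want to study
— entirely in one R process, with no external blockchain service — how a
tamper-evident audit trail, endorsement-gated writes, and a
Plan–Do–Check–Act (PDCA) quality loop interact on real trial data.

## What it models

**Ledger substrate.** Two append-only, hash-chained ledgers: a *trial ledger*
(T-ledger) holding the stratified safe domains of the monitored safety
factors, and a *patient ledger* (P-ledger) holding each participant's
`Initial → Before → After` transaction lifecycle. Each block stores
`SHA-256(index ∥ prev_hash ∥ transactions ∥ timestamp)` over a canonical
byte serialization, so any retroactive edit of block *b* invalidates
verification at index ≤ *b* + 1. Measurements travel as decimal strings, so
every value reads back from the ledger bit-exactly.

**Network.** Peers with the roles *single* (hosts one ledger), *double*
(hosts both), *DC issuer* (participant identity certificates), *endorser*,
*orderer*, and *committer*; six certificate authorities; two channels; and a
configurable endorsement policy (default: strict majority of the three
endorsers). Every write runs the full propose → endorse → order → commit
sequence, with per-channel validation ("chaincode") executed at endorsement
time and a unit-level API permission matrix gating reads and writes.
Commit-time alert hooks emulate smart-contract safety triggers. Personal
data stays in a LOCAL store; only a digest pointer goes on-chain.

**PDCA analytics.** The pipeline monitors factors F1 (blood pressure), F2
(heart rate, age-banded safe domains), F3.1–F3.4 (blood sugar by meal
context), F4 (stay-in-bed duration, informational), and F5 (ambient
temperature):

- *Plan* — screen the protocol for safety-critical factors, extract
  measurement procedures (LOCAL), commit safe domains `[L_f, U_f]` (with
  age strata and inclusive/exclusive bounds) to the T-ledger.
- *Do* — enroll participants (certificates + `Initial` transactions with all
  values `N/A`), then record pre/post administration values, gated against
  the before-phase domains (`strict` blocks deviating participants, `warn`
  records the deviations on-chain).
- *Check* — the risk assessor flags post-administration values with
  `out_of_range` (bound violated) or `borderline` (within a per-factor
  margin δ of a harmful bound, default δ = 1 unit) severity. The root-cause
  analyzer categorizes pre-values into low/normal/high levels (within a
  margin fraction of a bound; 10% default, 25% for heart rate) and induces
  conjunctive subgroup rules *sex ∧ age ∈ [a, b] ∧ pre-level conditions*
  with support ≥ 2 and precision computed against the whole cohort, age
  windows snapped outward to multiples of 5 years.
- *Act* — each rule becomes an exclusion strategy whose predicate screens
  the next cycle's roster at enrollment time, closing the loop.

A seeded synthetic-cohort generator (truncated-normal values around domain
midpoints, injectable unsafe-subgroup patterns with recorded ground truth)
supports property-style testing of the analytics.

## Worked example

The shipped pilot fixture is a 30-participant relative-bioavailability
trial: a structured protocol (factors, procedures, safe domains) plus the
pre/post measurement table.

```r
library(qbdchain)
fx  <- load_pilot_fixture()
res <- run_cycle(fx$paths[["protocol"]], fx$paths[["trial"]],
                 out_dir = "pilot-out")

res$summary$enrolled                        # 30
c(res$summary$tx_initial, res$summary$tx_before, res$summary$tx_after)
                                            # 30 30 30
flags <- res$flags
unique(flags$participant_id[flags$factor_id == "F2"])
# "P3" "P8" "P10" "P23" "P25" "P28"
```

P8 (male, 36) reaches a post-administration heart rate of 185 against the
under-40 band 90–153 (`out_of_range`); P3's 152 sits one unit under the
band's upper bound (`borderline`). Restricting the root-cause analysis to
the borderline heart-rate subset {P3, P8, P23, P28} yields two rules:

```r
named <- flags[flags$factor_id == "F2" &
               flags$participant_id %in% c("P3", "P8", "P23", "P28"), ]
analyze_root_cause(res$network, named, 1, risk_rule_config())
# <rule: sex F, age 60-65, F2-pre low, F3.1-pre high | support {P23, P28}, precision 1.00>
# <rule: sex M, age 35-40, F2-pre high, F3.2-pre high | support {P3, P8}, precision 1.00>
```

i.e. women aged 60–65 with low pre-dose heart rate and high fasting blood
sugar, and men aged 35–40 with high pre-dose heart rate and high
before-meal blood sugar, predict the unsafe post-dose heart rates. The
derived exclusion strategies screen exactly those four participants out of
a cycle-2 roster.

The same run is available from a shell:

```sh
Rscript inst/cli/qbdchain.R run-cycle \
    --protocol inst/extdata/pilot_protocol.yaml \
    --roster inst/extdata/pilot_trial.csv --out pilot-out
# cycle 1: 30 enrolled (0 excluded by strategy, 0 blocked by gate)
# P-ledger: 30 Initial / 30 Before / 30 After in 91 blocks (valid: TRUE)
# T-ledger: 9 blocks (valid: TRUE)
# risk flags: 16 (P1,P3,P4,P8,P9,P10,P14,P15,P16,P17,P19,P23,P25,P26,P28); rules: 4; strategies: 4

Rscript inst/cli/qbdchain.R verify-ledger --ledger pilot-out/pledger.jsonl
# ledger valid
Rscript inst/cli/qbdchain.R tamper-demo --ledger pilot-out/pledger.jsonl --block 12
# tampered block 12 (timestamp): detected=TRUE at index 12; file unchanged=TRUE
```

(The 16 default-configuration flags cover all factors — borderline findings
on blood pressure, blood sugar and bedtime levels included — while the
heart-rate column carries the six participants shown above.)

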