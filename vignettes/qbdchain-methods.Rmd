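---
title: "Methods: ledger mechanics and safety analytics in qbdchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ledger mechanics and safety analytics in qbdchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qbdchain)
```

qbdchain simulates a permissioned dual-ledger blockchain carrying a
Plan–Do–Check–Act (PDCA) participant-safety pipeline for clinical trials.
This vignette explains the model, the parameters that matter, the numerical
choices, and the limits of what the simulation shows.

## The ledger model

A ledger is an ordered chain of blocks. Block *i* stores the SHA-256 digest
of its own canonical serialization (over `index`, `prev_hash`,
`transactions`, `timestamp`; the stored hash itself is excluded) and the
digest of block *i −* 1. Verification recomputes every hash and every link
and reports the smallest failing index; the package's tamper-evidence
property is that any single-field mutation of block *b* fails verification
at index ≤ *b* + 1 (at *b* when the content no longer matches its stored
hash, at *b* + 1 when only the stored hash itself was replaced, which breaks
the successor's link).

Canonical serialization is deliberately hand-specified rather than delegated
to a JSON library: objects with lexicographically sorted keys (C locale), no
whitespace, UTF-8 text, integers in decimal, and **no floating-point values
on-ledger** — measurements are carried as decimal strings. This makes block
hashes reproducible across platforms and makes read-back exact: a value
recorded as `"78"` is returned as `"78"`, never `78.000001`. Timestamps are
logical integer ticks from a per-ledger counter, not wall-clock times, so
repeated runs of the same inputs produce byte-identical ledger exports
(the regeneration test in `test-cli.R` checks exactly this).

Block size is configurable; the default packs one transaction per block,
which keeps the mapping from pipeline events to blocks easy to audit. The
world state is a left-to-right fold over all committed transactions
(last-write-wins per record key) and is recomputed from genesis on every
read; a ledger that fails verification refuses to serve reads, which makes
the immutability contract observable rather than merely asserted.

## The network model

The default network reproduces the reference deployment: one *single* peer
hosting the trial ledger, one *double* peer hosting both ledgers (and
acting as DC issuer), three *endorser* peers, one combined
*orderer/committer*, six certificate authorities (one per server group:
four PDCA phase servers plus two blockchain servers), and two channels
(channel-1 ↔ T-ledger, channel-2 ↔ P-ledger). Certificates are simulated
as keyed digests over (issuer secret, subject, serial): deterministic, and
any alteration of subject, serial or token fails validation. Real PKI,
consensus protocols, network transport and key revocation are out of scope;
all components run in one process behind direct calls.

Writes run the full propose → endorse → order → commit sequence.
"Chaincode" is realized as a per-channel validation function run by every
endorser (schema, storage class, and status-lifecycle checks for the
patient ledger); replacing it under a version tag stands in for the
chaincode upgrade lifecycle. The endorsement policy defaults to a strict
majority of the endorsers and is configurable to `all` or `k_of_n`. The
commit-iff-quorum property is exhaustively testable: with three endorsers
there are eight verdict combinations, and a commit occurs iff at least two
approve.

One design question had no self-consistent answer in the field's usual
informal descriptions: which pipeline units may touch which ledger. The
narrow reading (safe-domain identifier reads/writes the trial ledger;
pre-trial unit reads trial, writes patient; post-trial unit writes patient;
risk assessor reads both; root-cause analyzer reads patient) leaves the
enrollment unit unable to write `Initial` transactions and the trial-order
and root-cause units unable to read what they demonstrably consume. The
package's matrix (`api_permissions()`) therefore adds DC issuer → write
patient ledger (+ read trial ledger), trial order → read both, and
root-cause analyzer → read trial ledger; every triple outside the matrix is
rejected. Similarly, the pre-trial unit recalls the patient roster through
the trial-order unit's read path rather than holding patient-ledger read
permission itself.

Personal data never enters a transaction: PII lives in a LOCAL store and
the on-chain payload carries only the certificate serial, a SHA-256 pointer
to the LOCAL record, and the demographics the analytics need (sex, age,
weight). Alert-hook conditions must declare the payload fields they read
and may not name LOCAL-class fields.

## Safe domains and the age-band gap policy

Safe domains are intervals with optional age (and, in the data model, sex)
strata and per-bound inclusivity; domains phrased "less than *x*" carry an
exclusive upper bound. The heart-rate family has six age bands
(\<40, 41–45, 46–50, 51–55, 56–60, 61–65 years), which leaves age 40 and
ages above 65 uncovered while the pilot roster contains participants aged
40 and 66. The resolution policy makes lookups total and deterministic:
"\<40" means ≤ 39; an uncovered age maps to the nearest band by age
distance with ties resolved toward the older band (so 40 → the 41–45
band); ages above the top band clamp to it (66 → 61–65). Stay-in-bed
durations (F4) are modeled as `duration_minimum` states and default to
informational (not interval-checked): the pilot data contain many values
below the stated minimums that the trial evidently did not treat as
deviations, so checking them would misrepresent the source process. Heart
rate is stratified by age only; the measurement procedures differ by sex
but the domains do not, and the data model supports sex strata should a
protocol define them.

## Risk flags

The risk assessor reads post-administration values (a configuration switch
extends the scan to pre-administration values) and emits, per participant ×
factor, `out_of_range` when a bound is violated under its inclusivity, or
`borderline` when the value is in-domain but within `borderline_delta`
(default 1.0, in factor units) of a bound on the factor's harmful side.
Harm directions come from the protocol (heart rate: high; blood pressure:
both; …). Three numerical details matter:

- borderline distance is inclusive (`U − v ≤ δ`), so heart rate 152 against
  an upper bound of 153 is borderline at δ = 1;
- δ = 0 disables borderline flagging entirely rather than flagging values
  sitting exactly on a bound — a value on an inclusive bound is safe;
- with harm direction "high", a value on the lower bound (heart rate 80 on
  78–132) is not flagged.

On the pilot fixture the heart-rate column then flags P8, P10, P23, P25,
P28 out of range and P3 borderline. The flag set is monotone in δ, and the
scan is property-tested against a brute-force double loop over participants
× factors.

## Level categories and rule induction

The root-cause analyzer reduces pre-administration values to
low/normal/high per factor: out-of-range values take the violated side;
in-domain values take `high` if strictly within a margin of the upper bound
(`v > U − m`), `low` if strictly within a margin of the lower bound, else
`normal`. The margin is a fraction of the domain width (two-sided) or of
the bound (one-sided): 10% by default, 25% for heart rate, whose clinically
meaningful "low/high" band is wider relative to its domain. The strict
inequality is load-bearing: a fasting blood sugar of 90 against "\< 100"
with margin 10 sits exactly on the margin edge and must read `normal`,
while 98 and 99 read `high`.

Rule induction is a deterministic concretization of subgroup discovery at
cohort scale (tens to a few hundred participants):

1. categorize pre-levels for the full cohort;
2. partition flagged participants by sex;
3. grow candidate subgroups breadth-first by shared non-normal level
   conditions (depth ≤ 4), never the full powerset;
4. each subgroup yields the conjunction *sex ∧ age ∈ [a, b] ∧ shared
   levels*, with `[a, b]` the members' age range snapped outward to
   multiples of 5 years;
5. precision = flagged / matching over the whole cohort;
6. keep rules with support ≥ `min_support` (default 2) and precision ≥
   `min_precision` (default 1.0); order by precision, then support size,
   then lexicographic participant ids; drop rules whose support is
   contained in an earlier rule's.

The defaults suit the deterministic pilot analysis, where the two induced
rules reach precision 1. For noisy recovery experiments the threshold must
sit below the expected in-group flag rate: the shipped recovery study
injects members whose post-dose exceedance probability is 0.9, so rule
precision concentrates near 0.9 and the experiment runs with
`min_precision = 0.8` — a choice made from the generative model, not from
the data.

Strategies are the rules' conditions turned into exclusion predicates. They
are LOCAL artifacts; they reach the trial ledger only inside the next
cycle's committed safe-domain payloads, where enrollment evaluates them
against each candidate's demographics and pre-levels (level conditions
require screening pre-values; without them only a full demographic match
could be evaluated, and no exclusion is applied).

## The synthetic-data generator

`generate_cohort()` emulates the shape of the pilot data: integer
demographics, integer measurements, one row per participant with before and
after values for all eight factors. Values are drawn from a truncated
normal centered at the resolved domain midpoint with coefficient of
variation 0.10 (one-sided domains center 1.5 standard deviations inside the
bound), rounded and clamped into the integer-feasible part of the domain —
so with no injected pattern every value is in-domain by construction.
Injected unsafe subgroups fix a member's sex and age inside the rule's
window, draw the patterned pre-values uniformly from the exact level
region the categorizer will reproduce, and push the target factor's
post-dose value past the harmful bound with the stated probability (0.9
in-group, 0.02 baseline in the shipped experiments). All randomness flows
from one seed; outputs are byte-identical across platforms because only
integer arithmetic reaches the emitted files.

What the generator does *not* emulate: pharmacokinetics (no
dose–response), correlation between factors, longitudinal trends within
the observation window, measurement error models, or missing data. Passing
recovery tests therefore show that the analytics find planted structure of
the kind they were designed for at realistic cohort sizes — not that they
would find arbitrary real-world risk patterns.

## Problem sizes and determinism

The shipped studies use the sizes a desk-scale analysis warrants: the full
pilot cycle (30 participants, 91 patient-ledger blocks), 100 randomized
single-field tampers on 6-block chains, all 8 endorsement combinations, 50
random cohorts of n = 100 for the brute-force scan comparison, and 50
seeded cohorts of n = 200 for subgroup recovery. Every stochastic component
is seeded; the pilot cycle itself contains no randomness, and regenerating
its artifacts from the same inputs reproduces them byte-for-byte.

## Known limitations

- One authoritative chain per channel: no forks, Merkle trees, gossip, or
  Byzantine behavior — tamper evidence is demonstrated on copies, not on a
  distributed adversary model.
- Certificates are keyed digests, not asymmetric signatures; revocation is
  out of scope.
- Warn-mode gating is the default because the pilot data themselves contain
  pre-administration values outside the committed domains for five
  participants (e.g. P20's heart rate 149 against 80–145) while all thirty
  were evidently dosed; strict mode enforces the stated rule and blocks
  them. Neither mode infers why the source process proceeded.
- The pilot's asterisked source annotations are carried as notes and never
  computed on.
- Rule induction is greedy; it is exact for the pilot-scale flag sets it
  targets but is not a complete subgroup search, and it reports association,
  not cause.
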