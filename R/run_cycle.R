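#' Run one full Plan-Do-Check-Act cycle
#'
#' Wires the phases end to end on a fresh network: the plan units identify
#' the safety-critical factors, extract measurement procedures into the
#' LOCAL store, and commit the safe domains to the trial ledger; the do
#' units enroll the roster (screened against any prior-cycle control
#' strategies), build the trial order, and record the pre/post measurement
#' lifecycle on the patient ledger; the check units flag unsafe
#' post-administration values and induce root-cause rules; the act unit
#' develops the control strategies for the next cycle. Artifacts (ledger
#' exports, flag/rule reports, strategies, summary) are written under
#' `out_dir` when given.
#'
#' @param protocol_path Trial-protocol YAML.
#' @param roster_path Cohort CSV (see [read_cohort()]).
#' @param network_config_path Optional network YAML; default configuration
#'   otherwise.
#' @param gate_mode `"warn"` (default) or `"strict"` pre-administration
#'   gating.
#' @param cfg A [risk_rule_config()].
#' @param cycle Cycle number.
#' @param seed Integer seed (recorded in the summary; the cycle itself is
#'   deterministic).
#' @param out_dir Output directory for artifacts, created if needed.
#' @param prior_strategies Control strategies from the previous cycle.
#' @return List with `network`, `summary`, `flags`, `rules`, `strategies`,
#'   `blocked`, `reports`.
#' @export
run_cycle <- function(protocol_path, roster_path, network_config_path = NULL,
                      gate_mode = c("warn", "strict"),
                      cfg = risk_rule_config(), cycle = 1L, seed = 1L,
                      out_dir = NULL, prior_strategies = list()) {
  gate_mode <- match.arg(gate_mode)
  set.seed(as.integer(seed))
  protocol <- read_protocol(protocol_path)
  protocol$cycle <- as.integer(cycle)
  cohort <- read_cohort(roster_path)
  config <- if (is.null(network_config_path)) default_network_config()
            else read_network_config(network_config_path)
  network <- build_network(config)

  # Plan
  factors <- identify_csa(protocol)
  determine_measurements(protocol, factors, network)
  network$local_store$checkable <- checkable_ids(factors)
  network$local_store$harm_direction <- harm_directions(factors)
  identify_safe_domains(protocol, factors, prior = prior_strategies,
                        network = network)

  # Do
  enrolled <- enroll(network, cohort$roster, cycle = cycle,
                     screening = cohort$before, cfg = cfg)
  excluded <- attr(enrolled, "excluded")
  build_trial_order(network, cycle)
  blocked <- character(0)
  for (pid in names(enrolled)) {
    row <- which(cohort$before$participant_id == pid)
    vals <- as.list(cohort$before[row, COHORT_FACTORS])
    rep <- record_pre(network, pid, vals, mode = gate_mode, cycle = cycle)
    if (rep$blocked) {
      blocked <- c(blocked, pid)
      next
    }
    row <- which(cohort$after$participant_id == pid)
    record_post(network, pid, as.list(cohort$after[row, COHORT_FACTORS]),
                cycle = cycle)
  }

  # Check
  flags <- assess_risk(network, cycle, cfg)
  rules <- analyze_root_cause(network, flags, cycle, cfg)

  # Act
  strategies <- develop_strategies(rules, next_cycle = cycle + 1L,
                                   network = network)

  tl <- network_ledger(network, "T-ledger")
  pl <- network_ledger(network, "P-ledger")
  state <- replay_state(pl)
  n_status <- function(st) {
    sum(vapply(state$entries, function(p) {
      identical(p$type, "patient_tx") && identical(p$status, st) &&
        identical(as.integer(p$cycle), as.integer(cycle))
    }, logical(1)))
  }
  summary <- list(
    cycle = as.integer(cycle),
    seed = as.integer(seed),
    gate_mode = gate_mode,
    n_factors = length(factors),
    n_subjective_groups = length(unique(vapply(
      Filter(function(f) identical(f$kind, "subjective"), factors),
      `[[`, character(1), "group"))),
    n_objective_groups = length(unique(vapply(
      Filter(function(f) identical(f$kind, "objective"), factors),
      `[[`, character(1), "group"))),
    enrolled = length(enrolled),
    excluded_by_strategy = length(excluded),
    blocked_by_gate = length(blocked),
    tx_initial = n_status("Initial"),
    tx_before = n_status("Before"),
    tx_after = n_status("After"),
    tledger_blocks = length(tl$chain),
    pledger_blocks = length(pl$chain),
    tledger_valid = verify_chain(tl)$valid,
    pledger_valid = verify_chain(pl)$valid,
    n_flags = nrow(flags),
    flagged_ids = attr(flags, "flagged_ids"),
    n_rules = length(rules),
    n_strategies = length(strategies)
  )

  reports <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    reports$tledger <- export_ledger(tl, file.path(out_dir, "tledger.jsonl"))
    reports$pledger <- export_ledger(pl, file.path(out_dir, "pledger.jsonl"))
    reports$flags_csv <- write_flag_report(flags, file.path(out_dir, "flags.csv"))
    reports$flags_json <- write_flag_report(flags, file.path(out_dir, "flags.json"))
    reports$rules_json <- write_rule_report(rules, file.path(out_dir, "rules.json"))
    reports$rules_csv <- write_rule_report(rules, file.path(out_dir, "rules.csv"))
    jsonlite::write_json(lapply(strategies, function(s) list(
      strategy_id = s$strategy_id, action = s$action,
      conditions = list(sex = s$conditions$sex,
                        age_min = s$conditions$age_min,
                        age_max = s$conditions$age_max,
                        levels = as.list(s$conditions$levels)),
      target_cycle = s$target_cycle
    )), file.path(out_dir, "strategies.json"), auto_unbox = TRUE, digits = NA)
    reports$strategies <- file.path(out_dir, "strategies.json")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    reports$summary <- file.path(out_dir, "summary.json")
    log_df <- network_log(network)
    utils::write.csv(log_df, file.path(out_dir, "lifecycle_log.csv"),
                     row.names = FALSE)
    reports$log <- file.path(out_dir, "lifecycle_log.csv")
  }

  list(network = network, summary = summary, flags = flags, rules = rules,
       strategies = strategies, blocked = blocked, excluded = excluded,
       reports = reports)
}

#' Verify an exported ledger file
#'
#' @param path JSON-lines ledger export.
#' @return The [verify_chain()] report.
#' @export
verify_ledger_file <- function(path) {
  verify_chain(import_ledger(path))
}

#' Demonstrate tamper evidence on an exported ledger
#'
#' Imports the export, mutates one field of the chosen block in memory
#' (never touching the file), re-verifies, and reports the detection trace.
#'
#' @param path JSON-lines ledger export.
#' @param block_index Block to tamper with.
#' @param field_path Field to mutate (default the block timestamp).
#' @param new_value Replacement value.
#' @return List with `tampered_index`, `detected`, `first_invalid_index`,
#'   and `file_unchanged` (always `TRUE`: the demo is read-only).
#' @export
tamper_demo <- function(path, block_index, field_path = "timestamp",
                        new_value = 999999L) {
  before_hash <- file_sha256(path)
  lg <- import_ledger(path)
  if (block_index < 0 || block_index >= length(lg$chain)) {
    qbd_stop("qbd_validation_error", "block index %d out of range", block_index)
  }
  tampered <- tamper_ledger(lg, block_index, field_path, new_value)
  rep <- verify_chain(tampered)
  after_hash <- file_sha256(path)
  list(
    tampered_index = as.integer(block_index),
    field_path = field_path,
    detected = !rep$valid,
    first_invalid_index = rep$first_invalid_index,
    file_unchanged = identical(before_hash, after_hash)
  )
}
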