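#' Conduct units: enrollment, trial order, pre/post recording
#'
#' The Do phase issues participant identity certificates (DCI), keeps all
#' personally identifiable information in the LOCAL store with only a digest
#' pointer on-chain, and writes the Initial -> Before -> After lifecycle to
#' the patient ledger. Pre-administration values are gated against the
#' committed safe domains: `strict` mode blocks out-of-domain participants,
#' `warn` mode (default) records the deviations in the Before payload and
#' proceeds.
#'
#' @name do_phase
NULL

participant_key <- function(pid, status, cycle) {
  sprintf("%s#%s#c%d", pid, status, as.integer(cycle))
}

# Latest patient payload for (pid, status, cycle), or NULL. Reads through
# the trial-order unit, which holds patient-ledger read permission.
patient_entry <- function(network, pid, status, cycle, unit = "TO") {
  hits <- query_ledger(network, unit, "channel-2", function(p) {
    identical(p$type, "patient_tx") &&
      identical(p$participant_id, pid) &&
      identical(p$status, status) &&
      identical(as.integer(p$cycle), as.integer(cycle))
  })
  if (length(hits)) hits[[1]] else NULL
}

#' Enroll a participant roster
#'
#' Per participant: a digital certificate is issued by the DC issuer's
#' certificate authority, personal information is stored in the LOCAL store
#' only, and one Initial transaction is committed to the patient ledger
#' carrying the demographics, all factor values as `"N/A"`, the certificate
#' serial, and a digest pointer to the LOCAL record. Requires the current
#' cycle's safe domains on the trial ledger. When the committed domains
#' carry prior-cycle control strategies and `screening` pre-values are
#' supplied, matching roster members are excluded before enrollment.
#'
#' @param network A `qbd_network`.
#' @param roster data.frame with columns `participant_id`, `sex`, `age`,
#'   `weight` (additional columns are treated as LOCAL personal data).
#' @param cycle Trial cycle.
#' @param screening Optional data.frame of pre-administration values
#'   (`participant_id` + factor columns) used to evaluate strategy
#'   eligibility predicates at enrollment time.
#' @param cfg Risk configuration (margins used for strategy level
#'   predicates); default [risk_rule_config()].
#' @return List with one element per enrolled participant:
#'   `list(certificate, payload)`. Excluded participant ids are in
#'   `attr(, "excluded")`.
#' @export
enroll <- function(network, roster, cycle = 1L, screening = NULL,
                   cfg = risk_rule_config()) {
  if (anyDuplicated(roster$participant_id)) {
    qbd_stop("qbd_validation_error", "duplicate participant ids in roster")
  }
  dom_payloads <- query_ledger(network, "DCI", "channel-1", function(p) {
    identical(p$type, "safe_domain") &&
      identical(as.integer(p$cycle), as.integer(cycle))
  })
  if (length(dom_payloads) == 0L) {
    qbd_stop("qbd_sequencing_error",
             "no safe domains on the T-ledger for cycle %d; run the plan phase first",
             cycle)
  }
  domains <- domains_from_payloads(dom_payloads)
  strategies <- strategies_from_payloads(dom_payloads)
  factor_set <- sort(names(domains))

  excluded <- character()
  if (length(strategies) && !is.null(screening)) {
    levels <- level_categories(merge_cohort(roster, screening), domains, cfg)
    for (i in seq_len(nrow(roster))) {
      pid <- roster$participant_id[i]
      for (s in strategies) {
        if (strategy_matches(s, roster$sex[i], roster$age[i], levels[[pid]])) {
          excluded <- c(excluded, pid)
          break
        }
      }
    }
  }

  dc_peer <- NULL
  for (pid in ls(network$peers)) {
    pe <- get(pid, envir = network$peers)
    if ("dc_issuer" %in% pe$roles) { dc_peer <- pe; break }
  }
  if (is.null(dc_peer)) {
    qbd_stop("qbd_validation_error", "network has no DC issuer peer")
  }
  ca_id <- paste0("ca-", dc_peer$server)

  out <- list()
  for (i in seq_len(nrow(roster))) {
    pid <- roster$participant_id[i]
    if (pid %in% excluded) next
    if (!is.null(patient_entry(network, pid, "Initial", cycle))) {
      qbd_stop("qbd_lifecycle_error",
               "participant %s already enrolled in cycle %d", pid, cycle)
    }
    cert <- issue_certificate(network, ca_id, pid)
    extra <- setdiff(names(roster), c("participant_id", "sex", "age", "weight"))
    pii <- c(list(participant_id = pid), as.list(roster[i, extra, drop = FALSE]))
    network$local_store$pii[[pid]] <- pii
    pii_pointer <- sha256_hex(canonical_serialize(pii))
    values <- stats::setNames(as.list(rep("N/A", length(factor_set))), factor_set)
    payload <- list(
      type = "patient_tx",
      storage_class = "P_LEDGER",
      record_key = participant_key(pid, "Initial", cycle),
      participant_id = pid,
      status = "Initial",
      cycle = as.integer(cycle),
      sex = roster$sex[i],
      age = as.integer(roster$age[i]),
      weight = dec_str(roster$weight[i]),
      values = values,
      cert_serial = cert$serial,
      pii_pointer = pii_pointer
    )
    tx <- new_transaction(sprintf("tx-dci-%s-c%d", pid, cycle), "channel-2",
                          payload, proposer_id = dc_peer$peer_id,
                          cert_ref = cert$serial)
    res <- submit_transaction(network, "DCI", list(tx))
    if (!res$committed) {
      qbd_stop("qbd_validation_error", "enrollment of %s rejected: %s",
               pid, res$reason_code)
    }
    out[[pid]] <- list(certificate = cert, payload = payload)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Build the trial order for a cycle
#'
#' Reads the Initial-status participants from the patient ledger, the
#' committed safe domains from the trial ledger, and the measurement
#' procedures from the LOCAL store, and assembles the conduct order handed
#' to the research organization. Stored LOCAL; no ledger write.
#'
#' @param network A `qbd_network`.
#' @param cycle Trial cycle.
#' @return A `trial_order` list.
#' @export
build_trial_order <- function(network, cycle = 1L) {
  initial <- query_ledger(network, "TO", "channel-2", function(p) {
    identical(p$type, "patient_tx") && identical(p$status, "Initial") &&
      identical(as.integer(p$cycle), as.integer(cycle))
  })
  if (length(initial) == 0L) {
    qbd_stop("qbd_sequencing_error",
             "no Initial transactions for cycle %d; enroll first", cycle)
  }
  roster <- do.call(rbind, lapply(initial, function(p) {
    data.frame(participant_id = p$participant_id, sex = p$sex,
               age = as.integer(p$age), weight = p$weight,
               stringsAsFactors = FALSE)
  }))
  roster <- roster[order_participants(roster$participant_id), , drop = FALSE]
  rownames(roster) <- NULL
  domains <- read_domains(network, cycle, api_unit = "TO")
  order <- structure(list(
    cycle = as.integer(cycle),
    roster = roster,
    procedures = network$local_store$procedures,
    domains_snapshot = domains,
    instructions = sprintf(
      "Conduct cycle %d for %d participants per the attached procedures; keep all factors within their committed safe domains.",
      cycle, nrow(roster))
  ), class = "trial_order")
  network$local_store$trial_orders[[as.character(cycle)]] <- order
  order
}

# P1, P2, ..., P10 natural ordering used in reports.
order_participants <- function(ids) {
  num <- suppressWarnings(as.integer(sub("^P", "", ids)))
  if (anyNA(num)) order(ids) else order(num)
}

#' Record pre-administration values with eligibility gating
#'
#' Values must cover every checkable factor. Eligibility is evaluated per
#' factor against the before-phase safe domain. In `strict` mode an
#' out-of-domain participant is blocked and no Before transaction is
#' written; in `warn` mode the Before transaction is committed with the
#' deviations embedded in its payload.
#'
#' @param network A `qbd_network`.
#' @param participant_id Enrolled participant code.
#' @param values Named list/vector of factor values (decimal strings or
#'   numerics).
#' @param mode `"warn"` (default) or `"strict"`.
#' @param cycle Trial cycle.
#' @return Eligibility report: list(participant_id, blocked, deviations,
#'   payload or NULL).
#' @export
record_pre <- function(network, participant_id, values,
                       mode = c("warn", "strict"), cycle = 1L) {
  mode <- match.arg(mode)
  initial <- patient_entry(network, participant_id, "Initial", cycle)
  if (is.null(initial)) {
    qbd_stop("qbd_lifecycle_error",
             "participant %s has no Initial transaction in cycle %d",
             participant_id, cycle)
  }
  if (!is.null(patient_entry(network, participant_id, "Before", cycle))) {
    qbd_stop("qbd_lifecycle_error",
             "participant %s already has a Before transaction", participant_id)
  }
  values <- as.list(values)
  domains <- read_domains(network, cycle, api_unit = "PrT")
  checkable <- checkable_domain_ids(network, domains)
  missing <- setdiff(checkable, names(values))
  if (length(missing)) {
    qbd_stop("qbd_validation_error", "missing factor value(s): %s",
             paste(missing, collapse = ", "))
  }
  deviations <- list()
  for (fid in checkable) {
    band <- lookup_domain(domains, fid, initial$sex, as.integer(initial$age),
                          phase = "before")
    v <- as.numeric(values[[fid]])
    ok <- in_domain(v, band)
    if (!isTRUE(ok)) {
      deviations[[length(deviations) + 1L]] <- list(
        factor_id = fid, observed = dec_str(values[[fid]]),
        direction = attr(ok, "direction"),
        lower = if (is.null(band$lower)) "" else dec_str(band$lower),
        upper = if (is.null(band$upper)) "" else dec_str(band$upper)
      )
    }
  }
  if (mode == "strict" && length(deviations)) {
    network_log_append(network, "gate", unit = "PrT",
                       detail = sprintf("blocked %s (%d deviation(s))",
                                        participant_id, length(deviations)))
    return(list(participant_id = participant_id, blocked = TRUE,
                deviations = deviations, payload = NULL))
  }
  payload <- list(
    type = "patient_tx",
    storage_class = "P_LEDGER",
    record_key = participant_key(participant_id, "Before", cycle),
    participant_id = participant_id,
    status = "Before",
    cycle = as.integer(cycle),
    sex = initial$sex,
    age = as.integer(initial$age),
    weight = initial$weight,
    values = lapply(values, dec_str),
    cert_serial = initial$cert_serial,
    pii_pointer = initial$pii_pointer,
    deviations = deviations
  )
  tx <- new_transaction(sprintf("tx-prt-%s-c%d", participant_id, cycle),
                        "channel-2", payload,
                        proposer_id = network$units[["PrT"]])
  res <- submit_transaction(network, "PrT", list(tx))
  if (!res$committed) {
    qbd_stop("qbd_validation_error", "Before commit for %s rejected: %s",
             participant_id, res$reason_code)
  }
  list(participant_id = participant_id, blocked = FALSE,
       deviations = deviations, payload = payload)
}

# The checkable factor set is shared by the plan phase through the LOCAL
# store; interval-state families are the fallback.
checkable_domain_ids <- function(network, domains) {
  ck <- network$local_store$checkable
  if (!is.null(ck)) return(intersect(sort(names(domains)), ck))
  sort(names(Filter(function(f) identical(f$state_kind, "interval"), domains)))
}

#' Record post-administration values
#'
#' Requires an existing Before transaction and no prior After transaction in
#' the cycle.
#'
#' @inheritParams record_pre
#' @return The committed After payload.
#' @export
record_post <- function(network, participant_id, values, cycle = 1L) {
  before <- patient_entry(network, participant_id, "Before", cycle)
  if (is.null(before)) {
    qbd_stop("qbd_lifecycle_error",
             "participant %s has no Before transaction in cycle %d",
             participant_id, cycle)
  }
  if (!is.null(patient_entry(network, participant_id, "After", cycle))) {
    qbd_stop("qbd_lifecycle_error",
             "participant %s already has an After transaction", participant_id)
  }
  values <- as.list(values)
  domains <- read_domains(network, cycle, api_unit = "PrT")
  checkable <- checkable_domain_ids(network, domains)
  missing <- setdiff(checkable, names(values))
  if (length(missing)) {
    qbd_stop("qbd_validation_error", "missing factor value(s): %s",
             paste(missing, collapse = ", "))
  }
  payload <- list(
    type = "patient_tx",
    storage_class = "P_LEDGER",
    record_key = participant_key(participant_id, "After", cycle),
    participant_id = participant_id,
    status = "After",
    cycle = as.integer(cycle),
    sex = before$sex,
    age = as.integer(before$age),
    weight = before$weight,
    values = lapply(values, dec_str),
    cert_serial = before$cert_serial,
    pii_pointer = before$pii_pointer
  )
  tx <- new_transaction(sprintf("tx-pot-%s-c%d", participant_id, cycle),
                        "channel-2", payload,
                        proposer_id = network$units[["PoT"]])
  res <- submit_transaction(network, "PoT", list(tx))
  if (!res$committed) {
    qbd_stop("qbd_validation_error", "After commit for %s rejected: %s",
             participant_id, res$reason_code)
  }
  payload
}

#' Full patient-ledger history of a participant
#'
#' @param network A `qbd_network`.
#' @param participant_id Participant code.
#' @return List of payloads in commit order (statuses appear in lifecycle
#'   order).
#' @export
get_participant_history <- function(network, participant_id) {
  hist <- query_history(network, "RCA", "channel-2", function(p) {
    identical(p$type, "patient_tx") &&
      identical(p$participant_id, participant_id)
  })
  if (length(hist) == 0L) {
    qbd_stop("qbd_validation_error", "unknown participant '%s'", participant_id)
  }
  hist
}
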