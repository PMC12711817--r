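#' Planning units: factor identification, measurement procedures, safe domains
#'
#' The Plan phase screens the structured trial protocol for the factors that
#' drive critical safety attributes (CSAI), extracts their measurement
#' procedures into the local store (MPD — never on-ledger), and commits the
#' stratified safe domains/states to the trial ledger (SDI), carrying any
#' safety control strategies from the previous cycle as eligibility
#' predicates.
#'
#' @name plan_phase
NULL

#' Read a trial protocol from YAML
#'
#' Expected keys: `protocol_id`, `cycle`, `factors[]` (id, group, name, kind,
#' unit, safety_critical, harm_direction, checkable), `procedures[]`
#' (factor, schedule, constraints, phase), `domains[]` (factor, phase,
#' state_kind, bands[] with optional sex/age strata and bounds), and
#' free-text `sponsor_meta` (LOCAL storage class).
#'
#' @param path YAML file path.
#' @return A `trial_protocol` list.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) {
    qbd_stop("qbd_parse_error", "protocol file '%s' does not exist", path)
  }
  p <- yaml::yaml.load_file(path)
  ids <- vapply(p$factors, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    qbd_stop("qbd_validation_error", "duplicate factor ids in protocol")
  }
  p$cycle <- as.integer(p$cycle %||% 1L)
  structure(p, class = "trial_protocol")
}

#' Identify the critical-safety factors of a protocol
#'
#' Returns exactly the factor entries flagged `safety_critical`, in protocol
#' order.
#'
#' @param protocol A `trial_protocol`.
#' @return List of factor specs.
#' @export
identify_csa <- function(protocol) {
  ids <- vapply(protocol$factors, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    qbd_stop("qbd_validation_error", "duplicate factor ids in protocol")
  }
  Filter(function(f) isTRUE(f$safety_critical), protocol$factors)
}

factor_ids <- function(factors) vapply(factors, `[[`, character(1), "id")

# Checkable factors participate in interval checking and level
# categorization; duration-minimum factors default to informational.
checkable_ids <- function(factors) {
  factor_ids(Filter(function(f) isTRUE(f$checkable), factors))
}

harm_directions <- function(factors) {
  hd <- vapply(factors, function(f) f$harm_direction %||% "both", character(1))
  names(hd) <- factor_ids(factors)
  hd
}

#' Extract measurement procedures for the selected factors
#'
#' One procedure set per factor, persisted to the network's LOCAL store when
#' a network is given, and shared with the Do phase. Procedures never touch
#' a ledger.
#'
#' @param protocol A `trial_protocol`.
#' @param factors Factor specs (subset of the protocol's).
#' @param network Optional `qbd_network` whose local store receives the
#'   procedures.
#' @return Named list factor id -> list of procedure entries.
#' @export
determine_measurements <- function(protocol, factors, network = NULL) {
  want <- factor_ids(factors)
  have <- vapply(protocol$procedures, `[[`, character(1), "factor")
  out <- list()
  for (fid in want) {
    entries <- protocol$procedures[have == fid]
    if (length(entries) == 0L) {
      qbd_stop("qbd_validation_error",
               "factor %s has no measurement procedure in the protocol", fid)
    }
    out[[fid]] <- entries
  }
  if (!is.null(network)) {
    network$local_store$procedures <- out
  }
  out
}

# ---- safe domains -----------------------------------------------------------

norm_band <- function(b, family_phase) {
  lower <- if (!is.null(b$lower)) as.numeric(b$lower) else NULL
  upper <- if (!is.null(b$upper)) as.numeric(b$upper) else NULL
  if (!is.null(lower) && !is.null(upper) && lower > upper) {
    qbd_stop("qbd_validation_error", "domain band with lower > upper")
  }
  list(
    sex = b$sex %||% NULL,
    age_min = if (!is.null(b$age_min)) as.integer(b$age_min) else NULL,
    age_max = if (!is.null(b$age_max)) as.integer(b$age_max) else NULL,
    lower = lower, upper = upper,
    lower_inclusive = b$lower_inclusive %||% TRUE,
    upper_inclusive = b$upper_inclusive %||% TRUE,
    phase = b$phase %||% family_phase
  )
}

#' Build a safe-domain set from a protocol
#'
#' @param protocol A `trial_protocol`.
#' @return A `safe_domain_set`: named list factor id -> family with bands.
#' @export
domains_from_protocol <- function(protocol) {
  out <- list()
  for (d in protocol$domains) {
    fam_phase <- d$phase %||% "any"
    out[[d$factor]] <- list(
      factor_id = d$factor,
      phase = fam_phase,
      state_kind = d$state_kind %||% "interval",
      bands = lapply(d$bands, norm_band, family_phase = fam_phase)
    )
  }
  structure(out, class = "safe_domain_set")
}

#' Commit safe domains to the trial ledger
#'
#' One T-ledger transaction per domain family (or a single batched block
#' with `batch = TRUE`). Prior-cycle safety control strategies are attached
#' to every committed payload as eligibility predicates; re-running in a
#' later cycle appends updated domain payloads under new record keys rather
#' than mutating old ones.
#'
#' @param protocol A `trial_protocol`.
#' @param factors The safety-critical factor specs.
#' @param prior List of prior-cycle `control_strategy` objects (empty on
#'   cycle 1).
#' @param network A `qbd_network`.
#' @param batch Commit all families in one block.
#' @return Invisibly, the list of committed safe-domain payloads.
#' @export
identify_safe_domains <- function(protocol, factors, prior = list(),
                                  network, batch = FALSE) {
  domains <- domains_from_protocol(protocol)
  cyc <- protocol$cycle
  strategies <- lapply(prior, function(s) list(
    strategy_id = s$strategy_id, action = s$action,
    sex = s$conditions$sex %||% "",
    age_min = as.integer(s$conditions$age_min),
    age_max = as.integer(s$conditions$age_max),
    levels = as.list(s$conditions$levels)
  ))
  proposals <- list()
  for (fid in names(domains)) {
    fam <- domains[[fid]]
    bands <- lapply(fam$bands, function(b) {
      out <- list(
        lower = if (is.null(b$lower)) "" else dec_str(b$lower),
        upper = if (is.null(b$upper)) "" else dec_str(b$upper),
        lower_inclusive = b$lower_inclusive,
        upper_inclusive = b$upper_inclusive,
        phase = b$phase
      )
      if (!is.null(b$sex)) out$sex <- b$sex
      if (!is.null(b$age_min)) out$age_min <- b$age_min
      if (!is.null(b$age_max)) out$age_max <- b$age_max
      out
    })
    payload <- list(
      type = "safe_domain",
      storage_class = "T_LEDGER",
      record_key = sprintf("domain#%s#c%d", fid, cyc),
      factor_id = fid,
      phase = fam$phase,
      state_kind = fam$state_kind,
      cycle = cyc,
      bands = bands,
      strategies = strategies
    )
    tx <- new_transaction(
      tx_id = sprintf("tx-sdi-%s-c%d", fid, cyc),
      channel_id = "channel-1", payload = payload,
      proposer_id = network$units[["SDI"]],
      cert_ref = get(network$units[["SDI"]], envir = network$peers)$cert$serial
    )
    proposals <- c(proposals, list(tx))
  }
  if (batch) {
    res <- submit_transaction(network, "SDI", proposals)
    if (!res$committed) {
      qbd_stop("qbd_validation_error", "safe-domain commit rejected: %s",
               res$reason_code)
    }
  } else {
    for (tx in proposals) {
      res <- submit_transaction(network, "SDI", list(tx))
      if (!res$committed) {
        qbd_stop("qbd_validation_error", "safe-domain commit rejected: %s",
                 res$reason_code)
      }
    }
  }
  invisible(lapply(proposals, function(tx) tx$payload))
}

#' Rebuild a safe-domain set from committed T-ledger payloads
#'
#' @param payloads Safe-domain payloads as returned by a ledger query.
#' @return A `safe_domain_set`.
#' @export
domains_from_payloads <- function(payloads) {
  out <- list()
  for (p in payloads) {
    if (!identical(p$type, "safe_domain")) next
    out[[p$factor_id]] <- list(
      factor_id = p$factor_id,
      phase = p$phase,
      state_kind = p$state_kind,
      bands = lapply(p$bands, function(b) list(
        sex = b$sex %||% NULL,
        age_min = if (!is.null(b$age_min)) as.integer(b$age_min) else NULL,
        age_max = if (!is.null(b$age_max)) as.integer(b$age_max) else NULL,
        lower = if (is.null(b$lower) || !nzchar(b$lower)) NULL else as.numeric(b$lower),
        upper = if (is.null(b$upper) || !nzchar(b$upper)) NULL else as.numeric(b$upper),
        lower_inclusive = isTRUE(b$lower_inclusive),
        upper_inclusive = isTRUE(b$upper_inclusive),
        phase = b$phase
      ))
    )
  }
  structure(out, class = "safe_domain_set")
}

#' Read the committed safe domains for a cycle through a unit's API
#'
#' @param network A `qbd_network`.
#' @param cycle Cycle number.
#' @param api_unit Unit performing the read (must hold T-ledger read
#'   permission).
#' @return A `safe_domain_set`.
#' @export
read_domains <- function(network, cycle = 1L, api_unit = "RA") {
  payloads <- query_ledger(network, api_unit, "channel-1", function(p) {
    identical(p$type, "safe_domain") && identical(as.integer(p$cycle),
                                                  as.integer(cycle))
  })
  if (length(payloads) == 0L) {
    qbd_stop("qbd_sequencing_error",
             "no safe domains committed for cycle %d", cycle)
  }
  domains_from_payloads(payloads)
}

#' Resolve the safe domain for one factor and participant
#'
#' Strata are resolved by sex and age. Ages not covered by any stratum map
#' to the nearest band by age distance, ties resolved toward the older band,
#' and ages above the top band clamp to it — so lookups are total over the
#' adult age range. A band stated as "less than" carries an exclusive upper
#' bound.
#'
#' @param domains A `safe_domain_set`.
#' @param factor_id Factor code, e.g. `"F2"`.
#' @param sex `"M"` or `"F"` (used only by sex-stratified families).
#' @param age Integer years.
#' @param phase `"before"`, `"after"`, or `"any"`.
#' @return The resolved band: list with `lower`, `upper`,
#'   `lower_inclusive`, `upper_inclusive`, `state_kind`.
#' @export
lookup_domain <- function(domains, factor_id, sex, age, phase = "any") {
  fam <- domains[[factor_id]]
  if (is.null(fam)) {
    qbd_stop("qbd_validation_error", "no safe-domain family for %s", factor_id)
  }
  cand <- Filter(function(b) {
    ph_ok <- identical(b$phase, "any") || identical(phase, "any") ||
      identical(b$phase, phase)
    sex_ok <- is.null(b$sex) || identical(b$sex, sex)
    ph_ok && sex_ok
  }, fam$bands)
  if (length(cand) == 0L) {
    qbd_stop("qbd_validation_error",
             "no band of %s applies to phase %s", factor_id, phase)
  }
  strat <- Filter(function(b) !is.null(b$age_min) || !is.null(b$age_max), cand)
  unstrat <- Filter(function(b) is.null(b$age_min) && is.null(b$age_max), cand)
  pick <- NULL
  if (length(strat)) {
    inside <- Filter(function(b) {
      (is.null(b$age_min) || age >= b$age_min) &&
        (is.null(b$age_max) || age <= b$age_max)
    }, strat)
    if (length(inside)) {
      pick <- inside[[1]]
    } else {
      # gap policy: nearest band by age distance; ties toward the older band
      dist <- vapply(strat, function(b) {
        lo <- b$age_min %||% -Inf
        hi <- b$age_max %||% Inf
        if (age < lo) lo - age else if (age > hi) age - hi else 0
      }, numeric(1))
      lo_key <- vapply(strat, function(b) b$age_min %||% -Inf, numeric(1))
      best <- which(dist == min(dist))
      pick <- strat[[best[which.max(lo_key[best])]]]
    }
  } else if (length(unstrat)) {
    pick <- unstrat[[1]]
  }
  if (is.null(pick)) {
    qbd_stop("qbd_validation_error",
             "no band of %s resolves for sex=%s age=%d", factor_id, sex, age)
  }
  c(pick, list(state_kind = fam$state_kind))
}

#' Is a value inside its resolved safe domain?
#'
#' @param value Numeric measurement.
#' @param band A resolved band from [lookup_domain()].
#' @return `TRUE`/`FALSE`; the attribute `"direction"` on `FALSE` says which
#'   bound was violated (`"low"` or `"high"`).
#' @export
in_domain <- function(value, band) {
  if (!is.null(band$lower)) {
    low_ok <- if (isTRUE(band$lower_inclusive)) value >= band$lower
              else value > band$lower
    if (!low_ok) return(structure(FALSE, direction = "low"))
  }
  if (!is.null(band$upper)) {
    up_ok <- if (isTRUE(band$upper_inclusive)) value <= band$upper
             else value < band$upper
    if (!up_ok) return(structure(FALSE, direction = "high"))
  }
  TRUE
}

# Decimal-string formatting used for on-ledger measurement values.
dec_str <- function(x) {
  if (is.character(x)) {
    if (!all(grepl("^-?[0-9]+(\\.[0-9]+)?$", x) | x == "N/A")) {
      qbd_stop("qbd_validation_error", "malformed decimal string '%s'", x)
    }
    return(x)
  }
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}
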