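#' Permissioned network simulation
#'
#' In-process simulation of the permissioned blockchain supporting the
#' trial pipeline: peers with roles (single, double, DC issuer, endorser,
#' orderer, committer), six certificate authorities, two channels (channel-1
#' carries the trial ledger, channel-2 the patient ledger), and the full
#' propose -> endorse -> order -> commit and query sequences. All components
#' run in one process behind direct calls; there is exactly one authoritative
#' chain per channel.
#'
#' @name network_sim
NULL

PEER_ROLES <- c("single", "double", "dc_issuer", "endorser", "orderer", "committer")

# Payload field names that belong to the LOCAL storage class and must never
# appear on-ledger nor be referenced by alert-hook conditions.
LOCAL_FIELDS <- c("pii", "full_name", "address", "contact", "phone",
                  "sponsor_meta", "procedures", "schedule")

#' Default network configuration
#'
#' Reproduces the reference deployment: one single peer (trial ledger), one
#' double peer (both ledgers, also the DC issuer), three endorser peers, one
#' combined orderer/committer peer, six certificate authorities (one per
#' server group), and two channels. Peers are grouped onto six servers: four
#' PDCA phase servers plus two blockchain servers.
#'
#' @param policy Endorsement policy: list with `rule` in
#'   `c("majority", "all", "k_of_n")` and, for `k_of_n`, an integer `k`.
#' @param batch_size Number of transactions packed per block (default 1).
#' @return A network configuration list accepted by [build_network()].
#' @export
default_network_config <- function(policy = list(rule = "majority", k = NULL),
                                   batch_size = 1L) {
  servers <- c("plan", "do", "check", "act", "blockchain-1", "blockchain-2")
  list(
    channels = list(
      list(name = "channel-1", ledger_kind = "T-ledger"),
      list(name = "channel-2", ledger_kind = "P-ledger")
    ),
    peers = list(
      list(peer_id = "peer-plan-single", roles = "single",
           channels = "channel-1", hosted_ledgers = "T-ledger", server = "plan"),
      list(peer_id = "peer-do-double", roles = c("double", "dc_issuer"),
           channels = c("channel-1", "channel-2"),
           hosted_ledgers = c("T-ledger", "P-ledger"), server = "do"),
      list(peer_id = "peer-endorser-1", roles = c("endorser", "committer"),
           channels = c("channel-1", "channel-2"), hosted_ledgers = character(),
           server = "blockchain-1"),
      list(peer_id = "peer-endorser-2", roles = c("endorser", "committer"),
           channels = c("channel-1", "channel-2"), hosted_ledgers = character(),
           server = "blockchain-1"),
      list(peer_id = "peer-endorser-3", roles = c("endorser", "committer"),
           channels = c("channel-1", "channel-2"), hosted_ledgers = character(),
           server = "blockchain-2"),
      list(peer_id = "peer-orderer", roles = c("orderer", "committer"),
           channels = c("channel-1", "channel-2"), hosted_ledgers = character(),
           server = "blockchain-2")
    ),
    cas = lapply(servers, function(s) list(ca_id = paste0("ca-", s), server = s)),
    servers = servers,
    policy = policy,
    batch_size = as.integer(batch_size),
    # unit -> peer wiring for the pipeline APIs
    units = list(
      SDI = "peer-plan-single",
      DCI = "peer-do-double", TO = "peer-do-double",
      PrT = "peer-do-double", PoT = "peer-do-double",
      RA = "peer-do-double", RCA = "peer-do-double"
    )
  )
}

#' Read a network configuration from YAML
#'
#' Accepts the same keys as [default_network_config()] output: `peers[]`,
#' `cas[]`, `channels[]`, `policy{rule,k}`, `servers[]`, `units{}`.
#'
#' @param path YAML file path.
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) {
    qbd_stop("qbd_parse_error", "network config '%s' does not exist", path)
  }
  cfg <- yaml::yaml.load_file(path)
  base <- default_network_config()
  for (k in names(base)) if (is.null(cfg[[k]])) cfg[[k]] <- base[[k]]
  cfg$batch_size <- as.integer(cfg$batch_size)
  cfg
}

#' The API permission matrix
#'
#' Which pipeline unit may read or write which ledger. The safe-domain
#' identifier (SDI) reads and writes the trial ledger; the pre-trial unit
#' (PrT) reads the trial ledger and writes the patient ledger; the post-trial
#' unit (PoT) writes the patient ledger; the risk assessor (RA) reads both;
#' the DC issuer (DCI) reads the trial ledger and writes enrollment
#' transactions to the patient ledger; the trial-order unit (TO) reads both;
#' the root-cause analyzer (RCA) reads the patient ledger and the safe
#' domains on the trial ledger. Every other (unit, action, ledger) triple is
#' rejected.
#'
#' @return A data.frame with columns `unit`, `action`, `ledger_kind`.
#' @export
api_permissions <- function() {
  rows <- list(
    c("SDI", "read",  "T-ledger"), c("SDI", "write", "T-ledger"),
    c("PrT", "read",  "T-ledger"), c("PrT", "write", "P-ledger"),
    c("PoT", "write", "P-ledger"),
    c("DCI", "read",  "T-ledger"), c("DCI", "write", "P-ledger"),
    c("TO",  "read",  "T-ledger"), c("TO",  "read",  "P-ledger"),
    c("RA",  "read",  "T-ledger"), c("RA",  "read",  "P-ledger"),
    c("RCA", "read",  "P-ledger"), c("RCA", "read",  "T-ledger")
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("unit", "action", "ledger_kind")
  out
}

unit_allowed <- function(unit, action, ledger_kind) {
  perm <- api_permissions()
  any(perm$unit == unit & perm$action == action & perm$ledger_kind == ledger_kind)
}

#' Build a simulated network
#'
#' Instantiates certificate authorities, certifies every peer through the CA
#' of its server group, creates the channels with genesis-initialized
#' ledgers, and installs the default per-channel validation logic
#' ("chaincode").
#'
#' @param config A configuration list, see [default_network_config()].
#' @return A mutable `qbd_network` handle.
#' @export
build_network <- function(config = default_network_config()) {
  peer_ids <- vapply(config$peers, `[[`, character(1), "peer_id")
  if (anyDuplicated(peer_ids)) {
    qbd_stop("qbd_validation_error", "duplicate peer ids in network config")
  }
  roles <- lapply(config$peers, `[[`, "roles")
  if (!any(vapply(roles, function(r) "orderer" %in% r, logical(1)))) {
    qbd_stop("qbd_validation_error", "network must have at least one orderer")
  }
  if (!any(vapply(roles, function(r) "committer" %in% r, logical(1)))) {
    qbd_stop("qbd_validation_error", "network must have at least one committer")
  }
  for (p in config$peers) {
    if (!all(p$roles %in% PEER_ROLES)) {
      qbd_stop("qbd_validation_error", "unknown role for peer %s", p$peer_id)
    }
    if ("single" %in% p$roles && length(p$hosted_ledgers) != 1L) {
      qbd_stop("qbd_validation_error",
               "single peer %s must host exactly one ledger kind", p$peer_id)
    }
    if ("double" %in% p$roles &&
        !setequal(p$hosted_ledgers, c("T-ledger", "P-ledger"))) {
      qbd_stop("qbd_validation_error",
               "double peer %s must host both ledger kinds", p$peer_id)
    }
  }
  chan_kind <- vapply(config$channels, `[[`, character(1), "ledger_kind")
  names(chan_kind) <- vapply(config$channels, `[[`, character(1), "name")
  for (p in config$peers) {
    hosted_ok <- p$hosted_ledgers %in% chan_kind[p$channels]
    if (length(p$hosted_ledgers) && !all(hosted_ok)) {
      qbd_stop("qbd_validation_error",
               "peer %s hosts a ledger of a channel it has not joined", p$peer_id)
    }
  }
  n_endorsers <- sum(vapply(roles, function(r) "endorser" %in% r, logical(1)))
  pol <- config$policy
  if (identical(pol$rule, "k_of_n") &&
      (is.null(pol$k) || pol$k < 1L || pol$k > n_endorsers)) {
    qbd_stop("qbd_validation_error",
             "k_of_n policy with k=%s unsatisfiable by %d endorsers",
             as.character(pol$k), n_endorsers)
  }
  for (ch in names(chan_kind)) {
    hosts <- vapply(config$peers, function(p) {
      ch %in% p$channels && chan_kind[[ch]] %in% p$hosted_ledgers
    }, logical(1))
    if (!any(hosts)) {
      qbd_stop("qbd_validation_error", "channel %s has no hosting peer", ch)
    }
  }

  net <- new.env(parent = emptyenv())
  net$config <- config
  net$policy <- pol
  net$batch_size <- config$batch_size %||% 1L
  net$tick <- 0L

  # certificate authorities; secrets are deterministic keyed digests so runs
  # are reproducible while forgery remains detectable
  net$cas <- new.env(parent = emptyenv())
  for (ca in config$cas) {
    e <- new.env(parent = emptyenv())
    e$ca_id <- ca$ca_id
    e$server <- ca$server
    e$secret <- sha256_hex(charToRaw(paste0("ca-secret::", ca$ca_id)))
    e$issued <- list()  # serial -> subject_id
    assign(ca$ca_id, e, envir = net$cas)
  }

  net$peers <- new.env(parent = emptyenv())
  for (p in config$peers) {
    ca_id <- paste0("ca-", p$server)
    if (!exists(ca_id, envir = net$cas)) {
      # fall back to the first CA when the server group has no dedicated one
      ca_id <- config$cas[[1]]$ca_id
    }
    pe <- new.env(parent = emptyenv())
    pe$peer_id <- p$peer_id
    pe$roles <- p$roles
    pe$channels <- p$channels
    pe$hosted_ledgers <- p$hosted_ledgers
    pe$server <- p$server
    class(net) <- "qbd_network"  # needed by issue_certificate below
    pe$cert <- issue_certificate(net, ca_id, p$peer_id)
    assign(p$peer_id, pe, envir = net$peers)
  }

  net$ledgers <- new.env(parent = emptyenv())
  for (ch in config$channels) {
    assign(ch$name, new_ledger(ch$ledger_kind, ch$name), envir = net$ledgers)
  }

  net$chaincode <- new.env(parent = emptyenv())
  for (ch in config$channels) {
    register_chaincode(net, ch$name,
                       default_chaincode(ch$ledger_kind), version = "1.0")
  }

  net$units <- config$units
  net$hooks <- list()
  net$hook_firings <- list()
  net$log <- list()
  net$local_store <- new.env(parent = emptyenv())
  net$local_store$pii <- list()
  net$local_store$procedures <- list()
  net$local_store$strategies <- list()
  net$local_store$trial_orders <- list()
  class(net) <- "qbd_network"
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qbd_network <- function(x, ...) {
  cat(sprintf("<qbd_network: %d peers, %d CAs, %d channels, policy=%s>\n",
              length(ls(x$peers)), length(ls(x$cas)),
              length(ls(x$ledgers)), x$policy$rule))
  invisible(x)
}

network_log_append <- function(net, step, unit = "", peer = "", channel = "",
                               tx_id = "", detail = "") {
  net$tick <- net$tick + 1L
  net$log[[length(net$log) + 1L]] <- list(
    tick = net$tick, step = step, unit = unit, peer = peer,
    channel = channel, tx_id = tx_id, detail = detail
  )
  invisible(NULL)
}

#' Structured lifecycle log
#'
#' One row per lifecycle step (propose, endorse, order, commit, query,
#' alert), so the full read/write sequence of a run can be audited.
#'
#' @param network A `qbd_network`.
#' @return data.frame with columns tick, step, unit, peer, channel, tx_id,
#'   detail.
#' @export
network_log <- function(network) {
  if (length(network$log) == 0L) {
    return(data.frame(tick = integer(), step = character(),
                      unit = character(), peer = character(),
                      channel = character(), tx_id = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(network$log, function(e) {
    data.frame(tick = e$tick, step = e$step, unit = e$unit, peer = e$peer,
               channel = e$channel, tx_id = e$tx_id, detail = e$detail,
               stringsAsFactors = FALSE)
  }))
}

# ---- certificates -----------------------------------------------------------

#' Issue a digital certificate
#'
#' Signatures are simulated as keyed digests over (issuer secret, subject,
#' serial): deterministic, and forged or altered certificates fail
#' validation because the token no longer recomputes.
#'
#' @param network A `qbd_network`.
#' @param ca_id Identifier of a configured certificate authority.
#' @param subject_id Peer or participant identifier (non-empty).
#' @return A `digital_certificate`: list(serial, subject_id, issuer, token).
#' @export
issue_certificate <- function(network, ca_id, subject_id) {
  if (!is_string(subject_id) || !nzchar(subject_id)) {
    qbd_stop("qbd_validation_error", "subject_id must be non-empty")
  }
  if (!exists(ca_id, envir = network$cas)) {
    qbd_stop("qbd_validation_error", "unknown certificate authority '%s'", ca_id)
  }
  ca <- get(ca_id, envir = network$cas)
  serial <- sprintf("%s-%05d", ca_id, length(ca$issued) + 1L)
  token <- sha256_hex(charToRaw(paste(ca$secret, subject_id, serial, sep = "|")))
  ca$issued[[serial]] <- subject_id
  structure(list(serial = serial, subject_id = subject_id,
                 issuer = ca_id, token = token),
            class = "digital_certificate")
}

#' Validate a digital certificate
#'
#' Returns `FALSE` (never throws) for unknown issuers, unissued serials, and
#' tokens that do not recompute from the issuer's records.
#'
#' @param cert A `digital_certificate`.
#' @param network A `qbd_network`.
#' @return Logical scalar.
#' @export
validate_certificate <- function(cert, network) {
  if (!is.list(cert) || is.null(cert$issuer) || is.null(cert$serial) ||
      is.null(cert$subject_id) || is.null(cert$token)) {
    return(FALSE)
  }
  if (!exists(cert$issuer, envir = network$cas)) return(FALSE)
  ca <- get(cert$issuer, envir = network$cas)
  subject <- ca$issued[[cert$serial]]
  if (is.null(subject) || !identical(subject, cert$subject_id)) return(FALSE)
  expected <- sha256_hex(charToRaw(paste(ca$secret, cert$subject_id,
                                         cert$serial, sep = "|")))
  identical(expected, cert$token)
}

# ---- chaincode --------------------------------------------------------------

#' Register per-channel validation logic
#'
#' The simulator's "chaincode": a validation function executed by every
#' endorser at endorsement time. Replacing it with a new version tag stands
#' in for the chaincode upgrade lifecycle.
#'
#' @param network A `qbd_network`.
#' @param channel Channel name.
#' @param validate `function(payload, state)` returning `TRUE` or a character
#'   refusal reason; `state` is the channel's current world state.
#' @param version Version tag string.
#' @export
register_chaincode <- function(network, channel, validate, version = "1.0") {
  assign(channel, list(validate = validate, version = version),
         envir = network$chaincode)
  invisible(NULL)
}

# Schema + storage-class + status-lifecycle validation per ledger kind.
default_chaincode <- function(ledger_kind) {
  if (ledger_kind == "T-ledger") {
    function(payload, state) {
      if (!identical(payload$storage_class, "T_LEDGER")) {
        return("storage class does not match T-ledger channel")
      }
      if (!identical(payload$type, "safe_domain")) {
        return("T-ledger accepts only safe_domain payloads")
      }
      if (is.null(payload$factor_id) || is.null(payload$bands)) {
        return("safe_domain payload missing factor_id/bands")
      }
      TRUE
    }
  } else {
    function(payload, state) {
      if (!identical(payload$storage_class, "P_LEDGER")) {
        return("storage class does not match P-ledger channel")
      }
      if (!identical(payload$type, "patient_tx")) {
        return("P-ledger accepts only patient_tx payloads")
      }
      st <- payload$status
      if (is.null(st) || !st %in% c("Initial", "Before", "After")) {
        return("status must be Initial/Before/After")
      }
      if (any(names(payload) %in% LOCAL_FIELDS)) {
        return("payload carries LOCAL-class fields")
      }
      pid <- payload$participant_id
      cyc <- payload$cycle
      key_of <- function(status) sprintf("%s#%s#c%s", pid, status, cyc)
      have <- function(status) !is.null(state$entries[[key_of(status)]])
      if (st == "Initial" && have("Initial")) {
        return("participant already enrolled in this cycle")
      }
      if (st == "Before" && (!have("Initial") || have("Before"))) {
        return("Before requires Initial and no prior Before")
      }
      if (st == "After" && (!have("Before") || have("After"))) {
        return("After requires Before and no prior After")
      }
      TRUE
    }
  }
}

# ---- transaction lifecycle --------------------------------------------------

endorse_proposal <- function(network, tx, proposer_cert) {
  cc <- get(tx$channel_id, envir = network$chaincode)
  state <- tryCatch(replay_state(get(tx$channel_id, envir = network$ledgers)),
                    error = function(e) NULL)
  endorsers <- Filter(function(pid) {
    pe <- get(pid, envir = network$peers)
    "endorser" %in% pe$roles && tx$channel_id %in% pe$channels
  }, ls(network$peers))
  lapply(endorsers, function(pid) {
    pe <- get(pid, envir = network$peers)
    ok_cert <- validate_certificate(proposer_cert, network)
    verdict <- "refuse"
    reason <- ""
    if (!ok_cert) {
      reason <- "invalid proposer certificate"
    } else {
      # chaincode may take (payload, state) or (payload, state, endorser_id)
      res <- if (length(formals(cc$validate)) >= 3L) {
        cc$validate(tx$payload, state, pid)
      } else {
        cc$validate(tx$payload, state)
      }
      if (isTRUE(res)) verdict <- "approve" else reason <- as.character(res)
    }
    token <- sha256_hex(c(charToRaw(pe$cert$token),
                          canonical_serialize(envelope_record(tx))))
    network_log_append(network, "endorse", peer = pid,
                       channel = tx$channel_id, tx_id = tx$tx_id,
                       detail = paste0(verdict,
                                       if (nzchar(reason)) paste0(": ", reason)))
    list(endorser_id = pid, tx_id = tx$tx_id, verdict = verdict,
         token = token, reason = reason)
  })
}

policy_met <- function(policy, endorsements) {
  n <- length(endorsements)
  approvals <- sum(vapply(endorsements, function(e)
    identical(e$verdict, "approve"), logical(1)))
  switch(policy$rule,
         majority = approvals > n / 2,
         all = approvals == n && n > 0L,
         k_of_n = approvals >= policy$k,
         qbd_stop("qbd_validation_error", "unknown policy rule '%s'", policy$rule))
}

#' Submit one or more transaction proposals
#'
#' Executes the full write sequence: the unit's API hands the proposal to
#' its peer, the peer broadcasts it to the endorsers, each endorser validates
#' the proposer's certificate and simulates the transaction against the
#' channel's validation logic, the endorsement policy is evaluated, approved
#' transactions are forwarded to the orderer which packages them into a
#' block, and the committers append the block to the channel ledger. On any
#' rejection nothing is appended anywhere and the result carries a distinct
#' reason code (`permission_denied`, `not_on_channel`, `channel_mismatch`,
#' `invalid_certificate`, `quorum_not_met`).
#'
#' @param network A `qbd_network`.
#' @param api_unit Pipeline unit name (row of [api_permissions()]).
#' @param proposals A single `tx_envelope` or list of envelopes (one block).
#' @return A `commit_result`: list(committed, reason_code, tx_ids,
#'   block_index, endorsements).
#' @export
submit_transaction <- function(network, api_unit, proposals) {
  if (inherits(proposals, "tx_envelope")) proposals <- list(proposals)
  stopifnot(length(proposals) >= 1L)
  channel <- proposals[[1]]$channel_id
  result <- function(committed, reason, block_index = NA_integer_,
                     endorsements = list()) {
    structure(list(
      committed = committed, reason_code = reason,
      tx_ids = vapply(proposals, `[[`, character(1), "tx_id"),
      block_index = block_index, endorsements = endorsements
    ), class = "commit_result")
  }
  if (!all(vapply(proposals, function(p)
    identical(p$channel_id, channel), logical(1)))) {
    return(result(FALSE, "channel_mismatch"))
  }
  if (!exists(channel, envir = network$ledgers)) {
    return(result(FALSE, "channel_mismatch"))
  }
  ledger <- get(channel, envir = network$ledgers)
  peer_id <- network$units[[api_unit]]
  if (is.null(peer_id)) return(result(FALSE, "permission_denied"))
  if (!unit_allowed(api_unit, "write", ledger$ledger_kind)) {
    network_log_append(network, "propose", unit = api_unit, channel = channel,
                       detail = "rejected: permission_denied")
    return(result(FALSE, "permission_denied"))
  }
  peer <- get(peer_id, envir = network$peers)
  if (!channel %in% peer$channels) {
    return(result(FALSE, "not_on_channel"))
  }
  expected_sc <- if (ledger$ledger_kind == "T-ledger") "T_LEDGER" else "P_LEDGER"
  for (p in proposals) {
    if (!identical(p$payload$storage_class, expected_sc)) {
      return(result(FALSE, "channel_mismatch"))
    }
  }
  if (!validate_certificate(peer$cert, network)) {
    return(result(FALSE, "invalid_certificate"))
  }
  all_endorsements <- list()
  for (i in seq_along(proposals)) {
    tx <- proposals[[i]]
    network_log_append(network, "propose", unit = api_unit, peer = peer_id,
                       channel = channel, tx_id = tx$tx_id)
    ends <- endorse_proposal(network, tx, peer$cert)
    if (!policy_met(network$policy, ends)) {
      reasons <- unique(unlist(lapply(ends, `[[`, "reason")))
      reasons <- reasons[nzchar(reasons)]
      if (any(grepl("certificate", reasons))) {
        return(result(FALSE, "invalid_certificate", endorsements = ends))
      }
      network_log_append(network, "order", unit = api_unit, channel = channel,
                         tx_id = tx$tx_id, detail = "rejected: quorum_not_met")
      return(result(FALSE, "quorum_not_met", endorsements = ends))
    }
    proposals[[i]]$endorsements <- lapply(ends, function(e)
      e[c("endorser_id", "tx_id", "verdict", "token")])
    all_endorsements <- c(all_endorsements, list(ends))
  }
  for (tx in proposals) {
    network_log_append(network, "order", unit = api_unit, peer = "peer-orderer",
                       channel = channel, tx_id = tx$tx_id)
  }
  blk <- append_block(ledger, proposals)
  for (tx in proposals) {
    network_log_append(network, "commit", unit = api_unit, channel = channel,
                       tx_id = tx$tx_id, detail = sprintf("block %d", blk$index))
    fire_hooks(network, channel, tx)
  }
  result(TRUE, "committed", block_index = blk$index,
         endorsements = all_endorsements)
}

#' Query a ledger through a unit's API
#'
#' Read-only: replays the channel ledger into its world state and returns
#' the latest payload of every record key matching the selector. Reads are
#' refused for units outside the permission matrix, for peers that have not
#' joined the channel, and for tampered ledgers.
#'
#' @param network A `qbd_network`.
#' @param api_unit Pipeline unit name.
#' @param channel Channel name.
#' @param selector `function(payload) -> logical`, or `NULL` for all records.
#' @return List of payloads.
#' @export
query_ledger <- function(network, api_unit, channel, selector = NULL) {
  if (!exists(channel, envir = network$ledgers)) {
    qbd_stop("qbd_isolation_error", "unknown channel '%s'", channel)
  }
  ledger <- get(channel, envir = network$ledgers)
  if (!unit_allowed(api_unit, "read", ledger$ledger_kind)) {
    qbd_stop("qbd_permission_error",
             "unit %s may not read the %s", api_unit, ledger$ledger_kind)
  }
  peer_id <- network$units[[api_unit]]
  peer <- get(peer_id, envir = network$peers)
  if (!channel %in% peer$channels) {
    qbd_stop("qbd_isolation_error",
             "peer %s has not joined channel %s", peer_id, channel)
  }
  state <- replay_state(ledger)  # integrity error propagates
  network_log_append(network, "query", unit = api_unit, peer = peer_id,
                     channel = channel)
  out <- unname(state$entries)
  if (!is.null(selector)) {
    out <- Filter(function(p) isTRUE(selector(p)), out)
  }
  out
}

# Full history variant (internal): all payloads per key in commit order.
query_history <- function(network, api_unit, channel, selector = NULL) {
  ledger <- get(channel, envir = network$ledgers)
  if (!unit_allowed(api_unit, "read", ledger$ledger_kind)) {
    qbd_stop("qbd_permission_error",
             "unit %s may not read the %s", api_unit, ledger$ledger_kind)
  }
  state <- replay_state(ledger)
  out <- list()
  for (b in ledger$chain) {
    for (tx in b$transactions) {
      if (is.null(selector) || isTRUE(selector(tx$payload))) {
        out <- c(out, list(tx$payload))
      }
    }
  }
  out
}

# ---- smart-contract alert hooks ---------------------------------------------

#' Register a commit-time alert hook
#'
#' Emulates smart-contract alerting: after every commit on the channel the
#' condition is evaluated against the committed payload, and matching
#' payloads invoke the action exactly once. Conditions may reference only
#' on-ledger payload fields; naming a LOCAL-class field is an error.
#'
#' @param network A `qbd_network`.
#' @param channel Channel to watch.
#' @param condition `function(payload) -> logical`.
#' @param action `function(payload, hook_id)` callback.
#' @param fields Character vector of payload field names the condition
#'   reads (declared for auditability and the LOCAL-data check).
#' @return The hook id (string).
#' @export
register_alert_hook <- function(network, channel, condition, action,
                                fields = character()) {
  bad <- intersect(fields, LOCAL_FIELDS)
  if (length(bad)) {
    qbd_stop("qbd_validation_error",
             "alert condition references LOCAL data: %s",
             paste(bad, collapse = ", "))
  }
  hook_id <- sprintf("hook-%03d", length(network$hooks) + 1L)
  network$hooks[[hook_id]] <- list(channel = channel, condition = condition,
                                   action = action, fields = fields)
  hook_id
}

fire_hooks <- function(network, channel, tx) {
  for (hook_id in names(network$hooks)) {
    h <- network$hooks[[hook_id]]
    if (!identical(h$channel, channel)) next
    hit <- tryCatch(isTRUE(h$condition(tx$payload)), error = function(e) FALSE)
    if (hit) {
      network$hook_firings[[length(network$hook_firings) + 1L]] <-
        list(hook_id = hook_id, tx_id = tx$tx_id,
             record_key = tx$payload$record_key)
      network_log_append(network, "alert", channel = channel, tx_id = tx$tx_id,
                         detail = hook_id)
      h$action(tx$payload, hook_id)
    }
  }
}

#' Firings recorded by alert hooks
#'
#' @param network A `qbd_network`.
#' @return data.frame with one row per firing (hook_id, tx_id, record_key).
#' @export
alert_firings <- function(network) {
  if (length(network$hook_firings) == 0L) {
    return(data.frame(hook_id = character(), tx_id = character(),
                      record_key = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(network$hook_firings, function(f) {
    data.frame(hook_id = f$hook_id, tx_id = f$tx_id,
               record_key = f$record_key, stringsAsFactors = FALSE)
  }))
}

network_ledger <- function(network, kind) {
  for (ch in ls(network$ledgers)) {
    lg <- get(ch, envir = network$ledgers)
    if (lg$ledger_kind == kind) return(lg)
  }
  qbd_stop("qbd_validation_error", "no %s in network", kind)
}
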