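#' Append-only hash-chained ledgers
#'
#' The trial ledger (T-ledger) and patient ledger (P-ledger) are both
#' instances of the same substrate: an ordered chain of blocks, each holding
#' the SHA-256 digest of its predecessor, so that any retroactive edit
#' invalidates every subsequent link. Blocks carry transaction envelopes;
#' the latest-value view of the chain (the world state) is recomputed
#' deterministically by replaying from genesis.
#'
#' @name ledger
NULL

GENESIS_PREV_HASH <- strrep("0", 64)

#' Create a transaction envelope
#'
#' Payloads are key-value records tagged with the storage class of the ledger
#' they are destined for (`"T_LEDGER"` or `"P_LEDGER"`). `"LOCAL"`-class
#' records (personally identifiable information, measurement procedures) may
#' never be placed inside an envelope; attempting to do so is an error, which
#' is how the off-chain privacy model is enforced at the type level. Every
#' payload must carry a `record_key` naming the world-state slot it updates.
#'
#' @param tx_id Unique transaction identifier within its ledger.
#' @param channel_id Channel the transaction belongs to.
#' @param payload Named list of scalar fields (decimal strings for
#'   measurements), including `record_key` and `storage_class`.
#' @param proposer_id Peer submitting the proposal.
#' @param cert_ref Serial of the proposer's digital certificate.
#' @param endorsements List of endorsement records (may be empty at proposal
#'   time; filled during the endorse step).
#' @param timestamp Logical integer tick; assigned at commit when `NULL`.
#' @return An object of class `tx_envelope`.
#' @export
new_transaction <- function(tx_id, channel_id, payload, proposer_id,
                            cert_ref = "", endorsements = list(),
                            timestamp = NULL) {
  if (!is_string(tx_id) || !nzchar(tx_id)) {
    qbd_stop("qbd_validation_error", "tx_id must be a non-empty string")
  }
  if (!is_string(channel_id)) {
    qbd_stop("qbd_validation_error", "channel_id must be a string")
  }
  if (!is.list(payload) || is.null(names(payload))) {
    qbd_stop("qbd_validation_error", "payload must be a named list")
  }
  sc <- payload[["storage_class"]]
  if (is.null(sc) || !sc %in% c("T_LEDGER", "P_LEDGER")) {
    qbd_stop("qbd_validation_error",
             "payload storage_class must be T_LEDGER or P_LEDGER (LOCAL data never enters an envelope)")
  }
  if (is.null(payload[["record_key"]])) {
    qbd_stop("qbd_validation_error", "payload must carry a record_key")
  }
  structure(list(
    tx_id = tx_id,
    channel_id = channel_id,
    payload = payload,
    proposer_id = proposer_id,
    cert_ref = cert_ref,
    endorsements = endorsements,
    timestamp = if (is.null(timestamp)) NULL else as.integer(timestamp)
  ), class = "tx_envelope")
}

# Plain-list view used for hashing/serialization (drops the S3 class, keeps
# the documented field set in canonical key order via canonical_serialize).
envelope_record <- function(tx) {
  list(
    tx_id = tx$tx_id,
    channel_id = tx$channel_id,
    payload = tx$payload,
    proposer_id = tx$proposer_id,
    cert_ref = tx$cert_ref,
    endorsements = lapply(tx$endorsements, function(e) {
      list(endorser_id = e$endorser_id, tx_id = e$tx_id,
           verdict = e$verdict, token = e$token)
    }),
    timestamp = tx$timestamp
  )
}

block_record <- function(block, with_hash = TRUE) {
  rec <- list(
    index = block$index,
    prev_hash = block$prev_hash,
    transactions = lapply(block$transactions, envelope_record),
    timestamp = block$timestamp
  )
  if (with_hash) rec$block_hash <- block$block_hash
  rec
}

#' Compute the hash of a block
#'
#' SHA-256 over the canonical serialization of `(index, prev_hash,
#' transactions, timestamp)` — the stored `block_hash` itself is excluded.
#'
#' @param block A `ledger_block`.
#' @return 64 lowercase hex characters.
#' @export
compute_block_hash <- function(block) {
  sha256_hex(canonical_serialize(block_record(block, with_hash = FALSE)))
}

new_block <- function(index, prev_hash, transactions, timestamp) {
  b <- structure(list(
    index = as.integer(index),
    prev_hash = prev_hash,
    transactions = transactions,
    timestamp = as.integer(timestamp),
    block_hash = NULL
  ), class = "ledger_block")
  b$block_hash <- compute_block_hash(b)
  b
}

#' Create an empty, genesis-initialized ledger
#'
#' @param ledger_kind `"T-ledger"` or `"P-ledger"`.
#' @param channel_id Name of the channel this ledger serves.
#' @return A mutable `qbd_ledger` handle (environment). The genesis block has
#'   index 0, a prev-hash of 64 zeros, no transactions, and timestamp 0.
#' @export
new_ledger <- function(ledger_kind = c("T-ledger", "P-ledger"),
                       channel_id = "channel-1") {
  ledger_kind <- match.arg(ledger_kind)
  lg <- new.env(parent = emptyenv())
  lg$ledger_kind <- ledger_kind
  lg$channel_id <- channel_id
  lg$tick <- 0L
  lg$chain <- list(new_block(0L, GENESIS_PREV_HASH, list(), 0L))
  class(lg) <- "qbd_ledger"
  lg
}

#' @export
print.qbd_ledger <- function(x, ...) {
  cat(sprintf("<%s on %s: %d block(s), tip hash %s...>\n",
              x$ledger_kind, x$channel_id, length(x$chain),
              substr(ledger_tip(x)$block_hash, 1, 12)))
  invisible(x)
}

ledger_tip <- function(ledger) ledger$chain[[length(ledger$chain)]]

#' Append a block of transactions to a ledger
#'
#' @param ledger A `qbd_ledger`.
#' @param txs Non-empty list of `tx_envelope`s, all on the ledger's channel.
#' @return The newly appended `ledger_block` (invisibly the ledger grows by
#'   exactly one block).
#' @export
append_block <- function(ledger, txs) {
  stopifnot(inherits(ledger, "qbd_ledger"))
  if (!is.list(txs) || length(txs) == 0L) {
    qbd_stop("qbd_validation_error", "append_block: txs must be a non-empty list")
  }
  for (tx in txs) {
    if (!inherits(tx, "tx_envelope")) {
      qbd_stop("qbd_validation_error", "append_block: txs must be tx_envelopes")
    }
    if (!identical(tx$channel_id, ledger$channel_id)) {
      qbd_stop("qbd_channel_error",
               "transaction channel '%s' does not match ledger channel '%s'",
               tx$channel_id, ledger$channel_id)
    }
  }
  seen <- unlist(lapply(ledger$chain, function(b)
    vapply(b$transactions, `[[`, character(1), "tx_id")))
  ids <- vapply(txs, `[[`, character(1), "tx_id")
  if (anyDuplicated(c(seen, ids))) {
    qbd_stop("qbd_validation_error", "duplicate tx_id on ledger")
  }
  ledger$tick <- ledger$tick + 1L
  txs <- lapply(txs, function(tx) {
    if (is.null(tx$timestamp)) tx$timestamp <- ledger$tick
    tx
  })
  tip <- ledger_tip(ledger)
  blk <- new_block(tip$index + 1L, tip$block_hash, txs, ledger$tick)
  ledger$chain[[length(ledger$chain) + 1L]] <- blk
  blk
}

#' Verify the hash chain of a ledger
#'
#' A ledger is valid iff every stored block hash matches its recomputation
#' from the block's contents and every `prev_hash` equals the predecessor's
#' stored hash. When invalid, the smallest failing block index is reported,
#' so a single tampered field is always detected at (or one link after) the
#' block it lives in.
#'
#' @param ledger A `qbd_ledger`.
#' @return List with elements `valid` (logical) and `first_invalid_index`
#'   (integer block index, `NA` when valid).
#' @export
verify_chain <- function(ledger) {
  stopifnot(inherits(ledger, "qbd_ledger"))
  prev <- NULL
  for (b in ledger$chain) {
    idx <- b$index
    bad <- !identical(compute_block_hash(b), b$block_hash) ||
      (is.null(prev) && (idx != 0L || !identical(b$prev_hash, GENESIS_PREV_HASH))) ||
      (!is.null(prev) && (idx != prev$index + 1L ||
                          !identical(b$prev_hash, prev$block_hash)))
    if (bad) {
      return(list(valid = FALSE, first_invalid_index = idx))
    }
    prev <- b
  }
  list(valid = TRUE, first_invalid_index = NA_integer_)
}

#' Replay a ledger into its world state
#'
#' Left-to-right fold over all committed transactions: later transactions for
#' the same `record_key` supersede earlier ones, and the full per-key history
#' is retained. A ledger that fails verification refuses to serve reads.
#'
#' @param ledger A `qbd_ledger`.
#' @return A `world_state`: list with `entries` (latest payload per record
#'   key) and `history` (all payloads per record key, in commit order).
#' @export
replay_state <- function(ledger) {
  chk <- verify_chain(ledger)
  if (!chk$valid) {
    qbd_stop("qbd_integrity_error",
             "ledger failed verification at block %d; refusing to read",
             chk$first_invalid_index)
  }
  entries <- list()
  history <- list()
  for (b in ledger$chain) {
    for (tx in b$transactions) {
      key <- tx$payload[["record_key"]]
      entries[[key]] <- tx$payload
      history[[key]] <- c(history[[key]], list(tx$payload))
    }
  }
  structure(list(entries = entries, history = history), class = "world_state")
}

#' Tamper with a committed block (testing/demo helper)
#'
#' Returns a modified deep copy of the ledger with one field changed and
#' *no* hashes recomputed, so that `verify_chain()` must fail. The original
#' ledger is untouched. `field_path` addresses a field inside the block,
#' e.g. `"timestamp"`, `"prev_hash"`, or
#' `"transactions[1].payload.value"` (1-based list indices in brackets).
#'
#' @param ledger A `qbd_ledger`.
#' @param block_index Index of the block to modify (0 = genesis).
#' @param field_path Dot/bracket path within the block.
#' @param new_value Replacement value.
#' @return A new, tampered `qbd_ledger`.
#' @export
tamper_ledger <- function(ledger, block_index, field_path, new_value) {
  stopifnot(inherits(ledger, "qbd_ledger"))
  pos <- block_index + 1L
  if (pos < 1L || pos > length(ledger$chain)) {
    qbd_stop("qbd_validation_error", "block index %d does not exist", block_index)
  }
  copy <- new.env(parent = emptyenv())
  copy$ledger_kind <- ledger$ledger_kind
  copy$channel_id <- ledger$channel_id
  copy$tick <- ledger$tick
  copy$chain <- ledger$chain  # blocks are immutable lists; copy-on-write below
  class(copy) <- "qbd_ledger"
  blk <- copy$chain[[pos]]
  blk_list <- unclass(blk)
  blk_list <- set_field_path(blk_list, field_path, new_value)
  copy$chain[[pos]] <- structure(blk_list, class = "ledger_block")
  copy
}

# Parse "a.b[2].c" into a path and set the value, erroring on unknown fields.
set_field_path <- function(x, path, value) {
  tokens <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(tokens) == 0L) qbd_stop("qbd_validation_error", "empty field path")
  setter <- function(node, toks) {
    tok <- toks[[1]]
    m <- regmatches(tok, regexec("^([^\\[]+)(\\[([0-9]+)\\])?$", tok))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      qbd_stop("qbd_validation_error", "malformed field path token '%s'", tok)
    }
    name <- m[2]
    if (is.null(node[[name]]) && !name %in% names(node)) {
      qbd_stop("qbd_validation_error", "unknown field '%s' in path", name)
    }
    target <- node[[name]]
    if (nzchar(m[4])) {
      i <- as.integer(m[4])
      if (!is.list(target) || i < 1L || i > length(target)) {
        qbd_stop("qbd_validation_error", "index %d out of range for '%s'", i, name)
      }
      if (length(toks) == 1L) {
        target[[i]] <- value
      } else {
        target[[i]] <- setter(target[[i]], toks[-1])
      }
      node[[name]] <- target
    } else if (length(toks) == 1L) {
      node[[name]] <- value
    } else {
      node[[name]] <- setter(target, toks[-1])
    }
    node
  }
  setter(x, tokens)
}

#' Export / import a ledger as JSON lines
#'
#' One canonical-JSON block per line, preceded by a single header line with
#' the ledger kind and channel. Round trips are byte-stable: exporting an
#' imported file reproduces the file exactly.
#'
#' @param ledger A `qbd_ledger`.
#' @param path File path.
#' @return `export_ledger` returns `path` invisibly; `import_ledger` returns
#'   a `qbd_ledger`.
#' @export
export_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "qbd_ledger"))
  header <- rawToChar(canonical_serialize(list(
    ledger_kind = ledger$ledger_kind, channel_id = ledger$channel_id,
    tick = ledger$tick
  )))
  lines <- vapply(ledger$chain, function(b) {
    rawToChar(canonical_serialize(block_record(b, with_hash = TRUE)))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname export_ledger
#' @export
import_ledger <- function(path) {
  if (!file.exists(path)) {
    qbd_stop("qbd_parse_error", "ledger file '%s' does not exist", path)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 2L) {
    qbd_stop("qbd_parse_error", "ledger file '%s' is empty or truncated", path)
  }
  header <- tryCatch(jsonlite::fromJSON(lines[[1]], simplifyVector = FALSE),
                     error = function(e) {
                       qbd_stop("qbd_parse_error", "bad ledger header: %s",
                                conditionMessage(e))
                     })
  lg <- new.env(parent = emptyenv())
  lg$ledger_kind <- header$ledger_kind
  lg$channel_id <- header$channel_id
  lg$tick <- as.integer(header$tick)
  lg$chain <- lapply(lines[-1], function(ln) {
    rec <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
                    error = function(e) {
                      qbd_stop("qbd_parse_error", "bad block line: %s",
                               conditionMessage(e))
                    })
    txs <- lapply(rec$transactions, function(t) {
      structure(list(
        tx_id = t$tx_id, channel_id = t$channel_id, payload = t$payload,
        proposer_id = t$proposer_id, cert_ref = t$cert_ref,
        endorsements = t$endorsements,
        timestamp = as.integer(t$timestamp)
      ), class = "tx_envelope")
    })
    structure(list(
      index = as.integer(rec$index), prev_hash = rec$prev_hash,
      transactions = txs, timestamp = as.integer(rec$timestamp),
      block_hash = rec$block_hash
    ), class = "ledger_block")
  })
  class(lg) <- "qbd_ledger"
  lg
}
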