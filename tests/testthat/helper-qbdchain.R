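# Shared fixtures built in code. The full pilot run is expensive enough to
# cache: tests that only read from it share one instance.

.pilot_cache <- new.env(parent = emptyenv())

pilot_fixture <- function() {
  if (is.null(.pilot_cache$fx)) .pilot_cache$fx <- load_pilot_fixture()
  .pilot_cache$fx
}

# One warn-mode PDCA cycle over the pilot fixture (shared, read-only).
pilot_run <- function() {
  if (is.null(.pilot_cache$run)) {
    fx <- pilot_fixture()
    .pilot_cache$run <- run_cycle(fx$paths[["protocol"]], fx$paths[["trial"]])
  }
  .pilot_cache$run
}

pilot_domains <- function() {
  domains_from_protocol(pilot_fixture()$protocol)
}

# Minimal committed-payload transaction for ledger-level tests.
make_tx <- function(id, key = id, channel = "channel-2",
                    extra = list(), class = "P_LEDGER") {
  payload <- c(list(type = "patient_tx", storage_class = class,
                    record_key = key), extra)
  new_transaction(tx_id = id, channel_id = channel, payload = payload,
                  proposer_id = "peer-x", cert_ref = "serial-x")
}

# Ledger with n appended single-tx blocks.
chain_of <- function(n, channel = "channel-2") {
  lg <- new_ledger("P-ledger", channel)
  for (i in seq_len(n)) {
    append_block(lg, list(make_tx(sprintf("tx-%03d", i),
                                  key = sprintf("k-%03d", i),
                                  channel = channel,
                                  extra = list(value = as.character(i)))))
  }
  lg
}

# Random envelope/block generator for serialization/hash property tests.
random_block <- function(seed) {
  set.seed(seed)
  txs <- lapply(seq_len(sample(1:3, 1)), function(i) {
    make_tx(sprintf("tx-%d-%d", seed, i),
            key = sprintf("key-%d-%d", seed, i),
            extra = list(value = as.character(sample(1:999, 1)),
                         note = paste(sample(letters, 5), collapse = "")))
  })
  lg <- new_ledger("P-ledger", "channel-2")
  append_block(lg, txs)
}

# Numeric cohort view (participant_id, sex, age + factor columns).
cohort_view <- function(roster, values) {
  m <- merge(roster[, c("participant_id", "sex", "age")], values,
             by = "participant_id", sort = FALSE)
  m[order(as.integer(sub("^P", "", m$participant_id))), , drop = FALSE]
}
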