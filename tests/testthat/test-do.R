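# Helper: fresh network with the pilot plan phase committed.
planned_network <- function() {
  fx <- pilot_fixture()
  net <- build_network()
  factors <- identify_csa(fx$protocol)
  determine_measurements(fx$protocol, factors, net)
  net$local_store$checkable <- c("F1", "F2", "F3.1", "F3.2", "F3.3",
                                 "F3.4", "F5")
  net$local_store$harm_direction <- c(F1 = "both", F2 = "high",
                                      `F3.1` = "high", `F3.2` = "both",
                                      `F3.3` = "high", `F3.4` = "both",
                                      F4 = "low", F5 = "both")
  identify_safe_domains(fx$protocol, factors, network = net)
  list(net = net, fx = fx)
}

patient_before <- function(net, pid) {
  hits <- query_ledger(net, "TO", "channel-2", function(p) {
    identical(p$status, "Before") && identical(p$participant_id, pid)
  })
  if (length(hits)) hits[[1]] else NULL
}

pre_values <- function(fx, pid) {
  i <- which(fx$before$participant_id == pid)
  as.list(fx$before[i, -1])
}
post_values <- function(fx, pid) {
  i <- which(fx$after$participant_id == pid)
  as.list(fx$after[i, -1])
}

test_that("enrollment commits one Initial tx per participant with N/A values", {
  pn <- planned_network()
  out <- enroll(pn$net, pn$fx$roster)
  expect_length(out, 30L)
  initial <- query_ledger(pn$net, "TO", "channel-2", function(p) {
    identical(p$status, "Initial")
  })
  expect_length(initial, 30L)
  for (p in initial) {
    expect_true(all(unlist(p$values) == "N/A"))
    expect_match(p$cert_serial, "^ca-do-")
    expect_match(p$pii_pointer, "^[0-9a-f]{64}$")
  }
  # re-enrollment of an existing participant fails, ledger keeps one Initial
  expect_error(enroll(pn$net, pn$fx$roster[1, ]),
               class = "qbd_lifecycle_error")
  again <- query_ledger(pn$net, "TO", "channel-2", function(p) {
    identical(p$status, "Initial") && identical(p$participant_id, "P1")
  })
  expect_length(again, 1L)
})

test_that("empty rosters and missing domains are rejected cleanly", {
  pn <- planned_network()
  empty <- pn$fx$roster[0, ]
  expect_length(enroll(pn$net, empty), 0L)
  # no plan phase -> sequencing error
  net2 <- build_network()
  expect_error(enroll(net2, pn$fx$roster), class = "qbd_sequencing_error")
  dup <- pn$fx$roster[c(1, 1), ]
  expect_error(enroll(pn$net, dup), "duplicate participant ids")
})

test_that("the trial order is built from ledger state, not input files", {
  pn <- planned_network()
  expect_error(build_trial_order(pn$net), class = "qbd_sequencing_error")
  enroll(pn$net, pn$fx$roster)
  ord <- build_trial_order(pn$net)
  expect_identical(nrow(ord$roster), 30L)
  expect_identical(ord$roster$participant_id,
                   paste0("P", 1:30))
  # domain snapshot comes from the committed T-ledger payloads
  b <- lookup_domain(ord$domains_snapshot, "F2", "M", 49, "before")
  expect_identical(c(b$lower, b$upper), c(80, 145))
  expect_named(ord$procedures)
})

test_that("strict gating blocks out-of-domain pre-values; warn mode records them", {
  pn <- planned_network()
  enroll(pn$net, pn$fx$roster)
  # P1's pre-values are fully in-domain
  rep1 <- record_pre(pn$net, "P1", pre_values(pn$fx, "P1"))
  expect_false(rep1$blocked)
  expect_length(rep1$deviations, 0L)
  # P20: heart rate 149 above the age-49 band upper 145 -> blocked in strict
  rep20 <- record_pre(pn$net, "P20", pre_values(pn$fx, "P20"),
                      mode = "strict")
  expect_true(rep20$blocked)
  expect_identical(rep20$deviations[[1]]$factor_id, "F2")
  expect_identical(rep20$deviations[[1]]$direction, "high")
  expect_null(patient_before(pn$net, "P20"))
  # warn mode commits with the deviation embedded
  rep20w <- record_pre(pn$net, "P20", pre_values(pn$fx, "P20"), mode = "warn")
  expect_false(rep20w$blocked)
  expect_length(rep20w$deviations, 1L)
  committed <- patient_before(pn$net, "P20")
  expect_identical(committed$deviations[[1]]$factor_id, "F2")
})

test_that("lifecycle order Initial -> Before -> After is enforced", {
  pn <- planned_network()
  enroll(pn$net, pn$fx$roster[1:2, ])
  # After before Before
  expect_error(record_post(pn$net, "P1", post_values(pn$fx, "P1")),
               class = "qbd_lifecycle_error")
  record_pre(pn$net, "P1", pre_values(pn$fx, "P1"))
  # duplicate Before
  expect_error(record_pre(pn$net, "P1", pre_values(pn$fx, "P1")),
               class = "qbd_lifecycle_error")
  record_post(pn$net, "P1", post_values(pn$fx, "P1"))
  # duplicate After
  expect_error(record_post(pn$net, "P1", post_values(pn$fx, "P1")),
               class = "qbd_lifecycle_error")
  # unknown participant / missing values
  expect_error(record_pre(pn$net, "P99", pre_values(pn$fx, "P1")),
               class = "qbd_lifecycle_error")
  short <- pre_values(pn$fx, "P2")
  short$F2 <- NULL
  expect_error(record_pre(pn$net, "P2", short), "missing factor")
})

test_that("statuses form a prefix of the lifecycle under arbitrary interleavings", {
  pn <- planned_network()
  enroll(pn$net, pn$fx$roster[1:5, ])
  set.seed(11)
  pids <- paste0("P", 1:5)
  for (step in 1:40) {
    pid <- sample(pids, 1)
    op <- sample(c("pre", "post"), 1)
    try(switch(op,
               pre = record_pre(pn$net, pid, pre_values(pn$fx, pid)),
               post = record_post(pn$net, pid, post_values(pn$fx, pid))),
        silent = TRUE)
    for (p in pids) {
      statuses <- vapply(tryCatch(get_participant_history(pn$net, p),
                                  error = function(e) list()),
                         `[[`, character(1), "status")
      n <- length(statuses)
      expect_identical(statuses, c("Initial", "Before", "After")[seq_len(n)])
    }
  }
})

test_that("the full warn-mode fixture run yields 90 patient transactions", {
  run <- pilot_run()
  s <- run$summary
  expect_identical(c(s$tx_initial, s$tx_before, s$tx_after), c(30L, 30L, 30L))
  expect_identical(s$pledger_blocks, 91L)  # genesis + 90 single-tx blocks
  # and this module wrote nothing to the trial ledger beyond the plan phase
  expect_identical(s$tledger_blocks, 9L)   # genesis + 8 domain families
})

test_that("participant history preserves values exactly as recorded", {
  run <- pilot_run()
  fx <- pilot_fixture()
  hist <- get_participant_history(run$network, "P23")
  expect_identical(vapply(hist, `[[`, character(1), "status"),
                   c("Initial", "Before", "After"))
  # decimal-string round trip for all 30 x 2 x 8 measurements
  for (pid in fx$roster$participant_id) {
    h <- get_participant_history(run$network, pid)
    before <- h[[2]]$values
    after <- h[[3]]$values
    i <- which(fx$before$participant_id == pid)
    for (f in names(before)) {
      expect_identical(before[[f]], as.character(fx$before[i, f]))
      expect_identical(after[[f]], as.character(fx$after[i, f]))
    }
  }
  expect_error(get_participant_history(run$network, "P99"),
               "unknown participant")
})

test_that("no LOCAL personal data ever reaches a committed payload", {
  run <- pilot_run()
  net <- run$network
  for (ch in ls(net$ledgers)) {
    lg <- get(ch, envir = net$ledgers)
    for (b in lg$chain) {
      for (tx in b$transactions) {
        expect_length(intersect(names(tx$payload),
                                c("pii", "full_name", "address", "contact",
                                  "phone", "sponsor_meta", "procedures",
                                  "schedule")), 0L)
      }
    }
  }
  # the on-chain pointer verifies against the LOCAL store
  for (pid in c("P1", "P17", "P30")) {
    h <- get_participant_history(net, pid)
    local_rec <- net$local_store$pii[[pid]]
    expect_identical(h[[1]]$pii_pointer,
                     sha256_hex(canonical_serialize(local_rec)))
  }
})
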