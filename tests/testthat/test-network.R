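test_that("the default network reproduces the reference deployment", {
  net <- build_network()
  peers <- mget(ls(net$peers), envir = net$peers)
  endorsers <- Filter(function(p) "endorser" %in% p$roles, peers)
  expect_length(endorsers, 3L)
  expect_length(ls(net$cas), 6L)
  expect_length(ls(net$ledgers), 2L)
  singles <- Filter(function(p) "single" %in% p$roles, peers)
  doubles <- Filter(function(p) "double" %in% p$roles, peers)
  expect_length(singles, 1L)
  expect_length(doubles, 1L)
  expect_setequal(doubles[[1]]$hosted_ledgers, c("T-ledger", "P-ledger"))
  # every peer certified by a configured CA
  for (p in peers) expect_true(validate_certificate(p$cert, net))
})

test_that("invalid configurations are rejected at construction", {
  cfg <- default_network_config()
  cfg$peers <- Filter(function(p) !"orderer" %in% p$roles, cfg$peers)
  expect_error(build_network(cfg), "orderer")
  cfg2 <- default_network_config()
  cfg2$peers[[2]]$peer_id <- cfg2$peers[[1]]$peer_id
  expect_error(build_network(cfg2), "duplicate peer ids")
  cfg3 <- default_network_config(policy = list(rule = "k_of_n", k = 9L))
  expect_error(build_network(cfg3), "unsatisfiable")
})

test_that("the YAML network config reproduces the built-in default counts", {
  path <- system.file("extdata", "network_default.yaml", package = "qbdchain")
  net <- build_network(read_network_config(path))
  expect_length(ls(net$cas), 6L)
  expect_length(Filter(function(pid) {
    "endorser" %in% get(pid, envir = net$peers)$roles
  }, ls(net$peers)), 3L)
})

test_that("certificates bind subject, issuer and serial", {
  net <- build_network()
  cert <- issue_certificate(net, "ca-do", "P1")
  expect_true(validate_certificate(cert, net))
  altered <- cert
  altered$subject_id <- "P2"
  expect_false(validate_certificate(altered, net))
  forged <- cert
  forged$token <- strrep("ab", 32)
  expect_false(validate_certificate(forged, net))
  unknown <- cert
  unknown$issuer <- "ca-rogue"
  expect_false(validate_certificate(unknown, net))
  # 30 enrollments -> 30 distinct serials
  serials <- vapply(pilot_fixture()$roster$participant_id, function(pid) {
    issue_certificate(net, "ca-do", pid)$serial
  }, character(1))
  expect_length(unique(serials), 30L)
})

test_that("commit occurs iff the endorsement quorum is met (all 8 cases)", {
  endorser_ids <- c("peer-endorser-1", "peer-endorser-2", "peer-endorser-3")
  combos <- expand.grid(e1 = c(TRUE, FALSE), e2 = c(TRUE, FALSE),
                        e3 = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    approve <- endorser_ids[unlist(combos[i, ])]
    net <- build_network()
    # test chaincode: verdict controlled per endorser via the payload
    register_chaincode(net, "channel-2", function(payload, state, endorser) {
      if (endorser %in% strsplit(payload$approvers, "\\|")[[1]]) TRUE
      else "refused by test harness"
    }, version = "test")
    tx <- make_tx("tx-quorum",
                  extra = list(approvers = paste(approve, collapse = "|")))
    res <- submit_transaction(net, "PoT", list(tx))
    lg <- get("channel-2", envir = net$ledgers)
    if (length(approve) >= 2) {
      expect_true(res$committed, label = paste("combo", i))
      expect_identical(length(lg$chain), 2L)
    } else {
      expect_false(res$committed, label = paste("combo", i))
      expect_identical(res$reason_code, "quorum_not_met")
      expect_identical(length(lg$chain), 1L)  # nothing appended
    }
  }
})

test_that("rejections carry distinct reason codes and never append", {
  net <- build_network()
  # invalid certificate: break the proposing peer's cert
  peer <- get("peer-do-double", envir = net$peers)
  good_cert <- peer$cert
  peer$cert$token <- strrep("00", 32)
  res <- submit_transaction(net, "PoT", list(make_tx("tx-bad-cert")))
  expect_false(res$committed)
  expect_identical(res$reason_code, "invalid_certificate")
  peer$cert <- good_cert
  # storage class not matching the channel ledger
  res2 <- submit_transaction(net, "PoT",
                             list(make_tx("tx-sc", class = "T_LEDGER")))
  expect_identical(res2$reason_code, "channel_mismatch")
  # permission matrix: RA may not write anywhere
  res3 <- submit_transaction(net, "RA", list(make_tx("tx-ra")))
  expect_identical(res3$reason_code, "permission_denied")
  expect_identical(length(get("channel-2", envir = net$ledgers)$chain), 1L)
})

test_that("the API permission matrix admits listed triples and no others", {
  run <- pilot_run()
  net <- run$network
  perm <- api_permissions()
  units <- unique(perm$unit)
  kinds <- c("T-ledger", "P-ledger")
  chan_of <- c("T-ledger" = "channel-1", "P-ledger" = "channel-2")
  for (u in units) {
    for (k in kinds) {
      allowed <- any(perm$unit == u & perm$action == "read" &
                       perm$ledger_kind == k)
      got <- tryCatch({
        query_ledger(net, u, chan_of[[k]], function(p) FALSE)
        TRUE
      }, qbd_permission_error = function(e) FALSE,
         qbd_isolation_error = function(e) FALSE)
      expect_identical(got, allowed, label = sprintf("read %s by %s", k, u))
    }
  }
  # writes: only SDI->T, PrT/PoT/DCI->P succeed past the permission gate
  for (u in units) {
    for (k in kinds) {
      allowed <- any(perm$unit == u & perm$action == "write" &
                       perm$ledger_kind == k)
      tx <- make_tx(paste0("tx-pm-", u, "-", k),
                    channel = chan_of[[k]],
                    class = if (k == "T-ledger") "T_LEDGER" else "P_LEDGER")
      res <- submit_transaction(net, u, list(tx))
      if (!allowed) {
        expect_identical(res$reason_code, "permission_denied",
                         label = sprintf("write %s by %s", k, u))
      } else {
        # permission passes; commit may still fail schema validation,
        # which is a different reason code
        expect_false(identical(res$reason_code, "permission_denied"),
                     label = sprintf("write %s by %s", k, u))
      }
    }
  }
  # unknown unit is rejected outright
  expect_identical(submit_transaction(net, "CSAI",
                                      list(make_tx("tx-csai")))$reason_code,
                   "permission_denied")
})

test_that("channel isolation blocks peers outside the channel", {
  net <- build_network()
  # SDI's peer (single, channel-1 only) cannot reach channel-2 even though
  # SDI cannot read the P-ledger anyway; force the isolation path with a
  # unit that has P-ledger read rights wired to the single peer
  net$units$RA <- "peer-plan-single"
  expect_error(query_ledger(net, "RA", "channel-2"),
               class = "qbd_isolation_error")
})

test_that("a committed transaction appears in exactly one block of one ledger", {
  run <- pilot_run()
  net <- run$network
  ids <- character()
  for (ch in ls(net$ledgers)) {
    lg <- get(ch, envir = net$ledgers)
    ids <- c(ids, unlist(lapply(lg$chain, function(b) {
      vapply(b$transactions, `[[`, character(1), "tx_id")
    })))
  }
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("alert hooks fire exactly once per matching commit, never on LOCAL fields", {
  net <- build_network()
  fired <- new.env(); fired$n <- 0L
  expect_error(
    register_alert_hook(net, "channel-2", function(p) TRUE,
                        function(p, id) NULL, fields = c("pii")),
    "LOCAL data")
  register_alert_hook(net, "channel-2",
                      function(p) !is.null(p$value) && as.numeric(p$value) > 100,
                      function(p, id) fired$n <- fired$n + 1L,
                      fields = "value")
  # permissive validation: these bare test payloads are not patient records
  register_chaincode(net, "channel-2", function(payload, state) TRUE)
  submit_transaction(net, "PoT", list(make_tx("t1", extra = list(value = "50"))))
  expect_identical(fired$n, 0L)
  submit_transaction(net, "PoT", list(make_tx("t2", key = "k2",
                                              extra = list(value = "150"))))
  submit_transaction(net, "PoT", list(make_tx("t3", key = "k3",
                                              extra = list(value = "200"))))
  expect_identical(fired$n, 2L)
  expect_identical(nrow(alert_firings(net)), 2L)
})

test_that("an age-banded heart-rate alert fires on the out-of-range After commit", {
  fx <- pilot_fixture()
  domains <- pilot_domains()
  net <- build_network()
  hits <- new.env(); hits$ids <- character()
  register_alert_hook(net, "channel-2", function(p) {
    if (!identical(p$status, "After")) return(FALSE)
    band <- lookup_domain(domains, "F2", p$sex, as.integer(p$age), "after")
    as.numeric(p$values[["F2"]]) > band$upper
  }, function(p, id) hits$ids <- c(hits$ids, p$participant_id),
  fields = c("status", "values", "sex", "age"))
  protocol <- fx$protocol
  factors <- identify_csa(protocol)
  determine_measurements(protocol, factors, net)
  identify_safe_domains(protocol, factors, network = net)
  enroll(net, fx$roster)
  for (pid in c("P1", "P8")) {
    i <- which(fx$before$participant_id == pid)
    record_pre(net, pid, as.list(fx$before[i, -1]))
    record_post(net, pid, as.list(fx$after[i, -1]))
  }
  expect_identical(hits$ids, "P8")  # 185 exceeds the <40 band upper 153
})
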