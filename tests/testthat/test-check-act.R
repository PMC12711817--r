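pilot_after_cohort <- function() {
  fx <- pilot_fixture()
  cohort_view(fx$roster, fx$after)
}
pilot_before_cohort <- function() {
  fx <- pilot_fixture()
  cohort_view(fx$roster, fx$before)
}
pilot_harm <- c(F1 = "both", F2 = "high", `F3.1` = "high", `F3.2` = "both",
                `F3.3` = "high", `F3.4` = "both", F5 = "both")

test_that("the default risk scan flags the narrative heart-rate set", {
  run <- pilot_run()
  flags <- assess_risk(run$network, 1, risk_rule_config())
  f2 <- flags[flags$factor_id == "F2", ]
  expect_setequal(f2$participant_id, c("P3", "P8", "P10", "P23", "P25", "P28"))
  expect_identical(f2$severity[f2$participant_id == "P3"], "borderline")
  out <- f2[f2$severity == "out_of_range", "participant_id"]
  expect_setequal(out, c("P8", "P10", "P23", "P25", "P28"))
  # P17 sits exactly on the lower bound 80; harm direction high -> no flag
  expect_false("P17" %in% f2$participant_id)
})

test_that("zero-delta both-direction scan matches the exhaustive arithmetic", {
  cfg <- risk_rule_config(borderline_delta = 0, use_harm_direction = FALSE)
  flags <- risk_scan(pilot_after_cohort(), pilot_domains(), cfg,
                     phase = "after")
  f2 <- flags[flags$factor_id == "F2", ]
  expect_setequal(f2$participant_id, c("P8", "P10", "P23", "P25", "P28"))
  expect_true(all(f2$severity == "out_of_range"))
})

test_that("a midpoint cohort produces no flags", {
  domains <- pilot_domains()
  mid <- data.frame(participant_id = "S1", sex = "M", age = 30,
                    F1 = 105, F2 = 121, `F3.1` = 50, `F3.2` = 100,
                    `F3.3` = 90, `F3.4` = 120, F5 = 22,
                    check.names = FALSE, stringsAsFactors = FALSE)
  flags <- risk_scan(mid, domains, risk_rule_config(), phase = "after",
                     harm_stored = pilot_harm)
  expect_identical(nrow(flags), 0L)
})

test_that("risk scan equals a brute-force interval comparison on random cohorts", {
  domains <- pilot_domains()
  checkable <- c("F1", "F2", "F3.1", "F3.2", "F3.3", "F3.4", "F5")
  # all factors high-harm, delta 1: borderline iff in-domain and within 1
  # of the upper bound
  brute_force <- function(cohort, delta = 1.0) {
    hits <- character()
    for (i in seq_len(nrow(cohort))) {
      for (fid in checkable) {
        v <- as.numeric(cohort[[fid]][i])
        b <- lookup_domain(domains, fid, cohort$sex[i], cohort$age[i], "after")
        lo_bad <- !is.null(b$lower) &&
          (if (b$lower_inclusive) v < b$lower else v <= b$lower)
        hi_bad <- !is.null(b$upper) &&
          (if (b$upper_inclusive) v > b$upper else v >= b$upper)
        border <- !lo_bad && !hi_bad && delta > 0 &&
          !is.null(b$upper) && b$upper - v <= delta
        if (lo_bad || hi_bad || border) {
          hits <- c(hits, paste(cohort$participant_id[i], fid,
                                if (lo_bad || hi_bad) "out_of_range"
                                else "borderline"))
        }
      }
    }
    sort(hits)
  }
  for (s in 1:12) {
    spec <- cohort_spec(n = 60, seed = 300 + s)
    coh <- generate_cohort(spec)
    cohA <- cohort_view(coh$roster, coh$after)
    # jitter some values out of domain so both severities occur
    set.seed(s)
    for (k in 1:8) {
      i <- sample(nrow(cohA), 1)
      f <- sample(checkable, 1)
      cohA[[f]][i] <- as.numeric(cohA[[f]][i]) + sample(c(-40, 40), 1)
    }
    cfg <- risk_rule_config(
      borderline_delta = c(default = 1.0, F2 = 1.0),
      use_harm_direction = TRUE,
      harm_direction = stats::setNames(rep("high", 7), checkable)
    )
    got <- risk_scan(cohA, domains, cfg, phase = "after")
    got_keys <- sort(paste(got$participant_id, got$factor_id, got$severity))
    expect_identical(got_keys, brute_force(cohA))
  }
})

test_that("flag sets grow monotonically with the borderline delta", {
  domains <- pilot_domains()
  cohA <- pilot_after_cohort()
  prev <- character()
  for (d in c(0, 0.5, 1, 2, 5)) {
    cfg <- risk_rule_config(borderline_delta = d)
    fl <- risk_scan(cohA, domains, cfg, phase = "after",
                    harm_stored = pilot_harm)
    keys <- paste(fl$participant_id, fl$factor_id)
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("pre-level categorization reproduces the narrative categories", {
  run <- pilot_run()
  p23 <- categorize_levels(run$network, "P23")
  expect_identical(unname(p23[["F2"]]), "low")     # 78 at band edge 78-132
  expect_identical(unname(p23[["F3.1"]]), "high")  # 99 against "< 100"
  p8 <- categorize_levels(run$network, "P8")
  expect_identical(unname(p8[["F2"]]), "high")     # 152 on 90-153, wide margin
  expect_identical(unname(p8[["F3.2"]]), "high")   # 128 on 70-130
  expect_identical(unname(p8[["F3.1"]]), "normal") # 90 sits ON the margin edge
  p28 <- categorize_levels(run$network, "P28")
  expect_identical(unname(p28[["F2"]]), "low")
  expect_identical(unname(p28[["F3.1"]]), "high")
  # midpoints are normal
  domains <- pilot_domains()
  mid <- data.frame(participant_id = "S1", sex = "F", age = 35,
                    F1 = 105, F2 = 121, check.names = FALSE,
                    stringsAsFactors = FALSE)
  lv <- level_categories(mid, domains, risk_rule_config())
  expect_identical(unname(lv$S1[["F1"]]), "normal")
  expect_identical(unname(lv$S1[["F2"]]), "normal")
})

test_that("rule induction recovers both narrative subgroups from the named flags", {
  run <- pilot_run()
  flags <- run$flags
  named <- flags[flags$factor_id == "F2" &
                   flags$participant_id %in% c("P3", "P8", "P23", "P28"), ]
  rules <- analyze_root_cause(run$network, named, 1, risk_rule_config())
  expect_length(rules, 2L)
  key <- vapply(rules, function(r) r$sex, character(1))
  female <- rules[[which(key == "F")]]
  male <- rules[[which(key == "M")]]
  expect_identical(c(female$age_min, female$age_max), c(60L, 65L))
  expect_identical(female$levels, c(F2 = "low", `F3.1` = "high"))
  expect_identical(female$support, c("P23", "P28"))
  expect_identical(female$precision, 1)
  expect_identical(c(male$age_min, male$age_max), c(35L, 40L))
  expect_identical(male$levels, c(F2 = "high", `F3.2` = "high"))
  expect_identical(male$support, c("P3", "P8"))
  expect_identical(male$precision, 1)
})

test_that("rules are sound: supports satisfy conditions, precision recounts", {
  domains <- pilot_domains()
  cohB <- pilot_before_cohort()
  for (s in 1:6) {
    rule <- list(sex = "F", age_min = 60L, age_max = 65L,
                 levels = c(F2 = "low", `F3.1` = "high"),
                 target_factor = "F2", direction = "high",
                 fraction = 0.12, p_exceed_in = 0.95, p_exceed_out = 0.02)
    spec <- cohort_spec(n = 120, seed = 500 + s, injected_rules = list(rule))
    coh <- generate_cohort(spec)
    cfg <- risk_rule_config(borderline_delta = 0, min_precision = 0.8)
    flags <- risk_scan(cohort_view(coh$roster, coh$after), domains, cfg,
                       phase = "after", harm_stored = c(F2 = "high"))
    cohBs <- cohort_view(coh$roster, coh$before)
    rules <- induce_rules(flags, cohBs, domains, cfg)
    levels <- level_categories(cohBs, domains, cfg)
    flagged <- unique(flags$participant_id)
    for (r in rules) {
      match_ids <- cohBs$participant_id[vapply(seq_len(nrow(cohBs)), function(i) {
        ok <- identical(cohBs$sex[i], r$sex) &&
          cohBs$age[i] >= r$age_min && cohBs$age[i] <= r$age_max
        if (ok && length(r$levels)) {
          lv <- levels[[cohBs$participant_id[i]]]
          for (f in names(r$levels)) {
            if (!identical(unname(lv[f]), unname(r$levels[f]))) ok <- FALSE
          }
        }
        ok
      }, logical(1))]
      expect_true(all(r$support %in% match_ids))
      expect_true(all(r$support %in% flagged))
      expect_identical(r$precision,
                       length(intersect(match_ids, flagged)) / length(match_ids))
      expect_gte(length(r$support), 2L)
    }
  }
})

empty_flags_df <- function() {
  data.frame(participant_id = character(), factor_id = character(),
             phase = character(), observed = numeric(), lower = numeric(),
             upper = numeric(), severity = character(),
             direction = character(), stringsAsFactors = FALSE)
}

test_that("empty flags yield no rules; strategies mirror their rules", {
  run <- pilot_run()
  expect_length(analyze_root_cause(run$network, empty_flags_df(), 1), 0L)
  named <- run$flags[run$flags$factor_id == "F2" &
                       run$flags$participant_id %in%
                       c("P3", "P8", "P23", "P28"), ]
  rules <- analyze_root_cause(run$network, named, 1, risk_rule_config())
  strategies <- develop_strategies(rules, next_cycle = 2L)
  expect_length(strategies, 2L)
  expect_length(develop_strategies(list(), 2L), 0L)
  fx <- pilot_fixture()
  excluded <- apply_strategies(strategies, fx$roster, fx$before,
                               pilot_domains())
  expect_setequal(excluded, c("P3", "P8", "P23", "P28"))
})

test_that("strategy predicates exclude exactly the matching synthetic members", {
  domains <- pilot_domains()
  rule <- list(sex = "M", age_min = 35L, age_max = 40L,
               levels = c(F2 = "high", `F3.2` = "high"),
               target_factor = "F2", direction = "high",
               fraction = 0.15, p_exceed_in = 1.0, p_exceed_out = 0)
  spec <- cohort_spec(n = 150, seed = 901, injected_rules = list(rule))
  coh <- generate_cohort(spec)
  strategy <- list(conditions = list(sex = "M", age_min = 35L, age_max = 40L,
                                     levels = c(F2 = "high", `F3.2` = "high")),
                   strategy_id = "scs-test", action = "exclude")
  excluded <- apply_strategies(list(strategy), coh$roster, coh$before, domains)
  members <- coh$ground_truth$rules[[1]]$members
  expect_true(all(members %in% excluded))
  # non-members may only be excluded if they genuinely match the pattern
  levels <- level_categories(cohort_view(coh$roster, coh$before), domains,
                             risk_rule_config())
  for (pid in setdiff(excluded, members)) {
    i <- which(coh$roster$participant_id == pid)
    expect_identical(coh$roster$sex[i], "M")
    expect_true(coh$roster$age[i] >= 35 && coh$roster$age[i] <= 40)
    expect_identical(unname(levels[[pid]][["F2"]]), "high")
    expect_identical(unname(levels[[pid]][["F3.2"]]), "high")
  }
})

test_that("the closed PDCA loop screens matching participants out of cycle 2", {
  run <- pilot_run()
  fx <- pilot_fixture()
  named <- run$flags[run$flags$factor_id == "F2" &
                       run$flags$participant_id %in%
                       c("P3", "P8", "P23", "P28"), ]
  rules <- analyze_root_cause(run$network, named, 1, risk_rule_config())
  strategies <- develop_strategies(rules, next_cycle = 2L)
  # fresh cycle-2 network planned with the strategies attached
  net2 <- build_network()
  factors <- identify_csa(fx$protocol)
  determine_measurements(fx$protocol, factors, net2)
  net2$local_store$checkable <- c("F1", "F2", "F3.1", "F3.2", "F3.3",
                                  "F3.4", "F5")
  p2 <- fx$protocol
  p2$cycle <- 2L
  identify_safe_domains(p2, factors, prior = strategies, network = net2)
  enrolled <- enroll(net2, fx$roster, cycle = 2L, screening = fx$before)
  expect_setequal(attr(enrolled, "excluded"), c("P3", "P8", "P23", "P28"))
  expect_length(enrolled, 26L)
})
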