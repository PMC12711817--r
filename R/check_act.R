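#' Check and Act units: risk assessment, root-cause analysis, strategies
#'
#' The risk assessor (RA) reads the committed safe domains from the trial
#' ledger and the post-administration transactions from the patient ledger
#' and flags out-of-range and borderline values. Flagged participant ids are
#' forwarded to the root-cause analyzer (RCA), which induces conjunctive
#' subgroup rules over demographics and pre-administration level categories.
#' The strategy developer (SCSD) turns each rule into an exclusion/limitation
#' strategy handed to the next planning cycle.
#'
#' @name check_act_phase
NULL

#' Risk and root-cause configuration
#'
#' @param borderline_delta Named numeric vector (or scalar) of per-factor
#'   borderline margins in factor units; a value inside its safe domain but
#'   within this distance of a harmful bound is flagged `borderline`. 0
#'   disables borderline flagging.
#' @param use_harm_direction When `TRUE` (default) borderline flags are
#'   raised only toward each factor's harmful direction.
#' @param harm_direction Named character vector factor -> `"high"`, `"low"`
#'   or `"both"`; unlisted factors default to `"both"`. `NULL` uses the
#'   directions the plan phase stored from the protocol.
#' @param categorization_margin Named numeric vector (or scalar) of
#'   fractions: a pre-value strictly within this fraction of the domain
#'   width (two-sided domains) or of the bound (one-sided) of a bound is
#'   categorized `low`/`high`. Default 0.10 with a 0.25 override for heart
#'   rate (F2), whose categories in the reference narrative span a wider
#'   band.
#' @param checkable_set Factor ids examined by the risk scan; `NULL` means
#'   all interval-checkable factors.
#' @param min_support Minimum number of flagged participants supporting an
#'   induced rule.
#' @param min_precision Minimum fraction of rule-matching cohort members
#'   that are flagged.
#' @param include_before Also scan pre-administration transactions
#'   (default `FALSE`: the assessor examines post-administration values).
#' @return A `risk_rule_config` list.
#' @export
risk_rule_config <- function(borderline_delta = 1.0,
                             use_harm_direction = TRUE,
                             harm_direction = NULL,
                             categorization_margin = c(default = 0.10, F2 = 0.25),
                             checkable_set = NULL,
                             min_support = 2L,
                             min_precision = 1.0,
                             include_before = FALSE) {
  if (any(borderline_delta < 0)) {
    qbd_stop("qbd_validation_error", "borderline_delta must be non-negative")
  }
  structure(list(
    borderline_delta = borderline_delta,
    use_harm_direction = use_harm_direction,
    harm_direction = harm_direction,
    categorization_margin = categorization_margin,
    checkable_set = checkable_set,
    min_support = as.integer(min_support),
    min_precision = min_precision,
    include_before = include_before
  ), class = "risk_rule_config")
}

cfg_named <- function(vec, fid, default) {
  if (is.null(vec)) return(default)
  if (!is.null(names(vec)) && fid %in% names(vec)) return(unname(vec[[fid]]))
  if (!is.null(names(vec)) && "default" %in% names(vec)) {
    return(unname(vec[["default"]]))
  }
  if (is.null(names(vec))) return(unname(vec[[1]]))
  default
}

cfg_harm <- function(cfg, fid, stored = NULL) {
  hd <- cfg$harm_direction
  if (!is.null(hd) && fid %in% names(hd)) return(unname(hd[[fid]]))
  if (!is.null(stored) && fid %in% names(stored)) return(unname(stored[[fid]]))
  "both"
}

empty_flags <- function() {
  data.frame(participant_id = character(), factor_id = character(),
             phase = character(), observed = numeric(), lower = numeric(),
             upper = numeric(), severity = character(),
             direction = character(), stringsAsFactors = FALSE)
}

#' Scan a value table against safe domains (pure core)
#'
#' Direct interval comparison per (participant, factor): a value violating
#' an inclusive/exclusive bound is `out_of_range`; an in-domain value within
#' the borderline margin of a harmful bound is `borderline`.
#'
#' @param cohort data.frame with `participant_id`, `sex`, `age` and one
#'   column per factor (numeric or decimal strings).
#' @param domains A `safe_domain_set`.
#' @param cfg A [risk_rule_config()].
#' @param phase Phase whose domains apply (`"after"` for the risk scan).
#' @param harm_stored Optional named harm-direction vector from the
#'   protocol.
#' @return Flags data.frame (participant_id, factor_id, phase, observed,
#'   lower, upper, severity, direction).
#' @export
risk_scan <- function(cohort, domains, cfg = risk_rule_config(),
                      phase = "after", harm_stored = NULL) {
  checkable <- cfg$checkable_set %||%
    sort(names(Filter(function(f) identical(f$state_kind, "interval"), domains)))
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$participant_id[i]
    for (fid in checkable) {
      if (!fid %in% names(cohort)) next
      v <- as.numeric(cohort[[fid]][i])
      if (is.na(v)) next
      band <- lookup_domain(domains, fid, cohort$sex[i],
                            as.integer(cohort$age[i]), phase = phase)
      delta <- cfg_named(cfg$borderline_delta, fid, 1.0)
      harm <- if (cfg$use_harm_direction) cfg_harm(cfg, fid, harm_stored)
              else "both"
      ok <- in_domain(v, band)
      severity <- NULL
      direction <- NULL
      if (!isTRUE(ok)) {
        severity <- "out_of_range"
        direction <- attr(ok, "direction")
      } else if (delta > 0) {
        if (harm %in% c("high", "both") && !is.null(band$upper) &&
            band$upper - v <= delta) {
          severity <- "borderline"; direction <- "high"
        } else if (harm %in% c("low", "both") && !is.null(band$lower) &&
                   v - band$lower <= delta) {
          severity <- "borderline"; direction <- "low"
        }
      }
      if (!is.null(severity)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, factor_id = fid, phase = phase,
          observed = v,
          lower = if (is.null(band$lower)) NA_real_ else band$lower,
          upper = if (is.null(band$upper)) NA_real_ else band$upper,
          severity = severity, direction = direction,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty_flags())
  out <- do.call(rbind, rows)
  out <- out[order(order_participants(out$participant_id) * 1000 +
                     match(out$factor_id, sort(unique(out$factor_id)))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assess post-administration risk through the ledger APIs
#'
#' Reads the cycle's safe domains from the trial ledger and the After
#' transactions from the patient ledger (both through the risk assessor's
#' API), scans every checkable factor, and forwards the flagged participant
#' ids to the root-cause analyzer (logged).
#'
#' @param network A `qbd_network`.
#' @param cycle Trial cycle.
#' @param cfg A [risk_rule_config()].
#' @return Flags data.frame with attribute `"flagged_ids"`.
#' @export
assess_risk <- function(network, cycle = 1L, cfg = risk_rule_config()) {
  domains <- read_domains(network, cycle, api_unit = "RA")
  afters <- query_ledger(network, "RA", "channel-2", function(p) {
    identical(p$type, "patient_tx") && identical(p$status, "After") &&
      identical(as.integer(p$cycle), as.integer(cycle))
  })
  if (length(afters) == 0L) {
    qbd_stop("qbd_sequencing_error",
             "no After transactions for cycle %d", cycle)
  }
  cohort <- payloads_to_cohort(afters)
  harm_stored <- network$local_store$harm_direction
  flags <- risk_scan(cohort, domains, cfg, phase = "after",
                     harm_stored = harm_stored)
  if (cfg$include_before) {
    befores <- query_ledger(network, "RA", "channel-2", function(p) {
      identical(p$type, "patient_tx") && identical(p$status, "Before") &&
        identical(as.integer(p$cycle), as.integer(cycle))
    })
    if (length(befores)) {
      fb <- risk_scan(payloads_to_cohort(befores), domains, cfg,
                      phase = "before", harm_stored = harm_stored)
      flags <- rbind(flags, fb)
    }
  }
  ids <- unique(flags$participant_id)
  ids <- ids[order_participants(ids)]
  network_log_append(network, "forward", unit = "RA",
                     detail = sprintf("flagged ids to RCA: %s",
                                      paste(ids, collapse = ",")))
  attr(flags, "flagged_ids") <- ids
  flags
}

payloads_to_cohort <- function(payloads) {
  fids <- sort(unique(unlist(lapply(payloads, function(p) names(p$values)))))
  rows <- lapply(payloads, function(p) {
    vals <- lapply(fids, function(f) {
      v <- p$values[[f]]
      if (is.null(v) || identical(v, "N/A")) NA_real_ else as.numeric(v)
    })
    names(vals) <- fids
    do.call(data.frame, c(list(participant_id = p$participant_id,
                               sex = p$sex, age = as.integer(p$age),
                               stringsAsFactors = FALSE), vals,
                          list(check.names = FALSE)))
  })
  out <- do.call(rbind, rows)
  out <- out[order_participants(out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- level categorization ---------------------------------------------------

level_of <- function(v, band, margin_frac) {
  ok <- in_domain(v, band)
  if (!isTRUE(ok)) return(attr(ok, "direction"))
  two_sided <- !is.null(band$lower) && !is.null(band$upper)
  if (two_sided) {
    m <- margin_frac * (band$upper - band$lower)
    if (v > band$upper - m) return("high")
    if (v < band$lower + m) return("low")
  } else if (!is.null(band$upper)) {
    m <- margin_frac * band$upper
    if (v > band$upper - m) return("high")
  } else if (!is.null(band$lower)) {
    m <- margin_frac * band$lower
    if (v < band$lower + m) return("low")
  }
  "normal"
}

#' Categorize pre-administration levels for a whole cohort (pure core)
#'
#' Assigns `low`/`high` when the pre-value is out of range on that side or
#' strictly within the categorization margin of the corresponding bound,
#' `normal` otherwise.
#'
#' @param cohort data.frame with `participant_id`, `sex`, `age` and factor
#'   columns of pre-administration values.
#' @param domains A `safe_domain_set`.
#' @param cfg A [risk_rule_config()].
#' @return Named list: participant id -> named character vector
#'   (factor -> level).
#' @export
level_categories <- function(cohort, domains, cfg = risk_rule_config()) {
  checkable <- cfg$checkable_set %||%
    sort(names(Filter(function(f) identical(f$state_kind, "interval"), domains)))
  checkable <- intersect(checkable, names(cohort))
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    lv <- character(0)
    for (fid in checkable) {
      v <- as.numeric(cohort[[fid]][i])
      if (is.na(v)) next
      band <- lookup_domain(domains, fid, cohort$sex[i],
                            as.integer(cohort$age[i]), phase = "before")
      frac <- cfg_named(cfg$categorization_margin, fid, 0.10)
      lv[[fid]] <- level_of(v, band, frac)
    }
    out[[cohort$participant_id[i]]] <- lv
  }
  out
}

#' Categorize one participant's pre-administration levels via the ledger
#'
#' @param network A `qbd_network`.
#' @param participant_id Participant code.
#' @param cfg A [risk_rule_config()].
#' @param cycle Trial cycle.
#' @return Named character vector factor -> `low`/`normal`/`high`.
#' @export
categorize_levels <- function(network, participant_id,
                              cfg = risk_rule_config(), cycle = 1L) {
  before <- query_ledger(network, "RCA", "channel-2", function(p) {
    identical(p$type, "patient_tx") && identical(p$status, "Before") &&
      identical(p$participant_id, participant_id) &&
      identical(as.integer(p$cycle), as.integer(cycle))
  })
  if (length(before) == 0L) {
    qbd_stop("qbd_sequencing_error",
             "participant %s has no Before transaction in cycle %d",
             participant_id, cycle)
  }
  domains <- read_domains(network, cycle, api_unit = "RCA")
  cohort <- payloads_to_cohort(before)
  level_categories(cohort, domains, cfg)[[participant_id]]
}

# ---- rule induction ---------------------------------------------------------

snap5 <- function(lo, hi) {
  c(5L * (lo %/% 5L), 5L * as.integer(ceiling(hi / 5)))
}

# Safe lookup in a named level vector (NA when the factor is absent).
lv_get <- function(lv, fid) {
  if (is.null(lv) || !fid %in% names(lv)) NA_character_ else unname(lv[[fid]])
}

rule_matches_vec <- function(sex, age_win, levels_req, cohort, levels) {
  vapply(seq_len(nrow(cohort)), function(i) {
    if (!identical(cohort$sex[i], sex)) return(FALSE)
    a <- cohort$age[i]
    if (a < age_win[1] || a > age_win[2]) return(FALSE)
    lv <- levels[[cohort$participant_id[i]]]
    for (fid in names(levels_req)) {
      if (!identical(lv_get(lv, fid), unname(levels_req[[fid]]))) return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' Induce root-cause subgroup rules (pure core)
#'
#' Deterministic concretization of the narrative procedure: (1) categorize
#' pre-administration levels for the full cohort; (2) partition the flagged
#' participants by sex; (3) grow candidate subgroups greedily by shared
#' level conditions (not the full powerset); (4) each subgroup yields the
#' conjunction of its sex, the tightest enclosing age interval snapped
#' outward to multiples of 5 years, and every non-normal pre-level shared by
#' all members; (5) precision is the fraction of all cohort members
#' satisfying the conditions that are flagged; (6) rules meeting the support
#' and precision thresholds are kept, maximal ones first, ties broken by
#' lexicographic participant ids.
#'
#' @param flags Flags data.frame from [risk_scan()]/[assess_risk()].
#' @param cohort Pre-administration cohort data.frame (`participant_id`,
#'   `sex`, `age`, factor columns).
#' @param domains A `safe_domain_set`.
#' @param cfg A [risk_rule_config()].
#' @return List of `root_cause_rule` objects: sex, age_min, age_max,
#'   levels (named factor -> level), support (participant ids), precision,
#'   n_matching.
#' @export
induce_rules <- function(flags, cohort, domains, cfg = risk_rule_config()) {
  if (nrow(flags) == 0L) return(list())
  levels <- level_categories(cohort, domains, cfg)
  flagged <- sort(unique(flags$participant_id))
  rules <- list()
  seen <- character(0)
  for (sex in sort(unique(cohort$sex[cohort$participant_id %in% flagged]))) {
    g0 <- sort(intersect(flagged,
                         cohort$participant_id[cohort$sex == sex]))
    if (length(g0) < cfg$min_support) next
    # breadth-first refinement by shared non-normal level conditions
    frontier <- list(g0)
    cand <- list(g0)
    cand_keys <- paste(g0, collapse = ",")
    depth <- 0L
    while (length(frontier) && depth < 4L) {
      depth <- depth + 1L
      nxt <- list()
      for (S in frontier) {
        conds <- unique(unlist(lapply(S, function(pid) {
          lv <- levels[[pid]]
          paste0(names(lv)[lv != "normal"], "=", lv[lv != "normal"])
        })))
        for (cstr in sort(conds)) {
          parts <- strsplit(cstr, "=", fixed = TRUE)[[1]]
          Sc <- Filter(function(pid) {
            identical(lv_get(levels[[pid]], parts[1]), parts[2])
          }, S)
          key <- paste(Sc, collapse = ",")
          if (length(Sc) >= cfg$min_support && !key %in% cand_keys) {
            cand <- c(cand, list(Sc))
            cand_keys <- c(cand_keys, key)
            nxt <- c(nxt, list(Sc))
          }
        }
      }
      frontier <- nxt
    }
    for (S in cand) {
      ages <- cohort$age[match(S, cohort$participant_id)]
      win <- snap5(min(ages), max(ages))
      shared <- NULL
      first <- levels[[S[[1]]]]
      for (fid in names(first)) {
        lv <- vapply(S, function(pid) {
          x <- levels[[pid]][[fid]]
          if (is.null(x)) "" else x
        }, character(1))
        if (all(lv == lv[[1]]) && lv[[1]] != "normal" && nzchar(lv[[1]])) {
          shared[[fid]] <- lv[[1]]
        }
      }
      match_vec <- rule_matches_vec(sex, win, shared, cohort, levels)
      matching <- cohort$participant_id[match_vec]
      support <- sort(intersect(matching, flagged))
      if (length(support) < cfg$min_support) next
      precision <- length(support) / length(matching)
      if (precision < cfg$min_precision) next
      rule_key <- paste(sex, win[1], win[2],
                        paste(names(shared), unlist(shared), sep = "=",
                              collapse = "&"), sep = "|")
      if (rule_key %in% seen) next
      seen <- c(seen, rule_key)
      rules[[length(rules) + 1L]] <- structure(list(
        sex = sex, age_min = win[1], age_max = win[2],
        levels = if (is.null(shared)) character(0) else unlist(shared),
        support = support, precision = precision,
        n_matching = length(matching)
      ), class = "root_cause_rule")
    }
  }
  if (length(rules) == 0L) return(list())
  # order: precision desc, support size desc, lexicographic support ids;
  # keep maximal rules (support not strictly contained in an earlier rule's)
  ord <- order(-vapply(rules, `[[`, numeric(1), "precision"),
               -vapply(rules, function(r) length(r$support), integer(1)),
               vapply(rules, function(r) paste(r$support, collapse = ","),
                      character(1)))
  rules <- rules[ord]
  kept <- list()
  for (r in rules) {
    sub <- any(vapply(kept, function(k) {
      all(r$support %in% k$support) && length(r$support) <= length(k$support)
    }, logical(1)))
    if (!sub) kept <- c(kept, list(r))
  }
  kept
}

#' @export
print.root_cause_rule <- function(x, ...) {
  lv <- if (length(x$levels)) {
    paste(names(x$levels), unname(x$levels), sep = "-pre ", collapse = ", ")
  } else "(no level conditions)"
  cat(sprintf("<rule: sex %s, age %d-%d, %s | support {%s}, precision %.2f>\n",
              x$sex, x$age_min, x$age_max, lv,
              paste(x$support, collapse = ", "), x$precision))
  invisible(x)
}

#' Root-cause analysis through the ledger APIs
#'
#' Reads the flagged participants' transactions and demographics from the
#' patient ledger and the safe domains from the trial ledger (root-cause
#' analyzer API), then induces subgroup rules over the *full* cohort so
#' precision is computed against everyone enrolled.
#'
#' @param network A `qbd_network`.
#' @param flags Flags data.frame from [assess_risk()].
#' @param cycle Trial cycle.
#' @param cfg A [risk_rule_config()].
#' @return List of `root_cause_rule`s (empty when `flags` is empty).
#' @export
analyze_root_cause <- function(network, flags, cycle = 1L,
                               cfg = risk_rule_config()) {
  if (is.null(flags) || nrow(flags) == 0L) return(list())
  befores <- query_ledger(network, "RCA", "channel-2", function(p) {
    identical(p$type, "patient_tx") && identical(p$status, "Before") &&
      identical(as.integer(p$cycle), as.integer(cycle))
  })
  domains <- read_domains(network, cycle, api_unit = "RCA")
  cohort <- payloads_to_cohort(befores)
  induce_rules(flags, cohort, domains, cfg)
}

# ---- strategies -------------------------------------------------------------

#' Develop safety control strategies from induced rules
#'
#' One strategy per rule, default action `exclude`: the rule's conditions
#' become an eligibility predicate for the next cycle's plan phase.
#' Strategies live in the LOCAL store; they reach the ledger only inside the
#' next cycle's committed safe-domain payloads.
#'
#' @param rules List of `root_cause_rule`s.
#' @param next_cycle Cycle the strategies target.
#' @param action `"exclude"` or `"limit"`.
#' @param network Optional network whose LOCAL store receives the
#'   strategies.
#' @return List of `control_strategy` objects.
#' @export
develop_strategies <- function(rules, next_cycle, action = "exclude",
                               network = NULL) {
  out <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    structure(list(
      strategy_id = sprintf("scs-c%d-%02d", as.integer(next_cycle), i),
      source_rule = r,
      action = action,
      conditions = list(sex = r$sex, age_min = r$age_min, age_max = r$age_max,
                        levels = r$levels),
      target_cycle = as.integer(next_cycle)
    ), class = "control_strategy")
  })
  if (!is.null(network)) {
    network$local_store$strategies[[as.character(next_cycle)]] <- out
  }
  out
}

# A strategy (or its on-ledger predicate form) matches a participant iff
# sex, age window and every required pre-level all hold.
strategy_matches <- function(strategy, sex, age, levels) {
  cond <- strategy$conditions %||% strategy
  if (!is.null(cond$sex) && nzchar(cond$sex) &&
      !identical(cond$sex, sex)) return(FALSE)
  if (!is.null(cond$age_min) && age < as.integer(cond$age_min)) return(FALSE)
  if (!is.null(cond$age_max) && age > as.integer(cond$age_max)) return(FALSE)
  req <- cond$levels
  if (length(req)) {
    for (fid in names(req)) {
      if (!identical(lv_get(levels, fid), unname(req[[fid]]))) return(FALSE)
    }
  }
  TRUE
}

#' Apply control strategies to a candidate roster
#'
#' @param strategies List of `control_strategy`s (or the predicate lists
#'   read back from safe-domain payloads).
#' @param roster data.frame with `participant_id`, `sex`, `age`.
#' @param before data.frame of pre-administration values.
#' @param domains A `safe_domain_set`.
#' @param cfg A [risk_rule_config()].
#' @return Character vector of excluded participant ids.
#' @export
apply_strategies <- function(strategies, roster, before, domains,
                             cfg = risk_rule_config()) {
  if (length(strategies) == 0L) return(character(0))
  levels <- level_categories(merge_cohort(roster, before), domains, cfg)
  out <- character(0)
  for (i in seq_len(nrow(roster))) {
    pid <- roster$participant_id[i]
    for (s in strategies) {
      if (strategy_matches(s, roster$sex[i], roster$age[i], levels[[pid]])) {
        out <- c(out, pid)
        break
      }
    }
  }
  out
}

merge_cohort <- function(roster, values) {
  m <- merge(roster[, c("participant_id", "sex", "age")], values,
             by = "participant_id", sort = FALSE)
  m[order_participants(m$participant_id), , drop = FALSE]
}

strategies_from_payloads <- function(dom_payloads) {
  out <- list()
  seen <- character(0)
  for (p in dom_payloads) {
    for (s in p$strategies %||% list()) {
      if (s$strategy_id %in% seen) next
      seen <- c(seen, s$strategy_id)
      out[[length(out) + 1L]] <- list(
        strategy_id = s$strategy_id, action = s$action,
        conditions = list(
          sex = s$sex %||% "",
          age_min = as.integer(s$age_min), age_max = as.integer(s$age_max),
          levels = unlist(s$levels)
        )
      )
    }
  }
  out
}

#' Export flags or rules as CSV/JSON with stable column order
#'
#' @param flags Flags data.frame.
#' @param rules List of `root_cause_rule`s.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @export
write_flag_report <- function(flags, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(flags, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(flags, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_flag_report
#' @export
write_rule_report <- function(rules, path) {
  recs <- lapply(rules, function(r) list(
    sex = r$sex, age_min = r$age_min, age_max = r$age_max,
    levels = as.list(r$levels), support = as.list(r$support),
    precision = r$precision, n_matching = r$n_matching
  ))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- do.call(rbind, lapply(recs, function(r) data.frame(
      sex = r$sex, age_min = r$age_min, age_max = r$age_max,
      levels = paste(names(r$levels), unlist(r$levels), sep = "=",
                     collapse = ";"),
      support = paste(unlist(r$support), collapse = ";"),
      precision = r$precision, n_matching = r$n_matching,
      stringsAsFactors = FALSE
    )))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
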