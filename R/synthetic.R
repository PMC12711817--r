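#' Fixtures and synthetic cohorts
#'
#' Ships the 30-participant pilot-trial fixture (protocol + roster with
#' pre/post measurements) and generates seeded synthetic cohorts with the
#' statistical structure the risk-assessment and root-cause analytics
#' assume: demographics, in-domain measurements drawn from a truncated
#' normal around each participant's resolved domain midpoint, and
#' injectable "unsafe subgroup" patterns with known ground truth.
#'
#' @name synthetic_data
NULL

# Pinned SHA-256 checksums of the shipped fixture files.
PILOT_CHECKSUMS <- c(
  pilot_protocol.yaml = "be498a67cda9b8c4e36ddb42950cbb5e7cf9b527ab9b9f38cee4a78e27725e30",
  pilot_trial.csv = "94ff0c9f60285f8b6479ab22e4caa120cdf3ea1ca75d83cb6e88d37f57c4d303"
)

file_sha256 <- function(path) {
  sha256_hex(readBin(path, "raw", n = file.info(path)$size))
}

#' Load the pilot-trial fixture
#'
#' Returns the structured protocol (factors, measurement procedures, safe
#' domains) and the 30-row roster with pre/post measurement tables. File
#' checksums are pinned; a mismatch raises a corrupted-fixture error.
#'
#' @param check Verify the pinned checksums (default `TRUE`).
#' @return List with `protocol`, `roster`, `before`, `after`, `notes`, and
#'   the fixture file `paths`.
#' @export
load_pilot_fixture <- function(check = TRUE) {
  proto_path <- system.file("extdata", "pilot_protocol.yaml",
                            package = "qbdchain", mustWork = TRUE)
  trial_path <- system.file("extdata", "pilot_trial.csv",
                            package = "qbdchain", mustWork = TRUE)
  if (check) {
    for (p in c(proto_path, trial_path)) {
      expect <- PILOT_CHECKSUMS[[basename(p)]]
      got <- file_sha256(p)
      if (!identical(got, expect)) {
        qbd_stop("qbd_integrity_error",
                 "fixture %s is corrupted (checksum %s != %s)",
                 basename(p), got, expect)
      }
    }
  }
  protocol <- read_protocol(proto_path)
  cohort <- read_cohort(trial_path)
  c(cohort, list(protocol = protocol,
                 paths = c(protocol = proto_path, trial = trial_path)))
}

COHORT_FACTORS <- c("F1", "F2", "F3.1", "F3.2", "F3.3", "F3.4", "F4", "F5")

#' Read / write a cohort CSV
#'
#' Schema: `Participant,Sex,Age,Weight`, the before-phase factor columns,
#' the same columns suffixed `_after`, and a trailing `flag_note` column
#' carrying source annotations (never computed on). Measurement values are
#' kept as decimal strings so round trips are lossless.
#'
#' @param path CSV file path.
#' @return `read_cohort`: list with `roster` (participant_id, sex, age,
#'   weight), `before` and `after` value tables (decimal-string columns),
#'   and `notes`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    qbd_stop("qbd_parse_error", "cohort file '%s' does not exist", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  need <- c("Participant", "Sex", "Age", "Weight", COHORT_FACTORS,
            paste0(COHORT_FACTORS, "_after"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    qbd_stop("qbd_parse_error", "cohort file '%s' is missing column(s): %s",
             path, paste(miss, collapse = ", "))
  }
  bad_age <- which(!grepl("^[0-9]+$", df$Age))
  if (length(bad_age)) {
    qbd_stop("qbd_parse_error", "non-integer Age at row %d", bad_age[1])
  }
  roster <- data.frame(participant_id = df$Participant, sex = df$Sex,
                       age = as.integer(df$Age), weight = df$Weight,
                       stringsAsFactors = FALSE)
  before <- df[, c("Participant", COHORT_FACTORS)]
  names(before) <- c("participant_id", COHORT_FACTORS)
  after <- df[, c("Participant", paste0(COHORT_FACTORS, "_after"))]
  names(after) <- c("participant_id", COHORT_FACTORS)
  notes <- if ("flag_note" %in% names(df)) df$flag_note else
    rep("", nrow(df))
  list(roster = roster, before = before, after = after, notes = notes)
}

#' @rdname read_cohort
#' @param cohort A cohort list (`roster`, `before`, `after`, optional
#'   `notes`, optional `ground_truth`).
#' @param ground_truth_path Optional JSON path for the generator's ground
#'   truth.
#' @export
write_cohort <- function(cohort, path, ground_truth_path = NULL) {
  r <- cohort$roster
  b <- cohort$before
  a <- cohort$after
  stopifnot(identical(r$participant_id, b$participant_id),
            identical(r$participant_id, a$participant_id))
  df <- data.frame(Participant = r$participant_id, Sex = r$sex,
                   Age = as.character(r$age), Weight = as.character(r$weight),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (f in COHORT_FACTORS) df[[f]] <- as.character(b[[f]])
  for (f in COHORT_FACTORS) df[[paste0(f, "_after")]] <- as.character(a[[f]])
  df$flag_note <- cohort$notes %||% rep("", nrow(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(ground_truth_path) && !is.null(cohort$ground_truth)) {
    jsonlite::write_json(cohort$ground_truth, ground_truth_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Specify a synthetic cohort
#'
#' @param n Cohort size.
#' @param seed Integer seed; the same (spec, seed) pair reproduces the
#'   cohort byte-for-byte.
#' @param sex_fraction_f Probability a participant is female.
#' @param age_range Integer `[min, max]` years.
#' @param weight_range Integer `[min, max]` kg.
#' @param cv Coefficient of variation of the truncated-normal value model
#'   (scalar or named per factor).
#' @param injected_rules List of injected unsafe-subgroup patterns, each a
#'   list with `sex`, `age_min`, `age_max`, `levels` (named factor ->
#'   `low`/`high` pre-level pattern), `target_factor`, `direction`
#'   (`high`/`low`), `fraction` (membership probability), `p_exceed_in`,
#'   `p_exceed_out`.
#' @param protocol A `trial_protocol` providing the domains; default the
#'   pilot protocol.
#' @param cfg [risk_rule_config()] whose categorization margins the injected
#'   pre-level patterns must satisfy.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 100L, seed = 1L, sex_fraction_f = 0.5,
                        age_range = c(18L, 75L), weight_range = c(55L, 95L),
                        cv = 0.10, injected_rules = list(),
                        protocol = NULL, cfg = risk_rule_config()) {
  if (sex_fraction_f < 0 || sex_fraction_f > 1) {
    qbd_stop("qbd_validation_error", "sex_fraction_f must be in [0, 1]")
  }
  for (r in injected_rules) {
    for (p in c(r$fraction, r$p_exceed_in, r$p_exceed_out)) {
      if (p < 0 || p > 1) {
        qbd_stop("qbd_validation_error",
                 "injected-rule probabilities must be in [0, 1]")
      }
    }
    if (r$age_min < age_range[1] || r$age_max > age_range[2]) {
      qbd_stop("qbd_validation_error",
               "injected-rule age window [%d, %d] outside cohort age range",
               r$age_min, r$age_max)
    }
  }
  if (is.null(protocol)) {
    protocol <- read_protocol(system.file("extdata", "pilot_protocol.yaml",
                                          package = "qbdchain",
                                          mustWork = TRUE))
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 sex_fraction_f = sex_fraction_f,
                 age_range = as.integer(age_range),
                 weight_range = as.integer(weight_range),
                 cv = cv, injected_rules = injected_rules,
                 protocol = protocol, cfg = cfg),
            class = "cohort_spec")
}

# Integer bounds of a band under its inclusivity flags.
band_int_bounds <- function(band) {
  lo <- if (is.null(band$lower)) NA_integer_ else {
    l <- ceiling(band$lower)
    if (!isTRUE(band$lower_inclusive) && l == band$lower) l + 1L else l
  }
  hi <- if (is.null(band$upper)) NA_integer_ else {
    u <- floor(band$upper)
    if (!isTRUE(band$upper_inclusive) && u == band$upper) u - 1L else u
  }
  c(as.integer(lo), as.integer(hi))
}

# Largest integer strictly below x (region boundaries of level categories).
int_below <- function(x) if (x == trunc(x)) as.integer(x - 1) else as.integer(floor(x))
# Smallest integer strictly above x.
int_above <- function(x) if (x == trunc(x)) as.integer(x + 1) else as.integer(ceiling(x))

# Integer range of the low/high/normal region of a band under the
# categorization margin; mirrors level_of() exactly.
level_region <- function(band, level, margin_frac) {
  ib <- band_int_bounds(band)
  lo <- ib[1]; hi <- ib[2]
  if (level == "low") {
    stopifnot(!is.na(lo))
    m <- if (!is.na(hi)) margin_frac * (band$upper - band$lower)
         else margin_frac * band$lower
    c(lo, min(int_below(band$lower + m), if (is.na(hi)) int_below(band$lower + m) else hi))
  } else if (level == "high") {
    stopifnot(!is.na(hi))
    m <- if (!is.na(lo)) margin_frac * (band$upper - band$lower)
         else margin_frac * band$upper
    c(max(int_above(band$upper - m), if (is.na(lo)) int_above(band$upper - m) else lo), hi)
  } else {
    stop("level_region supports low/high")
  }
}

# Truncated-normal integer draw inside a band (midpoint center, cv*center
# sd; one-sided domains center 1.5 sd inside the bound).
draw_in_domain <- function(band, cv) {
  ib <- band_int_bounds(band)
  lo <- ib[1]; hi <- ib[2]
  if (!is.na(lo) && !is.na(hi)) {
    center <- (band$lower + band$upper) / 2
    sd <- max(cv * center, 0.5)
  } else if (!is.na(hi)) {
    sd <- max(cv * band$upper, 0.5)
    center <- band$upper - 1.5 * sd
    lo <- as.integer(max(1, floor(center - 4 * sd)))
  } else {
    sd <- max(cv * band$lower, 0.5)
    center <- band$lower + 1.5 * sd
    hi <- as.integer(ceiling(center + 4 * sd))
  }
  v <- as.integer(round(stats::rnorm(1, center, sd)))
  min(max(v, lo), hi)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Demographics are sampled per the spec; pre-administration values are
#' drawn from a truncated normal around each participant's resolved domain
#' midpoint (so the low/normal/high level categories are all populated);
#' members of an injected rule receive demographics and pre-level patterns
#' matching the rule exactly, and post-administration values exceeding the
#' harmful bound of the rule's target factor with the stated in-group
#' probability (non-members with the baseline probability). All randomness
#' flows from the single seed; emitted values are integers, so files are
#' byte-stable across platforms.
#'
#' @param spec A [cohort_spec()].
#' @return List with `roster`, `before`, `after`, `notes`, and
#'   `ground_truth` (rule membership and per-participant exceedance
#'   outcomes).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  domains <- domains_from_protocol(spec$protocol)
  checkable <- checkable_ids(identify_csa(spec$protocol))
  n <- spec$n
  ids <- paste0("P", seq_len(n))
  sex <- ifelse(stats::runif(n) < spec$sex_fraction_f, "F", "M")
  age <- sample(spec$age_range[1]:spec$age_range[2], n, replace = TRUE)
  weight <- sample(spec$weight_range[1]:spec$weight_range[2], n,
                   replace = TRUE)
  membership <- rep(0L, n)  # 0 = none, otherwise index of injected rule
  for (ri in seq_along(spec$injected_rules)) {
    r <- spec$injected_rules[[ri]]
    pick <- membership == 0L & stats::runif(n) < r$fraction
    membership[pick] <- ri
    sex[pick] <- r$sex
    age[pick] <- sample(r$age_min:r$age_max, sum(pick), replace = TRUE)
  }
  before <- after <- data.frame(participant_id = ids,
                                stringsAsFactors = FALSE)
  for (f in COHORT_FACTORS) before[[f]] <- after[[f]] <- NA_integer_
  exceeded <- stats::setNames(rep(FALSE, n), ids)
  for (i in seq_len(n)) {
    ri <- membership[i]
    rule <- if (ri > 0L) spec$injected_rules[[ri]] else NULL
    for (f in COHORT_FACTORS) {
      cvf <- cfg_named(spec$cv, f, 0.10)
      b_band <- lookup_domain(domains, f, sex[i], age[i], phase = "before")
      a_band <- lookup_domain(domains, f, sex[i], age[i], phase = "after")
      if (!is.null(rule) && f %in% names(rule$levels) && f %in% checkable) {
        frac <- cfg_named(spec$cfg$categorization_margin, f, 0.10)
        reg <- level_region(b_band, rule$levels[[f]], frac)
        before[[f]][i] <- sample(reg[1]:reg[2], 1)
      } else {
        before[[f]][i] <- draw_in_domain(b_band, cvf)
      }
      is_target <- length(spec$injected_rules) && f %in%
        vapply(spec$injected_rules, `[[`, character(1), "target_factor")
      p_exc <- if (!is.null(rule) && identical(f, rule$target_factor)) {
        rule$p_exceed_in
      } else if (is_target) {
        # baseline exceedance applies to the target factor of some rule
        max(vapply(spec$injected_rules, function(r)
          if (identical(r$target_factor, f)) r$p_exceed_out else 0,
          numeric(1)))
      } else 0
      if (f %in% checkable && stats::runif(1) < p_exc) {
        dirn <- if (!is.null(rule) && identical(f, rule$target_factor)) {
          rule$direction
        } else {
          tf <- Filter(function(r) identical(r$target_factor, f),
                       spec$injected_rules)
          tf[[1]]$direction
        }
        ib <- band_int_bounds(a_band)
        width <- if (!is.na(ib[1]) && !is.na(ib[2])) ib[2] - ib[1] else 30L
        step <- sample(seq_len(max(2L, as.integer(0.15 * width))), 1)
        after[[f]][i] <- if (identical(dirn, "low")) ib[1] - step
                         else ib[2] + step
        exceeded[[ids[i]]] <- TRUE
      } else {
        after[[f]][i] <- draw_in_domain(a_band, cvf)
      }
    }
  }
  roster <- data.frame(participant_id = ids, sex = sex, age = age,
                       weight = weight, stringsAsFactors = FALSE)
  gt <- list(
    rules = lapply(seq_along(spec$injected_rules), function(ri) {
      r <- spec$injected_rules[[ri]]
      list(sex = r$sex, age_min = r$age_min, age_max = r$age_max,
           levels = as.list(r$levels), target_factor = r$target_factor,
           direction = r$direction,
           members = ids[membership == ri])
    }),
    exceeded = as.list(exceeded)
  )
  for (f in COHORT_FACTORS) {
    before[[f]] <- as.character(before[[f]])
    after[[f]] <- as.character(after[[f]])
  }
  list(roster = roster, before = before, after = after,
       notes = rep("", n), ground_truth = gt)
}
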