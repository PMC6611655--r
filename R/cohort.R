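#' Eligibility filter: continuous enrollment and long-term care
#'
#' Keeps members having at least one enrollment span strictly longer than
#' five calendar years and not flagged as long-term-care residents (LTC
#' residence is strongly associated with pre-existing, possibly
#' under-coded, dementia). Records both steps, in that order, in an
#' exclusion ledger.
#'
#' @param members member table (`member_id`, `birth_year`, `gender`,
#'   `ltc_flag`).
#' @param spans enrollment spans (`member_id`, `start_date`, `end_date`).
#' @return list with `members` (the eligible members, augmented with
#'   `eligible_span_start`/`eligible_span_end`, the earliest span longer
#'   than five years) and `ledger`.
#' @export
filter_eligible <- function(members, spans) {
  members <- as.data.table(members)
  spans <- as.data.table(spans)
  led <- exclusion_ledger(nrow(members), "all_members")

  long_spans <- spans[end_date > add_years(start_date, 5L)]
  setorderv(long_spans, c("member_id", "start_date"))
  first_long <- long_spans[, .(eligible_span_start = start_date[1L],
                               eligible_span_end = end_date[1L]),
                           by = member_id]
  keep <- members[member_id %chin% first_long$member_id]
  led <- ledger_add(led, "enrollment_under_5y", nrow(members) - nrow(keep))

  n_before <- nrow(keep)
  keep <- keep[ltc_flag == FALSE]
  led <- ledger_add(led, "long_term_care", n_before - nrow(keep))

  keep <- merge(keep, first_long, by = "member_id", sort = FALSE)
  list(members = keep[], ledger = led)
}

#' Empirical percentiles of case enrollment-to-index durations
#'
#' Computes the 101 nearest-rank percentiles (0, 1, ..., 100) of the
#' case durations from enrollment start to index date, in days. The 0th
#' percentile is the minimum and the 100th the maximum. Controls are later
#' assigned one of these 101 values uniformly at random, so their
#' enrollment-duration distribution matches the cases'.
#'
#' @param durations numeric vector of case durations in days (>= 1 value).
#' @return Named numeric vector of length 101 (names `"0"`..`"100"`) of
#'   class `percentile_table`; nondecreasing by construction.
#' @export
enrollment_duration_percentiles <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) == 0L || anyNA(durations)) {
    stop("`durations` must be a non-empty vector without NAs")
  }
  s <- sort(durations)
  n <- length(s)
  idx <- pmax(1L, as.integer(ceiling((0:100) / 100 * n)))
  structure(setNames(s[idx], 0:100), class = "percentile_table")
}

#' Assign index dates to controls by sampled enrollment duration
#'
#' Each control draws one of the 101 percentile durations uniformly at
#' random (seeded); the control's index date is its eligible span start
#' plus that duration. Controls whose index date falls after their span end
#' are dropped and counted in the ledger as `outside_coverage`.
#'
#' @param controls `data.table` with `member_id`, `eligible_span_start`,
#'   `eligible_span_end` (as produced by [filter_eligible()]).
#' @param table a [enrollment_duration_percentiles()] table.
#' @param seed integer seed; fixed seed gives identical assignments.
#' @return list with `assignments` (`member_id`, `duration_days`,
#'   `index_date` for retained controls) and `ledger`.
#' @export
assign_control_index_dates <- function(controls, table, seed = 1L) {
  stopifnot(inherits(table, "percentile_table"))
  controls <- as.data.table(controls)
  set.seed(as.integer(seed))
  n <- nrow(controls)
  led <- exclusion_ledger(n, "eligible_controls")
  if (n == 0L) {
    return(list(assignments = data.table(member_id = character(0),
                                         duration_days = numeric(0),
                                         index_date = as.Date(character(0))),
                ledger = led))
  }
  dur <- unname(table[sample.int(101L, n, replace = TRUE)])
  out <- controls[, .(member_id,
                      duration_days = dur,
                      index_date = eligible_span_start + dur,
                      eligible_span_end)]
  dropped <- out[index_date > eligible_span_end, .N]
  out <- out[index_date <= eligible_span_end][, eligible_span_end := NULL]
  led <- ledger_add(led, "outside_coverage", dropped)
  list(assignments = out[], ledger = led)
}

#' Ordered cohort exclusions with ledger
#'
#' Applies named exclusion rules in order to a cohort with index dates and
#' returns the surviving cohort plus the ledger. Supported rules:
#' \describe{
#'   \item{no_confirmation}{drop members whose qualifying events never
#'     satisfy a confirmation criterion (`is_case` is `FALSE` in the
#'     determinations).}
#'   \item{short_preindex_enrollment_or_under_45}{drop confirmed cases that
#'     are not incident (washout/enrollment failure) or younger than
#'     `min_age` at index; reported as one combined step.}
#'   \item{under_45}{drop members younger than `min_age` at index.}
#'   \item{no_claims}{drop members with no medical or pharmacy claim in the
#'     feature window (days 1096-1825 before index).}
#'   \item{outside_coverage}{drop members whose index date lies outside
#'     every enrollment span.}
#' }
#'
#' @param cohort `data.table` with `member_id` and `index_date`.
#' @param rules character vector of rule names, applied in order.
#' @param dataset the `claims_dataset`.
#' @param determinations output of [phenotype_population()] (needed for the
#'   confirmation/washout rules).
#' @param min_age minimum age at index (default 45).
#' @return list with `cohort` and `ledger`.
#' @export
apply_exclusions <- function(cohort, rules, dataset, determinations = NULL,
                             min_age = 45L) {
  cohort <- as.data.table(cohort)
  members <- as.data.table(dataset$members)
  spans <- as.data.table(dataset$spans)
  known <- c("no_confirmation", "short_preindex_enrollment_or_under_45",
             "under_45", "no_claims", "outside_coverage")
  if (length(setdiff(rules, known))) {
    stop("configuration error: unknown exclusion rule(s): ",
         paste(setdiff(rules, known), collapse = ", "))
  }
  age_at_index <- function(ch) {
    by <- members[match(ch$member_id, member_id), birth_year]
    data.table::year(ch$index_date) - by
  }
  led <- exclusion_ledger(nrow(cohort), "cohort")
  for (r in rules) {
    drop <- switch(r,
      no_confirmation = {
        if (is.null(determinations)) stop("rule 'no_confirmation' needs `determinations`")
        d <- determinations[match(cohort$member_id, member_id)]
        !(d$is_case %in% TRUE)
      },
      short_preindex_enrollment_or_under_45 = {
        if (is.null(determinations)) {
          stop("rule 'short_preindex_enrollment_or_under_45' needs `determinations`")
        }
        d <- determinations[match(cohort$member_id, member_id)]
        !(d$status %in% "incident") | age_at_index(cohort) < min_age
      },
      under_45 = age_at_index(cohort) < min_age,
      no_claims = {
        has <- members_with_window_claims(cohort, dataset)
        !(cohort$member_id %chin% has)
      },
      outside_coverage = {
        ok <- spans[cohort, on = .(member_id, start_date <= index_date,
                                   end_date >= index_date),
                    nomatch = NULL, x.member_id]
        is.na(cohort$index_date) | !(cohort$member_id %chin% ok)
      }
    )
    drop[is.na(drop)] <- TRUE
    led <- ledger_add(led, r, sum(drop))
    cohort <- cohort[!drop]
  }
  list(cohort = cohort[], ledger = led)
}

# member ids having at least one claim in the 1096-1825-day pre-index window
members_with_window_claims <- function(cohort, dataset) {
  med <- window_claims(dataset$medical_claims, cohort, date_col = "service_date")
  phr <- window_claims(dataset$pharmacy_claims, cohort, date_col = "fill_date")
  unique(c(med$member_id, phr$member_id))
}

#' Train/test split of cases and controls
#'
#' Draws a seeded simple random sample of the cases (and, independently,
#' the same fraction of controls) into the test set; everyone else trains.
#' Sample sizes are rounded half-up. Because control index dates were drawn
#' from the case enrollment-duration percentiles, test controls are
#' enrollment-duration matched to cases by construction; no age or gender
#' matching is applied to the test set.
#'
#' @param case_ids,control_ids character vectors of member ids.
#' @param test_fraction fraction of each arm assigned to test, in `[0, 1]`.
#' @param seed integer seed.
#' @return `data.table` with `member_id`, `role` (`case`/`control`),
#'   `split` (`train`/`test`).
#' @export
split_train_test <- function(case_ids, control_ids, test_fraction = 0.3,
                             seed = 1L) {
  if (is.na(test_fraction) || test_fraction < 0 || test_fraction > 1) {
    stop("`test_fraction` must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  take <- function(ids) {
    n_test <- as.integer(floor(length(ids) * test_fraction + 0.5))
    test <- if (n_test > 0L) sample(ids, n_test) else character(0)
    data.table(member_id = ids, split = fifelse(ids %chin% test, "test", "train"))
  }
  out <- rbind(take(case_ids)[, role := "case"],
               take(control_ids)[, role := "control"])
  setcolorder(out, c("member_id", "role", "split"))
  out[]
}

#' 1:k matching of training controls to cases
#'
#' Cases are processed in seeded random order; each selects, without
#' replacement and uniformly at random, up to `k` controls agreeing on all
#' matching keys (gender, 5-year age bin at index, enrollment-duration
#' stratum). Controls are used at most once; cases with fewer than `k`
#' available matches keep what was found.
#'
#' @param cases `data.table` with `member_id` and the key columns
#'   `gender`, `age_bin`, `duration_stratum`.
#' @param controls candidate control pool, same columns; must be disjoint
#'   from the test set.
#' @param k maximum matched controls per case (default 5).
#' @param seed integer seed.
#' @return `data.table` of matched controls: `member_id`,
#'   `matched_case_id`, plus the key columns.
#' @export
match_controls <- function(cases, controls, k = 5L, seed = 1L) {
  cases <- as.data.table(cases)
  controls <- as.data.table(controls)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  keys <- c("gender", "age_bin", "duration_stratum")
  if (!all(keys %chin% names(cases)) || !all(keys %chin% names(controls))) {
    stop("cases and controls must carry columns: ", paste(keys, collapse = ", "))
  }
  set.seed(as.integer(seed))
  case_order <- sample.int(nrow(cases))
  ctrl_order <- sample.int(nrow(controls))

  cs <- cases[case_order, c("member_id", keys), with = FALSE]
  cs[, key_ := do.call(paste, c(.SD, sep = "\r")), .SDcols = keys]
  ct <- controls[ctrl_order, c("member_id", keys), with = FALSE]
  ct[, key_ := do.call(paste, c(.SD, sep = "\r")), .SDcols = keys]

  # within each key group, cases (in global random order) take consecutive
  # blocks of k from the shuffled control list
  cs[, slot := seq_len(.N), by = key_]
  ct[, pos := seq_len(.N), by = key_]
  ct[, case_slot := ((pos - 1L) %/% k) + 1L]
  matched <- ct[cs, on = .(key_, case_slot = slot), nomatch = NULL,
                .(member_id = x.member_id, matched_case_id = i.member_id,
                  gender, age_bin, duration_stratum)]
  matched[]
}

#' Five-year age bins with an 89-year cap
#'
#' Ages above 89 are mapped to 89 before binning (privacy convention of the
#' source data); bins are `"40-44"`, `"45-49"`, ..., `"85-89"`.
#'
#' @param age integer ages.
#' @return character bin labels.
#' @export
age_bin <- function(age) {
  a <- pmin(89L, as.integer(age))
  lo <- (a %/% 5L) * 5L
  sprintf("%d-%d", lo, lo + 4L)
}

#' Decile strata of enrollment durations
#'
#' Builds nearest-rank decile breakpoints from the case durations and
#' assigns each duration to a stratum 1-10. Used as the enrollment-duration
#' matching key.
#'
#' @param case_durations durations (days) of the training cases.
#' @return function mapping durations to integer strata.
#' @export
duration_strata <- function(case_durations) {
  pt <- enrollment_duration_percentiles(case_durations)
  breaks <- unique(unname(pt[as.character(seq(10, 90, by = 10))]))
  function(d) findInterval(d, breaks, left.open = TRUE) + 1L
}

#' Build the nested case-control study from a phenotyped dataset
#'
#' End-to-end cohort construction: eligibility filtering, incident-case
#' selection with the ordered exclusion cascade, enrollment-duration
#' percentile computation, control index-date assignment, control
#' exclusions, train/test split, and 1:k matching of training controls on
#' gender, age bin and duration stratum.
#'
#' @param dataset a `claims_dataset`.
#' @param code_set an [adrd_code_set()].
#' @param determinations optional precomputed [phenotype_population()]
#'   output.
#' @param k controls matched per training case.
#' @param test_fraction fraction of cases (and controls) held out for test.
#' @param min_age minimum age at index.
#' @param seed integer seed driving control index assignment, the split and
#'   matching.
#' @return list of class `cohort_assignment` with
#'   `assignments` (`member_id`, `role`, `split`, `index_date`,
#'   `matched_case_id`, `age_at_index`, `duration_days`), `percentiles`,
#'   and `ledgers` (named list: `eligibility`, `cases`, `controls`).
#' @export
build_cohort <- function(dataset, code_set = adrd_code_set(),
                         determinations = NULL, k = 5L, test_fraction = 0.3,
                         min_age = 45L, seed = 1L) {
  members <- as.data.table(dataset$members)
  elig <- filter_eligible(members, dataset$spans)
  if (is.null(determinations)) {
    determinations <- phenotype_population(dataset, code_set)
  }
  det <- as.data.table(determinations)

  # case arm: eligible members with any qualifying event
  cand <- elig$members[member_id %chin% det[n_events > 0L, member_id]]
  cand_det <- det[match(cand$member_id, member_id)]
  case_cohort <- data.table(member_id = cand$member_id,
                            index_date = cand_det$index_date)
  case_excl <- apply_exclusions(
    case_cohort,
    rules = c("no_confirmation", "short_preindex_enrollment_or_under_45",
              "no_claims"),
    dataset = dataset, determinations = det, min_age = min_age
  )
  cases <- case_excl$cohort

  # enrollment-to-index durations of the incident cases, measured from the
  # start of the span containing the index date
  spans <- as.data.table(dataset$spans)
  case_spans <- spans[cases, on = .(member_id, start_date <= index_date,
                                    end_date >= index_date),
                      .(member_id, span_start = x.start_date,
                        index_date = i.index_date), nomatch = NULL]
  cases <- merge(cases, case_spans[, .(member_id, span_start)],
                 by = "member_id", sort = FALSE)
  cases[, duration_days := as.numeric(index_date - span_start)]
  pt <- enrollment_duration_percentiles(cases$duration_days)

  # control arm: eligible members with no qualifying event at all
  ctrl_pool <- elig$members[member_id %chin% det[n_events == 0L, member_id]]
  idx <- assign_control_index_dates(ctrl_pool, pt, seed = seed)
  ctrl_cohort <- idx$assignments
  ctrl_excl <- apply_exclusions(
    ctrl_cohort[, .(member_id, index_date)],
    rules = c("under_45", "no_claims"),
    dataset = dataset, min_age = min_age
  )
  controls <- merge(ctrl_excl$cohort,
                    ctrl_cohort[, .(member_id, duration_days)],
                    by = "member_id", sort = FALSE)
  ctrl_ledger <- ledger_bind(idx$ledger, ctrl_excl$ledger)

  split <- split_train_test(cases$member_id, controls$member_id,
                            test_fraction = test_fraction, seed = seed)

  demo <- members[, .(member_id, birth_year, gender)]
  decorate <- function(dt) {
    dt <- merge(dt, demo, by = "member_id", sort = FALSE)
    dt[, age_at_index := data.table::year(index_date) - birth_year]
    dt[, age_bin := age_bin(age_at_index)]
    dt[, birth_year := NULL]
    dt
  }
  cases <- decorate(cases)
  controls <- decorate(controls)
  strat <- duration_strata(cases$duration_days)
  cases[, duration_stratum := strat(duration_days)]
  controls[, duration_stratum := strat(duration_days)]

  cases <- merge(cases, split[role == "case", .(member_id, split)],
                 by = "member_id", sort = FALSE)
  controls <- merge(controls, split[role == "control", .(member_id, split)],
                    by = "member_id", sort = FALSE)

  matched <- match_controls(cases[split == "train"],
                            controls[split == "train"], k = k, seed = seed)

  mk_rows <- function(dt, role, split_val, match_col = NA_character_) {
    data.table(member_id = dt$member_id, role = role, split = split_val,
               index_date = dt$index_date,
               matched_case_id = match_col,
               age_at_index = dt$age_at_index,
               duration_days = dt$duration_days)
  }
  train_ctrl <- controls[match(matched$member_id, member_id)]
  assignments <- rbind(
    mk_rows(cases[split == "train"], "case", "train"),
    mk_rows(cases[split == "test"], "case", "test"),
    data.table(member_id = train_ctrl$member_id, role = "control",
               split = "train", index_date = train_ctrl$index_date,
               matched_case_id = matched$matched_case_id,
               age_at_index = train_ctrl$age_at_index,
               duration_days = train_ctrl$duration_days),
    mk_rows(controls[split == "test"], "control", "test")
  )
  structure(
    list(assignments = assignments[], percentiles = pt,
         ledgers = list(eligibility = elig$ledger, cases = case_excl$ledger,
                        controls = ctrl_ledger)),
    class = "cohort_assignment"
  )
}

#' @export
print.cohort_assignment <- function(x, ...) {
  a <- x$assignments
  cat("<cohort_assignment>\n")
  for (sp in c("train", "test")) {
    n_ca <- nrow(a[split == sp & role == "case"])
    n_co <- nrow(a[split == sp & role == "control"])
    cat(sprintf("  %-5s: %d cases, %d controls (prevalence %.2f%%)\n",
                sp, n_ca, n_co, 100 * n_ca / max(1L, n_ca + n_co)))
  }
  invisible(x)
}
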