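test_that("exclusion ledgers keep exact running arithmetic", {
  led <- exclusion_ledger(100)
  led <- ledger_add(led, "a", 40)
  led <- ledger_add(led, "b", 0)
  led <- ledger_add(led, "c", 60)
  expect_identical(ledger_remaining(led), 0L)
  expect_true(ledger_validate(led))
  expect_error(ledger_add(led, "d", 1), "only 0 remain")
  expect_error(exclusion_ledger(-1), "nonnegative")
  expect_error(ledger_replay(10, c(5, 2)), "named")

  # conservation: first remaining - sum(removed) = last remaining
  set.seed(4)
  for (i in 1:20) {
    start <- sample(50:500, 1)
    rem <- c()
    led <- exclusion_ledger(start)
    left <- start
    for (s in 1:sample(1:6, 1)) {
      r <- sample(0:left, 1)
      led <- ledger_add(led, paste0("s", s), r)
      rem <- c(rem, r)
      left <- left - r
    }
    expect_identical(led$remaining[1] - sum(led$removed), ledger_remaining(led))
    expect_true(ledger_validate(led))
  }
})

test_that("eligibility keeps >5-year spans and drops long-term care, in order", {
  members <- data.table(
    member_id = c("short", "ltc", "ok", "exact5"),
    birth_year = 1940L, gender = "female",
    ltc_flag = c(FALSE, TRUE, FALSE, FALSE)
  )
  spans <- data.table(
    member_id = c("short", "ltc", "ok", "exact5"),
    start_date = as.Date(c("2004-01-01", "2004-01-01", "2004-01-01",
                           "2004-01-01")),
    end_date = as.Date(c("2008-01-01",  # 4 years: out
                         "2010-06-01",  # >5 years but LTC: out at LTC step
                         "2010-06-01",  # >5 years: kept
                         "2009-01-01")) # exactly 5 years: out (strict)
  )
  res <- filter_eligible(members, spans)
  expect_identical(res$members$member_id, "ok")
  expect_identical(res$ledger$step,
                   c("all_members", "enrollment_under_5y", "long_term_care"))
  expect_identical(res$ledger$removed, c(0L, 2L, 1L))
  expect_identical(ledger_remaining(res$ledger), 1L)
})

test_that("duration percentiles use nearest rank with min and max endpoints", {
  # degenerate single case
  pt <- enrollment_duration_percentiles(1827)
  expect_length(pt, 101L)
  expect_true(all(pt == 1827))

  # 0..100 once each: identity
  pt <- enrollment_duration_percentiles(0:100)
  expect_identical(as.vector(unname(pt)), as.numeric(0:100))

  # nondecreasing for arbitrary input; endpoints are min and max
  set.seed(8)
  for (i in 1:10) {
    d <- sample(1827:2735, sample(3:200, 1), replace = TRUE)
    pt <- enrollment_duration_percentiles(d)
    expect_true(all(diff(pt) >= 0))
    expect_identical(unname(pt[c("0", "100")]), as.numeric(range(d)))
  }
  expect_error(enrollment_duration_percentiles(numeric(0)), "non-empty")
})

test_that("control index dates: forced drops, forced keeps, and the quantile property", {
  pt <- enrollment_duration_percentiles(1827:1927)  # 101 distinct values
  mk_controls <- function(n, len) {
    data.table(member_id = sprintf("c%05d", seq_len(n)),
               eligible_span_start = as.Date("2004-01-01"),
               eligible_span_end = as.Date("2004-01-01") + len)
  }
  # span shorter than the 0th percentile: removed with certainty
  res <- assign_control_index_dates(mk_controls(50, 1800), pt, seed = 1)
  expect_identical(nrow(res$assignments), 0L)
  expect_identical(res$ledger$removed[2], 50L)
  # span longer than the 100th percentile: retained with certainty
  res <- assign_control_index_dates(mk_controls(50, 3000), pt, seed = 1)
  expect_identical(nrow(res$assignments), 50L)
  # span at the 50th percentile: retention fraction ~ P(duration <= v50)
  v50 <- unname(pt["50"])
  res <- assign_control_index_dates(mk_controls(10000, v50), pt, seed = 5)
  p_keep <- mean(pt <= v50)  # 51/101 for distinct values
  frac <- nrow(res$assignments) / 10000
  expect_lt(abs(frac - p_keep), 3 * sqrt(p_keep * (1 - p_keep) / 10000))
  # determinism
  r2 <- assign_control_index_dates(mk_controls(10000, v50), pt, seed = 5)
  expect_identical(res$assignments, r2$assignments)
})

test_that("exclusion rules are applied in order with exact ledger counts", {
  ds <- simulate_claims(sim_config(n_members = 600, seed = 17))
  det <- phenotype_population(ds)
  elig <- filter_eligible(ds$members, ds$spans)
  cand <- det[n_events > 0L & member_id %in% elig$members$member_id]
  cohort <- cand[, .(member_id, index_date)]

  res <- apply_exclusions(cohort, c("no_confirmation",
                                    "short_preindex_enrollment_or_under_45",
                                    "no_claims"),
                          dataset = ds, determinations = det)
  expect_true(ledger_validate(res$ledger))
  expect_identical(nrow(res$cohort),
                   ledger_remaining(res$ledger))
  # empty rule list leaves the cohort unchanged with only the starting row
  res0 <- apply_exclusions(cohort, character(0), dataset = ds,
                           determinations = det)
  expect_identical(res0$cohort, cohort)
  expect_identical(nrow(res0$ledger), 1L)
  expect_error(apply_exclusions(cohort, "bogus_rule", dataset = ds),
               "unknown exclusion rule")
})

test_that("train/test split handles boundary fractions and rounds half-up", {
  cases <- sprintf("ca%04d", 1:1000)
  ctrls <- sprintf("co%04d", 1:500)
  s0 <- split_train_test(cases, ctrls, 0, seed = 2)
  expect_identical(nrow(s0[role == "case" & split == "test"]), 0L)
  s1 <- split_train_test(cases, ctrls, 1, seed = 2)
  expect_identical(nrow(s1[role == "case" & split == "train"]), 0L)
  s3 <- split_train_test(cases, ctrls, 0.3, seed = 2)
  expect_identical(nrow(s3[role == "case" & split == "test"]), 300L)
  # half-up rounding: 0.5 % of 101 cases -> 51 test (floor(50.5 + .5))
  s5 <- split_train_test(sprintf("x%03d", 1:101), character(0), 0.5, seed = 2)
  expect_identical(nrow(s5[split == "test"]), 51L)
  # determinism and disjointness
  s3b <- split_train_test(cases, ctrls, 0.3, seed = 2)
  expect_identical(s3, s3b)
  expect_identical(anyDuplicated(s3$member_id), 0L)
})

test_that("matching takes up to k controls per case on exact keys, each control once", {
  mk <- function(ids, gender, bin, stratum) {
    data.table(member_id = ids, gender = gender, age_bin = bin,
               duration_stratum = stratum)
  }
  case <- mk("case1", "female", "75-79", 3L)
  pool5 <- mk(sprintf("c%d", 1:5), "female", "75-79", 3L)
  m <- match_controls(case, pool5, k = 5, seed = 1)
  expect_identical(sort(m$member_id), sort(pool5$member_id))
  expect_identical(unique(m$matched_case_id), "case1")

  pool3 <- mk(sprintf("c%d", 1:3), "female", "75-79", 3L)
  m3 <- match_controls(case, pool3, k = 5, seed = 1)
  expect_identical(nrow(m3), 3L)

  # key-mismatched controls are never used
  pool_mixed <- rbind(pool3, mk(sprintf("w%d", 1:5), "male", "75-79", 3L))
  m_mix <- match_controls(case, pool_mixed, k = 5, seed = 1)
  expect_identical(sort(m_mix$member_id), sort(pool3$member_id))

  # abundant pool: every case fully matched, prevalence 1/(k+1), no reuse
  set.seed(9)
  cases <- mk(sprintf("ca%03d", 1:60),
              sample(c("male", "female"), 60, TRUE),
              sample(c("70-74", "75-79"), 60, TRUE),
              sample(1:3, 60, TRUE))
  pool <- cases[rep(1:60, each = 8)]
  pool[, member_id := sprintf("co%04d", seq_len(.N))]
  mm <- match_controls(cases, pool, k = 5, seed = 9)
  expect_identical(nrow(mm), 300L)
  expect_identical(anyDuplicated(mm$member_id), 0L)
  expect_equal(60 / (60 + nrow(mm)), 1 / 6)
  # key agreement by direct scan
  joined <- merge(mm, cases, by.x = "matched_case_id", by.y = "member_id",
                  suffixes = c("", ".case"))
  expect_true(all(joined$gender == joined$gender.case))
  expect_true(all(joined$age_bin == joined$age_bin.case))
  expect_true(all(joined$duration_stratum == joined$duration_stratum.case))
})

test_that("age bins cap at 89 and duration strata cover all durations", {
  expect_identical(age_bin(c(67, 93, 45, 89)),
                   c("65-69", "85-89", "45-49", "85-89"))
  strat <- duration_strata(c(1827, 1900, 2000, 2100, 2200, 2300, 2400, 2500,
                             2600, 2735))
  s <- strat(c(1827, 2735, 2050))
  expect_true(all(s >= 1L & s <= 10L))
})

test_that("end-to-end cohort build: disjoint splits, single-use controls, matched keys", {
  ds <- simulate_claims(sim_config(n_members = 6000, target_case_fraction = 0.08,
                                   seed = 23))
  coh <- build_cohort(ds, seed = 23)
  a <- coh$assignments
  expect_identical(anyDuplicated(a$member_id), 0L)
  expect_identical(anyDuplicated(a[role == "control" & split == "train",
                                   member_id]), 0L)
  for (l in coh$ledgers) expect_true(ledger_validate(l))
  # every matched control shares split/gender/age bin/duration stratum
  train <- a[split == "train"]
  ctrl <- train[role == "control"]
  case <- train[role == "case"]
  expect_true(all(ctrl$matched_case_id %in% case$member_id))
  demo <- ds$members[, .(member_id, gender)]
  ctrl_g <- demo$gender[match(ctrl$member_id, demo$member_id)]
  case_g <- demo$gender[match(ctrl$matched_case_id, demo$member_id)]
  expect_identical(ctrl_g, case_g)
  cb <- age_bin(case$age_at_index[match(ctrl$matched_case_id, case$member_id)])
  expect_identical(age_bin(ctrl$age_at_index), cb)
  # percentile table endpoints within the simulated duration range
  expect_gte(unname(coh$percentiles["0"]), 1827)
  # up-to-k matching
  expect_lte(max(table(ctrl$matched_case_id)), 5L)
})
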