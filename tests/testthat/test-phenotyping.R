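cs <- adrd_code_set()

test_that("the five canonical trajectory fixtures reproduce their determinations exactly", {
  fx <- case_pattern_fixtures(cs)
  expect_length(fx, 5L)
  for (nm in names(fx)) {
    ds <- fx[[nm]]$dataset
    exp <- fx[[nm]]$expected
    det <- determine_case(ds$medical_claims, ds$pharmacy_claims, cs)
    expect_true(det$is_case, info = nm)
    expect_identical(det$rule, exp$rule, info = nm)
    expect_identical(det$index_date, exp$index_date, info = nm)
    expect_identical(det$confirmation_date, exp$confirmation_date, info = nm)
    # population path agrees and all fixtures are incident (spans cover the
    # 60-month washout)
    pop <- phenotype_population(ds, cs)
    expect_identical(pop$rule, exp$rule, info = nm)
    expect_identical(pop$status, "incident", info = nm)
  }
  # pattern-specific shape checks
  expect_gt(as.integer(fx$inpatient_late_confirm$expected$confirmation_date -
                         fx$inpatient_late_confirm$expected$index_date), 730L)
  expect_identical(fx$inpatient_only$expected$index_date,
                   fx$inpatient_only$expected$confirmation_date)
})

test_that("qualifying events are extracted with the right kinds and ordering", {
  expect_identical(nrow(find_qualifying_events(
    med_claim("m", "2010-01-01", code = "401.9"),
    rx_claim("m", "2010-01-01", "simvastatin"), cs)), 0L)

  ev <- find_qualifying_events(no_med(),
                               rx_claim("m", "2010-03-01",
                                        "Donepezil Hydrochloride"), cs)
  expect_identical(ev$kind, "monotherapy_fill")

  # header position is irrelevant; outpatient dx is any_dx only
  ev <- find_qualifying_events(
    med_claim("m", "2010-05-01", setting = "outpatient", pos = 3L), no_rx(), cs)
  expect_identical(ev$kind, "any_dx")
  expect_false(ev$is_inpatient_dx)

  # inpatient dx carries both flags
  ev <- find_qualifying_events(
    med_claim("m", "2010-05-01", setting = "inpatient"), no_rx(), cs)
  expect_identical(ev$kind, "inpatient_dx")
  expect_true(ev$is_dx)

  # sorted by date
  ev <- find_qualifying_events(
    rbind(med_claim("m", "2011-01-01"), med_claim("m", "2010-01-01")),
    no_rx(), cs)
  expect_identical(ev$event_date, as.Date(c("2010-01-01", "2011-01-01")))
})

test_that("two-claim rule respects the inclusive 1-730 day window", {
  pair <- function(gap) {
    determine_case(rbind(med_claim("m", "2010-01-01"),
                         med_claim("m", as.Date("2010-01-01") + gap)),
                   no_rx(), cs)
  }
  expect_false(pair(0L)$is_case)   # same-day duplicate never confirms
  expect_true(pair(1L)$is_case)    # lower bound
  expect_true(pair(730L)$is_case)  # upper bound
  expect_false(pair(731L)$is_case) # just outside
  d <- pair(365L)
  expect_identical(d$rule, "b")
  expect_identical(d$index_date, as.Date("2010-01-01"))
  expect_identical(d$confirmation_date, as.Date("2010-01-01") + 365L)
})

test_that("memantine requires a diagnosis claim within the 0-730 day window, either order", {
  mem_only <- determine_case(no_med(),
                             rx_claim("m", "2010-01-01", cs$confirm_drug), cs)
  expect_false(mem_only$is_case)

  mk <- function(dx_date, mem_date) {
    determine_case(med_claim("m", dx_date),
                   rx_claim("m", mem_date, cs$confirm_drug), cs)
  }
  expect_true(mk("2010-01-01", "2010-01-01")$is_case)  # gap 0 qualifies
  expect_true(mk("2010-06-01", "2010-01-01")$is_case)  # dx after fill
  expect_true(mk("2010-01-01", "2010-06-01")$is_case)  # fill after dx
  expect_false(mk("2008-01-01", "2010-06-01")$is_case) # gap > 730
  d <- mk("2010-06-01", "2010-01-01")
  expect_identical(d$rule, "d")
  expect_identical(d$confirmation_date, as.Date("2010-06-01"))
  expect_identical(d$index_date, as.Date("2010-01-01"))
})

test_that("index date is the earliest qualifying event of any kind", {
  # a monotherapy fill long before an inpatient dx sets the index
  d <- determine_case(med_claim("m", "2011-06-01", setting = "inpatient"),
                      rx_claim("m", "2008-02-01", cs$monotherapy_drugs[2]), cs)
  expect_identical(d$index_date, as.Date("2008-02-01"))
  expect_identical(d$confirmation_date, as.Date("2008-02-01"))  # rule c fires first
  expect_identical(d$rule, "c")
})

test_that("adding non-ADRD claims never changes a determination", {
  set.seed(11)
  for (i in 1:25) {
    seq <- random_event_sequence()
    cl <- events_to_claims("m", seq$dates, seq$kinds, cs)
    before <- determine_case(cl$medical, cl$pharmacy, cs)
    noise_med <- rbind(cl$medical,
                       med_claim("m", sample(seq(as.Date("2007-01-01"),
                                                 as.Date("2013-01-01"), 1), 1),
                                 code = "401.9", setting = "inpatient"),
                       med_claim("m", "2009-07-07", code = "71020",
                                 type = "CPT"))
    noise_rx <- rbind(cl$pharmacy, rx_claim("m", "2010-10-10", "simvastatin"))
    after <- determine_case(noise_med, noise_rx, cs)
    expect_identical(before, after)
  }
})

test_that("brute-force oracle agrees on random short event sequences", {
  set.seed(12)
  for (i in 1:200) {
    seq <- random_event_sequence()
    cl <- events_to_claims("m", seq$dates, seq$kinds, cs)
    got <- determine_case(cl$medical, cl$pharmacy, cs)
    want <- oracle_determine(seq$dates, seq$kinds, cs)
    expect_identical(got$is_case, want$is_case)
    if (want$is_case) {
      expect_identical(got$index_date, want$index_date)
      expect_identical(got$confirmation_date, want$confirmation_date)
      expect_identical(got$rule, want$rule)
      expect_lte(as.integer(got$index_date), as.integer(got$confirmation_date))
    }
  }
})

test_that("washout separates incident from prevalent or unobservable cases", {
  mk_case <- function(span_start) {
    list(
      det = determine_case(med_claim("m", "2010-06-15", setting = "inpatient"),
                           no_rx(), cs),
      spans = data.table(member_id = "m", start_date = as.Date(span_start),
                         end_date = as.Date("2012-12-31"))
    )
  }
  # span starts 72 months pre-index: incident
  x <- mk_case("2004-06-15")
  expect_identical(
    apply_incidence_washout(x$det, x$spans,
                            med_claim("m", "2010-06-15", setting = "inpatient"),
                            no_rx(), cs),
    "incident")
  # span starts 24 months pre-index: unobservable
  x <- mk_case("2008-06-15")
  expect_identical(
    apply_incidence_washout(x$det, x$spans,
                            med_claim("m", "2010-06-15", setting = "inpatient"),
                            no_rx(), cs),
    "prevalent_or_unobservable")
  # non-case input is a contract violation
  noncase <- determine_case(no_med(), no_rx(), cs)
  expect_error(apply_incidence_washout(noncase, x$spans, no_med(), no_rx(), cs),
               "confirmed case")
  # inconsistent inputs (event before the claimed index) are caught
  det <- data.table(member_id = "m", is_case = TRUE,
                    index_date = as.Date("2010-06-15"),
                    confirmation_date = as.Date("2010-06-15"), rule = "a")
  expect_error(
    apply_incidence_washout(det, x$spans,
                            med_claim("m", "2008-01-01"), no_rx(), cs),
    "precedes the index")
})

test_that("60-month washout uses calendar months with month-end clamping", {
  # index on 2012-02-29: 60 months earlier is 2007-02-28; a span starting
  # exactly there covers the washout
  det <- determine_case(med_claim("m", "2012-02-29", setting = "inpatient"),
                        no_rx(), cs)
  spans_ok <- data.table(member_id = "m", start_date = as.Date("2007-02-28"),
                         end_date = as.Date("2012-12-31"))
  spans_short <- data.table(member_id = "m", start_date = as.Date("2007-03-01"),
                            end_date = as.Date("2012-12-31"))
  med <- med_claim("m", "2012-02-29", setting = "inpatient")
  expect_identical(apply_incidence_washout(det, spans_ok, med, no_rx(), cs),
                   "incident")
  expect_identical(apply_incidence_washout(det, spans_short, med, no_rx(), cs),
                   "prevalent_or_unobservable")
})
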