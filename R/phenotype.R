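#' Qualifying ADRD events for one or more members
#'
#' Scans medical and pharmacy claims for events that can participate in the
#' ADRD case definition:
#' \itemize{
#'   \item a medical claim with an ADRD diagnosis code in any header
#'     position (`any_dx`; additionally flagged `inpatient_dx` when the care
#'     setting is inpatient),
#'   \item a fill of one of the monotherapy drugs (`monotherapy_fill`),
#'   \item a fill of the confirmation drug (`memantine_fill`).
#' }
#' Header position never matters; setting matters only for the inpatient
#' flag.
#'
#' @param medical medical claims `data.table` (`member_id`, `service_date`,
#'   `code`, `code_type`, `setting`, `header_position`).
#' @param pharmacy pharmacy claims `data.table` (`member_id`, `fill_date`,
#'   `drug_name`).
#' @param code_set an [adrd_code_set()].
#' @return A `data.table` with columns `member_id`, `event_date`, `kind`
#'   (one of `inpatient_dx`, `any_dx`, `monotherapy_fill`, `memantine_fill`),
#'   and logical helper columns `is_dx`, `is_inpatient_dx`, `is_monotherapy`,
#'   `is_memantine`, sorted by date (stable on ties, claims before fills in
#'   input order). Empty input gives an empty table.
#' @export
find_qualifying_events <- function(medical, pharmacy, code_set) {
  stopifnot(inherits(code_set, "adrd_code_set"))
  medical <- as.data.table(medical)
  pharmacy <- as.data.table(pharmacy)

  med <- medical[code_type == "ICD9_DX" & code %chin% code_set$dx_codes]
  if (nrow(med)) {
    med_ev <- med[, .(
      member_id,
      event_date = as.Date(service_date),
      is_dx = TRUE,
      is_inpatient_dx = setting == "inpatient",
      is_monotherapy = FALSE,
      is_memantine = FALSE
    )]
  } else {
    med_ev <- empty_events()
  }

  drug <- norm_drug(pharmacy$drug_name)
  is_mono <- drug %chin% code_set$monotherapy_drugs
  is_mem <- drug == code_set$confirm_drug
  rx <- pharmacy[is_mono | is_mem]
  if (nrow(rx)) {
    rx_ev <- rx[, .(
      member_id,
      event_date = as.Date(fill_date),
      is_dx = FALSE,
      is_inpatient_dx = FALSE,
      is_monotherapy = is_mono[is_mono | is_mem],
      is_memantine = is_mem[is_mono | is_mem]
    )]
  } else {
    rx_ev <- empty_events()
  }

  ev <- rbind(med_ev, rx_ev)
  if (nrow(ev)) {
    setorderv(ev, "event_date")  # stable, preserves input order on ties
    ev[, kind := fifelse(is_inpatient_dx, "inpatient_dx",
                 fifelse(is_dx, "any_dx",
                 fifelse(is_monotherapy, "monotherapy_fill", "memantine_fill")))]
    setcolorder(ev, c("member_id", "event_date", "kind"))
  } else {
    ev[, kind := character(0)]
    setcolorder(ev, c("member_id", "event_date", "kind"))
  }
  ev[]
}

empty_events <- function() {
  data.table(
    member_id = character(0),
    event_date = as.Date(character(0)),
    is_dx = logical(0),
    is_inpatient_dx = logical(0),
    is_monotherapy = logical(0),
    is_memantine = logical(0)
  )
}

#' Determine ADRD case status for a single member
#'
#' Applies the four qualifying criteria to one member's claims:
#' \describe{
#'   \item{a}{an ADRD diagnosis claim in an inpatient setting;}
#'   \item{b}{two ADRD diagnosis claims (any setting) whose dates differ by
#'     1 to 730 days inclusive;}
#'   \item{c}{a fill of donepezil, galantamine, rivastigmine or tacrine;}
#'   \item{d}{a memantine fill with an ADRD diagnosis claim within 0 to 730
#'     days in either temporal order.}
#' }
#' The confirmation date is the earliest date at which any criterion is
#' fully satisfied (for the pair rules b and d, the later member of the
#' earliest satisfying pair). The rule label is the criterion confirming at
#' that date, ties broken in the order a, b, c, d. The index date is the
#' earliest qualifying event of any kind across the member's whole history —
#' it may precede the confirmation date by more than 730 days.
#'
#' @param medical,pharmacy claims of a single member.
#' @inheritParams find_qualifying_events
#' @return A one-row `data.table`: `member_id`, `is_case`, `index_date`,
#'   `confirmation_date`, `rule`. For non-cases the last three are `NA`.
#' @export
determine_case <- function(medical, pharmacy, code_set) {
  medical <- as.data.table(medical)
  pharmacy <- as.data.table(pharmacy)
  ids <- unique(c(medical$member_id, pharmacy$member_id))
  if (length(ids) > 1L) stop("claims of more than one member supplied")
  ev <- find_qualifying_events(medical, pharmacy, code_set)
  id <- if (length(ids)) ids else NA_character_
  det <- determine_from_events(ev, code_set)
  det[, member_id := id]
  setcolorder(det, "member_id")
  det[]
}

# core rule engine over a single member's event table
determine_from_events <- function(ev, code_set) {
  no_case <- data.table(
    is_case = FALSE, index_date = as.Date(NA),
    confirmation_date = as.Date(NA), rule = NA_character_
  )
  if (nrow(ev) == 0L) return(no_case)

  d <- as.integer(ev$event_date)
  dx <- sort(d[ev$is_dx])
  inpt <- d[ev$is_inpatient_dx]
  mono <- d[ev$is_monotherapy]
  mem <- d[ev$is_memantine]
  bw <- code_set$confirm_window_days
  mw <- code_set$memantine_window_days

  conf_a <- if (length(inpt)) min(inpt) else NA_integer_
  conf_c <- if (length(mono)) min(mono) else NA_integer_

  # rule b: earliest dx that has another dx 1..730 days before it
  conf_b <- NA_integer_
  if (length(dx) >= 2L) {
    for (j in 2:length(dx)) {
      gaps <- dx[j] - dx[1:(j - 1L)]
      if (any(gaps >= bw[1] & gaps <= bw[2])) {
        conf_b <- dx[j]
        break
      }
    }
  }

  # rule d: earliest instant at which a memantine fill and a dx claim lie
  # within the window of each other (either order); the confirming date is
  # the later of the pair, minimised over qualifying pairs
  conf_d <- NA_integer_
  if (length(mem) && length(dx)) {
    cand <- Inf
    for (m in mem) {
      gaps <- abs(dx - m)
      ok <- gaps >= mw[1] & gaps <= mw[2]
      if (any(ok)) cand <- min(cand, min(pmax(dx[ok], m)))
    }
    if (is.finite(cand)) conf_d <- as.integer(cand)
  }

  confs <- c(a = conf_a, b = conf_b, c = conf_c, d = conf_d)
  if (all(is.na(confs))) return(no_case)
  best <- which.min(confs)  # first minimum => precedence a > b > c > d
  data.table(
    is_case = TRUE,
    index_date = as.Date(min(d), origin = "1970-01-01"),
    confirmation_date = as.Date(confs[[best]], origin = "1970-01-01"),
    rule = names(confs)[best]
  )
}

#' Incidence washout: incident versus prevalent-or-unobservable
#'
#' A confirmed case is incident only if it is observably new: a single
#' enrollment span must cover the full washout period ending at the index
#' date, and no qualifying event may fall inside the washout before the
#' index date. Because the index date is defined as the earliest qualifying
#' event, the second condition holds by construction; it is still checked
#' and an inconsistency raises an error.
#'
#' @param det a one-row case determination (`is_case` must be `TRUE`).
#' @param spans enrollment spans of the member.
#' @param medical,pharmacy claims of the member.
#' @inheritParams find_qualifying_events
#' @param washout_months washout length in calendar months (default 60);
#'   the window start is the index date minus this many months, with
#'   month-end clamping (e.g. 60 months before 2012-02-29 is 2007-02-28).
#' @return `"incident"` or `"prevalent_or_unobservable"`.
#' @export
apply_incidence_washout <- function(det, spans, medical, pharmacy, code_set,
                                    washout_months = 60L) {
  det <- as.data.table(det)
  if (nrow(det) != 1L || !isTRUE(det$is_case)) {
    stop("`det` must be a single confirmed case determination")
  }
  spans <- as.data.table(spans)
  idx <- as.Date(det$index_date)
  w_start <- add_months(idx, -as.integer(washout_months))

  ev <- find_qualifying_events(medical, pharmacy, code_set)
  if (nrow(ev) && min(ev$event_date) < idx) {
    stop("inconsistent inputs: qualifying event precedes the index date")
  }
  prior <- nrow(ev[event_date >= w_start & event_date < idx]) > 0L
  covered <- nrow(spans[start_date <= w_start & end_date >= idx]) > 0L
  if (covered && !prior) "incident" else "prevalent_or_unobservable"
}

#' Phenotype every member of a claims dataset
#'
#' Runs [determine_case()] over all members and, for confirmed cases,
#' [apply_incidence_washout()]. Members without qualifying events are
#' returned with `is_case = FALSE`.
#'
#' @param dataset a `claims_dataset` (see [simulate_claims()]) or any list
#'   with `members`, `spans`, `medical_claims`, `pharmacy_claims`.
#' @inheritParams apply_incidence_washout
#' @return A `data.table` with one row per member: `member_id`, `is_case`,
#'   `index_date`, `confirmation_date`, `rule`, `status` (`"incident"`,
#'   `"prevalent_or_unobservable"`, or `NA` for non-cases), and `n_events`
#'   (count of qualifying events).
#' @export
phenotype_population <- function(dataset, code_set = adrd_code_set(),
                                 washout_months = 60L) {
  members <- as.data.table(dataset$members)
  spans <- as.data.table(dataset$spans)
  ev <- find_qualifying_events(dataset$medical_claims, dataset$pharmacy_claims,
                               code_set)

  det <- ev[, determine_from_events(.SD, code_set), by = member_id]
  n_ev <- ev[, .(n_events = .N), by = member_id]

  out <- data.table(member_id = members$member_id)
  out <- merge(out, det, by = "member_id", all.x = TRUE, sort = FALSE)
  out <- merge(out, n_ev, by = "member_id", all.x = TRUE, sort = FALSE)
  out[is.na(is_case), is_case := FALSE]
  out[is.na(n_events), n_events := 0L]

  out[, status := NA_character_]
  case_ids <- out[is_case == TRUE, member_id]
  if (length(case_ids)) {
    w <- as.integer(washout_months)
    ev_case <- ev[member_id %chin% case_ids]
    setkey(ev_case, member_id)
    spans_case <- spans[member_id %chin% case_ids]
    setkey(spans_case, member_id)
    idx <- out[match(case_ids, member_id), index_date]
    w_start <- add_months(idx, -w)
    cov <- spans_case[data.table(member_id = case_ids, ws = w_start, ix = idx),
                      on = "member_id", allow.cartesian = TRUE][
      start_date <= ws & end_date >= ix, unique(member_id)]
    prior <- ev_case[data.table(member_id = case_ids, ws = w_start, ix = idx),
                     on = "member_id", allow.cartesian = TRUE][
      event_date >= ws & event_date < ix, unique(member_id)]
    out[member_id %chin% case_ids,
        status := fifelse(member_id %chin% cov & !(member_id %chin% prior),
                          "incident", "prevalent_or_unobservable")]
  }
  out[]
}
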