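#' Configuration for the synthetic claims generator
#'
#' The generator emulates the structure of an administrative claims
#' warehouse: members with demographics, one multi-year continuous
#' enrollment span each, sparse background diagnosis/procedure/drug events,
#' and a planted fraction of ADRD cases whose claims realise one of the
#' five canonical case trajectories. Planted cases additionally carry
#' elevated rates of configurable risk codes in the 4th-5th years before
#' their index date, which is the window later used for feature
#' engineering.
#'
#' @param n_members number of members to generate.
#' @param target_case_fraction probability that a member is a planted case.
#' @param background_code_rates named numeric vector, medical code ->
#'   per-year probability of one claim with that code. Codes that look like
#'   five-digit numbers are emitted as CPT procedure claims, all others as
#'   ICD-9 diagnoses. Must not contain any ADRD diagnosis code.
#' @param background_drug_rates named numeric vector, drug name -> per-year
#'   fill probability. Must not contain the qualifying ADRD drugs.
#' @param planted_risk_codes named numeric vector, medical code -> odds
#'   multiplier applied to cases (relative to `risk_code_base_prob`) for
#'   presence of that code in the 4th-5th pre-index-year window.
#' @param risk_code_base_prob control-arm probability of a risk code
#'   appearing in the window.
#' @param trajectory_mix named proportions over the five case patterns
#'   (see [inject_case_trajectory()]); must sum to 1.
#' @param span_length_range length-2 integer, enrollment span length range
#'   in days (uniform draw).
#' @param index_offset_range length-2 integer, days from span start to the
#'   planted index date (uniform draw). The default floor of 1827 days
#'   guarantees planted cases can satisfy a 60-month washout; the default
#'   range matches enrollment-to-index durations observed in large claims
#'   cohorts (roughly 5 to 7.5 years).
#' @param enrollment_start first possible span start date.
#' @param enrollment_start_window_days span starts are drawn uniformly in
#'   `[enrollment_start, enrollment_start + window]`.
#' @param birth_year_range inclusive birth-year range (uniform draw).
#' @param ltc_rate probability of the long-term-care residence flag.
#' @param seed integer RNG seed; a fixed seed makes the generated dataset
#'   (and its CSV export) bit-identical across runs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_members = 1000L,
                       target_case_fraction = 0.05,
                       background_code_rates = c(
                         # common chronic/acute ICD-9 diagnoses
                         "401.9" = 0.25, "272.4" = 0.20, "272.0" = 0.12,
                         "729.5" = 0.10, "780.79" = 0.10, "250.00" = 0.08,
                         "465.9" = 0.12, "462" = 0.08, "724.2" = 0.08,
                         "786.50" = 0.07, "530.81" = 0.07, "715.90" = 0.06,
                         "786.2" = 0.06, "244.9" = 0.06, "285.9" = 0.05,
                         "599.0" = 0.05, "414.00" = 0.05, "496" = 0.05,
                         "427.31" = 0.04, "268.9" = 0.04,
                         # CPT procedures (radiology chapter plus an ECG)
                         "71020" = 0.15, "77052" = 0.08, "76499" = 0.06,
                         "70450" = 0.05, "77080" = 0.05, "93000" = 0.10
                       ),
                       background_drug_rates = c(
                         "simvastatin" = 0.12, "lisinopril" = 0.10,
                         "azithromycin" = 0.15, "amoxicillin" = 0.12,
                         "hydrocodone bit/acetaminophen" = 0.10,
                         "levothyroxine sodium" = 0.08,
                         "metformin hcl" = 0.07, "furosemide" = 0.05
                       ),
                       planted_risk_codes = c(
                         "780.93" = 4, "332.0" = 3, "331.83" = 3,
                         "296.80" = 2.5, "298.9" = 2, "783.21" = 2,
                         "780.97" = 1.8, "V15.88" = 1.5
                       ),
                       risk_code_base_prob = 0.05,
                       trajectory_mix = c(
                         inpatient_only = 0.2,
                         inpatient_late_confirm = 0.2,
                         outpatient_pair = 0.2,
                         memantine_confirmed = 0.2,
                         monotherapy_fills = 0.2
                       ),
                       span_length_range = c(1400L, 4000L),
                       index_offset_range = c(1827L, 2735L),
                       enrollment_start = as.Date("2001-01-01"),
                       enrollment_start_window_days = 1460L,
                       birth_year_range = c(1920L, 1965L),
                       ltc_rate = 0.03,
                       seed = 1L) {
  cfg <- list(
    n_members = as.integer(n_members),
    target_case_fraction = target_case_fraction,
    background_code_rates = background_code_rates,
    background_drug_rates = background_drug_rates,
    planted_risk_codes = planted_risk_codes,
    risk_code_base_prob = risk_code_base_prob,
    trajectory_mix = trajectory_mix,
    span_length_range = as.integer(span_length_range),
    index_offset_range = as.integer(index_offset_range),
    enrollment_start = as.Date(enrollment_start),
    enrollment_start_window_days = as.integer(enrollment_start_window_days),
    birth_year_range = as.integer(birth_year_range),
    ltc_rate = ltc_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("configuration error in `%s`: %s", field, why), call. = FALSE)
  }
  if (is.na(cfg$n_members) || cfg$n_members < 0L) {
    bad("n_members", "must be a nonnegative count")
  }
  prop_fields <- c("target_case_fraction", "risk_code_base_prob", "ltc_rate")
  for (f in prop_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      bad(f, "must be a proportion in [0, 1]")
    }
  }
  for (f in c("background_code_rates", "background_drug_rates")) {
    v <- cfg[[f]]
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v))))) {
      bad(f, "must be a named vector")
    }
    if (any(v < 0 | v > 1)) bad(f, "rates must lie in [0, 1]")
  }
  if (length(cfg$planted_risk_codes)) {
    if (is.null(names(cfg$planted_risk_codes))) {
      bad("planted_risk_codes", "must be a named vector")
    }
    if (any(cfg$planted_risk_codes <= 0)) {
      bad("planted_risk_codes", "odds multipliers must be positive")
    }
  }
  mix <- cfg$trajectory_mix
  if (!setequal(names(mix), trajectory_patterns())) {
    bad("trajectory_mix", paste("must be named over:",
                                paste(trajectory_patterns(), collapse = ", ")))
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    bad("trajectory_mix", "proportions must be nonnegative and sum to 1")
  }
  for (f in c("span_length_range", "index_offset_range", "birth_year_range")) {
    v <- cfg[[f]]
    if (length(v) != 2L || anyNA(v) || v[1] > v[2] || v[1] < 0) {
      bad(f, "must be an ordered nonnegative pair")
    }
  }
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  invisible(TRUE)
}

#' The five canonical case trajectory patterns
#'
#' @return Character vector of pattern names:
#' \describe{
#'   \item{inpatient_only}{a single inpatient ADRD diagnosis; index and
#'     confirmation coincide (rule a).}
#'   \item{inpatient_late_confirm}{an outpatient ADRD diagnosis more than
#'     730 days before an inpatient one; the inpatient claim confirms
#'     (rule a) but the earlier claim is the index.}
#'   \item{outpatient_pair}{two outpatient diagnoses 1-730 days apart; the
#'     second confirms, the first is the index (rule b).}
#'   \item{memantine_confirmed}{a memantine fill within 730 days of an
#'     outpatient diagnosis, preceded (by more than 730 days) by an earlier
#'     outpatient diagnosis that becomes the index (rule d).}
#'   \item{monotherapy_fills}{repeated fills of an ADRD monotherapy drug;
#'     the earliest fill is both index and confirmation (rule c).}
#' }
#' @export
trajectory_patterns <- function() {
  c("inpatient_only", "inpatient_late_confirm", "outpatient_pair",
    "memantine_confirmed", "monotherapy_fills")
}

#' Emit claims realising a case trajectory for one member
#'
#' Draws the within-pattern gaps from the current RNG stream and returns
#' the medical and pharmacy claims that make the member a confirmed ADRD
#' case with the given index date under the given pattern.
#'
#' @param member_id member identifier.
#' @param pattern one of [trajectory_patterns()].
#' @param index_date planted index date (earliest qualifying event).
#' @param code_set an [adrd_code_set()]; diagnosis codes are drawn from it.
#' @param span optional one-row span (`start_date`, `end_date`); when
#'   supplied, the function errors if the span does not cover both the
#'   60-month washout before `index_date` and every emitted claim.
#' @return list with `medical` and `pharmacy` claim `data.table`s.
#' @export
inject_case_trajectory <- function(member_id, pattern, index_date, code_set,
                                   span = NULL) {
  pattern <- match.arg(pattern, trajectory_patterns())
  index_date <- as.Date(index_date)
  dx <- function(date, setting) {
    data.table(
      member_id = member_id, service_date = as.Date(date),
      code = sample(code_set$dx_codes, 1L), code_type = "ICD9_DX",
      setting = setting, header_position = sample(1:5, 1L)
    )
  }
  rx <- function(date, drug) {
    data.table(member_id = member_id, fill_date = as.Date(date),
               drug_name = drug)
  }
  med <- NULL
  phr <- NULL
  if (pattern == "inpatient_only") {
    med <- dx(index_date, "inpatient")
  } else if (pattern == "inpatient_late_confirm") {
    gap <- sample(731:1000, 1L)
    med <- rbind(dx(index_date, "outpatient"),
                 dx(index_date + gap, "inpatient"))
  } else if (pattern == "outpatient_pair") {
    gap <- sample(1:730, 1L)
    med <- rbind(dx(index_date, "outpatient"),
                 dx(index_date + gap, "outpatient"))
  } else if (pattern == "memantine_confirmed") {
    g1 <- sample(731:900, 1L)
    g2 <- sample(0:200, 1L)
    med <- rbind(dx(index_date, "outpatient"),
                 dx(index_date + g1, "outpatient"))
    phr <- rx(index_date + g1 + g2, code_set$confirm_drug)
  } else { # monotherapy_fills
    n_fill <- sample(2:4, 1L)
    drug <- sample(code_set$monotherapy_drugs, 1L)
    gaps <- cumsum(c(0L, sample(30:400, n_fill - 1L, replace = TRUE)))
    phr <- rbindlist(lapply(index_date + gaps, rx, drug = drug))
  }
  if (is.null(med)) med <- empty_medical()
  if (is.null(phr)) phr <- empty_pharmacy()

  if (!is.null(span)) {
    span <- as.data.table(span)
    w_start <- add_months(index_date, -60L)
    last_claim <- max(c(med$service_date, phr$fill_date, index_date))
    if (span$start_date[1] > w_start || span$end_date[1] < last_claim) {
      stop(sprintf(
        "enrollment span too short for pattern '%s' at index %s", pattern,
        format(index_date)
      ))
    }
  }
  list(medical = med, pharmacy = phr)
}

empty_medical <- function() {
  data.table(
    member_id = character(0), service_date = as.Date(character(0)),
    code = character(0), code_type = character(0), setting = character(0),
    header_position = integer(0)
  )
}

empty_pharmacy <- function() {
  data.table(
    member_id = character(0), fill_date = as.Date(character(0)),
    drug_name = character(0)
  )
}

#' Generate a synthetic claims dataset
#'
#' Seeded generation of members, spans, claims and a truth sidecar. Planted
#' cases realise their assigned trajectory at the planted index date, keep
#' a clean 60-month pre-index washout (background generation never emits
#' ADRD codes or qualifying drugs, so the trajectory claims are the only
#' qualifying events), and carry planted risk codes in the 4th-5th
#' pre-index-year window at odds-multiplied rates. Controls receive risk
#' codes at the base rate in the window around their own (sidecar-only)
#' reference index date.
#'
#' The truth sidecar (`truth` element) records planted labels, patterns,
#' planted index dates and reference index dates; it exists for validation
#' and is never consumed by the pipeline stages.
#'
#' @param config a [sim_config()].
#' @param code_set an [adrd_code_set()] used for trajectory injection;
#'   background rates must not mention its codes or drugs.
#' @return A list of class `claims_dataset` with elements `members`,
#'   `spans`, `medical_claims`, `pharmacy_claims`, `truth`.
#' @export
simulate_claims <- function(config = sim_config(), code_set = adrd_code_set()) {
  validate_sim_config(config)
  if (any(names(config$background_code_rates) %in% code_set$dx_codes)) {
    stop("configuration error in `background_code_rates`: ",
         "must not contain ADRD diagnosis codes")
  }
  if (any(norm_drug(names(config$background_drug_rates)) %in%
          c(code_set$monotherapy_drugs, code_set$confirm_drug))) {
    stop("configuration error in `background_drug_rates`: ",
         "must not contain qualifying ADRD drugs")
  }
  set.seed(config$seed)
  n <- config$n_members
  if (n == 0L) {
    ds <- list(
      members = data.table(member_id = character(0), birth_year = integer(0),
                           gender = character(0), ltc_flag = logical(0)),
      spans = data.table(member_id = character(0),
                         start_date = as.Date(character(0)),
                         end_date = as.Date(character(0))),
      medical_claims = empty_medical(),
      pharmacy_claims = empty_pharmacy(),
      truth = data.table(member_id = character(0), planted_case = logical(0),
                         pattern = character(0),
                         planted_index_date = as.Date(character(0)),
                         ref_index_date = as.Date(character(0)))
    )
    class(ds) <- "claims_dataset"
    return(ds)
  }

  id <- sprintf("M%07d", seq_len(n))
  members <- data.table(
    member_id = id,
    birth_year = sample(config$birth_year_range[1]:config$birth_year_range[2],
                        n, replace = TRUE),
    gender = sample(c("male", "female"), n, replace = TRUE),
    ltc_flag = runif(n) < config$ltc_rate
  )

  start_date <- config$enrollment_start +
    sample(0:config$enrollment_start_window_days, n, replace = TRUE)
  span_len <- sample(config$span_length_range[1]:config$span_length_range[2],
                     n, replace = TRUE)
  dur_to_index <- sample(config$index_offset_range[1]:config$index_offset_range[2],
                         n, replace = TRUE)
  ref_index <- start_date + dur_to_index

  planted <- runif(n) < config$target_case_fraction
  pattern <- rep(NA_character_, n)
  pattern[planted] <- sample(names(config$trajectory_mix), sum(planted),
                             replace = TRUE, prob = config$trajectory_mix)

  # case trajectories; spans are stretched so the whole trajectory plus the
  # pre-index washout fits inside the member's single span
  med_parts <- list(NULL)
  phr_parts <- list(NULL)
  end_date <- start_date + span_len
  for (i in which(planted)) {
    traj <- inject_case_trajectory(id[i], pattern[i], ref_index[i], code_set)
    last_claim <- max(c(traj$medical$service_date, traj$pharmacy$fill_date,
                        ref_index[i]))
    tail_pad <- sample(30:180, 1L)
    end_date[i] <- max(end_date[i], last_claim + tail_pad)
    med_parts[[length(med_parts) + 1L]] <- traj$medical
    phr_parts[[length(phr_parts) + 1L]] <- traj$pharmacy
  }
  spans <- data.table(member_id = id, start_date = start_date,
                      end_date = end_date)
  span_years <- pmax(1L, as.integer(round((span_len + 1) / 365.25)))

  # background medical codes: per-year Bernoulli presence, dates uniform in
  # the member's span
  for (k in seq_along(config$background_code_rates)) {
    code_k <- names(config$background_code_rates)[k]
    rate <- config$background_code_rates[[k]]
    n_claims <- rbinom(n, span_years, rate)
    who <- rep.int(seq_len(n), n_claims)
    if (length(who)) {
      offs <- floor(runif(length(who)) *
                      (as.integer(end_date[who] - start_date[who]) + 1))
      is_cpt <- grepl("^[0-9]{5}$", code_k)
      med_parts[[length(med_parts) + 1L]] <- data.table(
        member_id = id[who],
        service_date = start_date[who] + offs,
        code = code_k,
        code_type = if (is_cpt) "CPT" else "ICD9_DX",
        setting = if (is_cpt) "outpatient" else {
          sample(c("outpatient", "inpatient", "other"), length(who),
                 replace = TRUE, prob = c(0.75, 0.10, 0.15))
        },
        header_position = sample(1:5, length(who), replace = TRUE)
      )
    }
  }

  # background drug fills
  for (k in seq_along(config$background_drug_rates)) {
    drug_k <- names(config$background_drug_rates)[k]
    rate <- config$background_drug_rates[[k]]
    n_claims <- rbinom(n, span_years, rate)
    who <- rep.int(seq_len(n), n_claims)
    if (length(who)) {
      offs <- floor(runif(length(who)) *
                      (as.integer(end_date[who] - start_date[who]) + 1))
      phr_parts[[length(phr_parts) + 1L]] <- data.table(
        member_id = id[who],
        fill_date = start_date[who] + offs,
        drug_name = drug_k
      )
    }
  }

  # planted risk codes: presence in the feature window (days 1096-1825
  # before the reference index) with case odds multiplied; emitted only
  # when the window lies inside the span
  win_hi <- ref_index - 1096L
  win_lo <- ref_index - 1825L
  covered <- win_lo >= start_date & win_hi <= end_date
  p0 <- config$risk_code_base_prob
  odds0 <- p0 / (1 - p0)
  for (k in seq_along(config$planted_risk_codes)) {
    code_k <- names(config$planted_risk_codes)[k]
    mult <- config$planted_risk_codes[[k]]
    p1 <- mult * odds0 / (1 + mult * odds0)
    p <- ifelse(planted, p1, p0)
    present <- runif(n) < p & covered
    who <- which(present)
    if (length(who)) {
      offs <- floor(runif(length(who)) * 730)
      med_parts[[length(med_parts) + 1L]] <- data.table(
        member_id = id[who],
        service_date = win_lo[who] + offs,
        code = code_k,
        code_type = if (grepl("^[0-9]{5}$", code_k)) "CPT" else "ICD9_DX",
        setting = "outpatient",
        header_position = sample(1:5, length(who), replace = TRUE)
      )
    }
  }

  medical <- rbindlist(c(list(empty_medical()), med_parts[-1L]))
  pharmacy <- rbindlist(c(list(empty_pharmacy()), phr_parts[-1L]))
  setorderv(medical, c("member_id", "service_date", "code"))
  setorderv(pharmacy, c("member_id", "fill_date", "drug_name"))

  truth <- data.table(
    member_id = id,
    planted_case = planted,
    pattern = pattern,
    planted_index_date = fifelse(planted, ref_index, as.Date(NA)),
    ref_index_date = ref_index
  )
  ds <- list(members = members, spans = spans, medical_claims = medical,
             pharmacy_claims = pharmacy, truth = truth)
  class(ds) <- "claims_dataset"
  validate_claims_dataset(ds)
  ds
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat("  members:         ", nrow(x$members), "\n")
  cat("  spans:           ", nrow(x$spans), "\n")
  cat("  medical claims:  ", nrow(x$medical_claims), "\n")
  cat("  pharmacy claims: ", nrow(x$pharmacy_claims), "\n")
  if (!is.null(x$truth) && nrow(x$truth)) {
    cat("  planted cases:   ", sum(x$truth$planted_case), "\n")
  }
  invisible(x)
}

#' Validate referential and temporal integrity of a claims dataset
#'
#' Checks member-id uniqueness, that every claim belongs to a known member
#' and falls inside one of that member's enrollment spans, that spans of a
#' member do not overlap, and that the truth sidecar covers all members.
#'
#' @param ds a `claims_dataset`.
#' @return `TRUE` invisibly; errors on the first violated invariant.
#' @export
validate_claims_dataset <- function(ds) {
  m <- as.data.table(ds$members)
  s <- as.data.table(ds$spans)
  if (anyDuplicated(m$member_id)) stop("duplicate member_id in members")
  if (!all(s$member_id %chin% m$member_id)) stop("span for unknown member")
  if (nrow(s)) {
    if (any(s$start_date > s$end_date)) stop("span with start after end")
    ov <- s[order(member_id, start_date)][
      , any(start_date[-1L] <= end_date[-.N]), by = member_id][V1 == TRUE]
    if (nrow(ov)) stop("overlapping spans for member ", ov$member_id[1])
  }
  in_span <- function(ids, dates) {
    if (!length(ids)) return(TRUE)
    dt <- data.table(member_id = ids, d = dates)
    hit <- s[dt, on = .(member_id, start_date <= d, end_date >= d),
             nomatch = NULL]
    nrow(hit) == nrow(dt)
  }
  med <- as.data.table(ds$medical_claims)
  phr <- as.data.table(ds$pharmacy_claims)
  if (!all(med$member_id %chin% m$member_id)) stop("medical claim for unknown member")
  if (!all(phr$member_id %chin% m$member_id)) stop("pharmacy claim for unknown member")
  if (nrow(med) && any(!nzchar(med$code))) stop("empty medical code")
  if (nrow(phr) && any(!nzchar(phr$drug_name))) stop("empty drug name")
  if (!in_span(med$member_id, med$service_date)) {
    stop("medical claim dated outside every span of its member")
  }
  if (!in_span(phr$member_id, phr$fill_date)) {
    stop("pharmacy claim dated outside every span of its member")
  }
  if (!is.null(ds$truth)) {
    tr <- as.data.table(ds$truth)
    if (!setequal(tr$member_id, m$member_id)) {
      stop("truth sidecar does not cover exactly the member set")
    }
  }
  invisible(TRUE)
}

#' Write / read a claims dataset as CSV tables
#'
#' Writes `members.csv`, `spans.csv`, `medical_claims.csv`,
#' `pharmacy_claims.csv` and the sidecar `truth.csv` with ISO-8601 dates.
#' With a fixed generator seed the exported files are byte-identical across
#' runs.
#'
#' @param ds a `claims_dataset`.
#' @param dir output (input) directory.
#' @return `write_claims_dataset()` the directory invisibly;
#'   `read_claims_dataset()` a `claims_dataset`.
#' @export
write_claims_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite(ds$members, file.path(dir, "members.csv"))
  fwrite(ds$spans, file.path(dir, "spans.csv"))
  fwrite(ds$medical_claims, file.path(dir, "medical_claims.csv"))
  fwrite(ds$pharmacy_claims, file.path(dir, "pharmacy_claims.csv"))
  if (!is.null(ds$truth)) fwrite(ds$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_claims_dataset
#' @export
read_claims_dataset <- function(dir) {
  rd <- function(f) fread(file.path(dir, f))
  as_date_cols <- function(dt, cols) {
    for (cl in intersect(cols, names(dt))) set(dt, j = cl, value = as.Date(dt[[cl]]))
    dt
  }
  ds <- list(
    members = rd("members.csv"),
    spans = as_date_cols(rd("spans.csv"), c("start_date", "end_date")),
    medical_claims = as_date_cols(rd("medical_claims.csv"), "service_date"),
    pharmacy_claims = as_date_cols(rd("pharmacy_claims.csv"), "fill_date")
  )
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) {
    ds$truth <- as_date_cols(fread(tf),
                             c("planted_index_date", "ref_index_date"))
  }
  class(ds) <- "claims_dataset"
  ds
}

#' Hand-built single-member fixtures for the five case patterns
#'
#' Five tiny datasets with fixed dates, one per canonical trajectory, each
#' paired with the case determination the phenotyper must produce. They
#' double as executable documentation of the outcome rules.
#'
#' @param code_set an [adrd_code_set()]; the first diagnosis code and the
#'   listed drugs are used.
#' @return A named list of five elements, each `list(dataset, expected)`
#'   where `expected` is a one-row `data.table` with `member_id`,
#'   `is_case`, `index_date`, `confirmation_date`, `rule`.
#' @export
case_pattern_fixtures <- function(code_set = adrd_code_set()) {
  dxc <- code_set$dx_codes[1]
  mk <- function(id, span_start, span_end, med, phr, index, conf, rule,
                 pattern) {
    ds <- list(
      members = data.table(member_id = id, birth_year = 1940L,
                           gender = "female", ltc_flag = FALSE),
      spans = data.table(member_id = id, start_date = as.Date(span_start),
                         end_date = as.Date(span_end)),
      medical_claims = if (is.null(med)) empty_medical() else med,
      pharmacy_claims = if (is.null(phr)) empty_pharmacy() else phr,
      truth = data.table(member_id = id, planted_case = TRUE,
                         pattern = pattern,
                         planted_index_date = as.Date(index),
                         ref_index_date = as.Date(index))
    )
    class(ds) <- "claims_dataset"
    list(
      dataset = ds,
      expected = data.table(member_id = id, is_case = TRUE,
                            index_date = as.Date(index),
                            confirmation_date = as.Date(conf), rule = rule)
    )
  }
  med_row <- function(id, date, setting, pos = 1L) {
    data.table(member_id = id, service_date = as.Date(date), code = dxc,
               code_type = "ICD9_DX", setting = setting,
               header_position = as.integer(pos))
  }
  rx_row <- function(id, date, drug) {
    data.table(member_id = id, fill_date = as.Date(date), drug_name = drug)
  }
  list(
    inpatient_only = mk(
      "F1", "2004-01-01", "2012-12-31",
      med_row("F1", "2010-06-15", "inpatient"), NULL,
      index = "2010-06-15", conf = "2010-06-15", rule = "a", pattern = "inpatient_only"
    ),
    inpatient_late_confirm = mk(
      "F2", "2002-06-01", "2012-12-31",
      rbind(med_row("F2", "2008-01-10", "outpatient", 2L),
            med_row("F2", "2010-06-15", "inpatient")), NULL,
      index = "2008-01-10", conf = "2010-06-15", rule = "a", pattern = "inpatient_late_confirm"
    ),
    outpatient_pair = mk(
      "F3", "2004-01-01", "2012-12-31",
      rbind(med_row("F3", "2010-01-05", "outpatient", 3L),
            med_row("F3", "2010-07-01", "outpatient")), NULL,
      index = "2010-01-05", conf = "2010-07-01", rule = "b", pattern = "outpatient_pair"
    ),
    memantine_confirmed = mk(
      "F4", "2001-06-01", "2012-12-31",
      rbind(med_row("F4", "2007-03-01", "outpatient"),
            med_row("F4", "2010-02-01", "outpatient")),
      rx_row("F4", "2010-05-01", code_set$confirm_drug),
      index = "2007-03-01", conf = "2010-05-01", rule = "d", pattern = "memantine_confirmed"
    ),
    monotherapy_fills = mk(
      "F5", "2004-01-01", "2012-12-31",
      NULL,
      rbindlist(lapply(c("2010-04-01", "2010-10-01", "2011-04-01"), rx_row,
                       id = "F5", drug = code_set$monotherapy_drugs[1])),
      index = "2010-04-01", conf = "2010-04-01", rule = "c", pattern = "monotherapy_fills"
    )
  )
}
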