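# Independent oracles and small builders shared across test files.
# The oracles deliberately use brute-force enumeration, never the package's
# own code paths.

library(data.table)

# ---- claim builders ---------------------------------------------------------

med_claim <- function(id, date, code = "331.0", setting = "outpatient",
                      pos = 1L, type = "ICD9_DX") {
  data.table(member_id = id, service_date = as.Date(date), code = code,
             code_type = type, setting = setting,
             header_position = as.integer(pos))
}

rx_claim <- function(id, date, drug) {
  data.table(member_id = id, fill_date = as.Date(date), drug_name = drug)
}

no_med <- function() med_claim("x", "2000-01-01")[0L]
no_rx <- function() rx_claim("x", "2000-01-01", "d")[0L]

# turn an abstract event sequence into claims; kinds:
# inpatient_dx / outpatient_dx / other_dx / mono / mem
events_to_claims <- function(id, dates, kinds, code_set = adrd_code_set()) {
  dates <- as.Date(dates, origin = "1970-01-01")
  med <- no_med()
  rx <- no_rx()
  for (i in seq_along(dates)) {
    k <- kinds[i]
    if (k %in% c("inpatient_dx", "outpatient_dx", "other_dx")) {
      med <- rbind(med, med_claim(id, dates[i], code = code_set$dx_codes[1],
                                  setting = sub("_dx$", "", k)))
    } else if (k == "mono") {
      rx <- rbind(rx, rx_claim(id, dates[i], code_set$monotherapy_drugs[1]))
    } else {
      rx <- rbind(rx, rx_claim(id, dates[i], code_set$confirm_drug))
    }
  }
  list(medical = med, pharmacy = rx)
}

# ---- brute-force case-determination oracle ---------------------------------

# enumerates every event and event pair against the four criteria
oracle_determine <- function(dates, kinds, code_set = adrd_code_set()) {
  d <- as.integer(as.Date(dates, origin = "1970-01-01"))
  dx <- d[kinds %in% c("inpatient_dx", "outpatient_dx", "other_dx")]
  inpt <- d[kinds == "inpatient_dx"]
  mono <- d[kinds == "mono"]
  mem <- d[kinds == "mem"]
  bw <- code_set$confirm_window_days
  mw <- code_set$memantine_window_days

  confs <- c(a = Inf, b = Inf, c = Inf, d = Inf)
  if (length(inpt)) confs["a"] <- min(inpt)
  if (length(dx) >= 2L) {
    for (i in seq_along(dx)) for (j in seq_along(dx)) {
      if (i < j || j < i) {
        gap <- abs(dx[i] - dx[j])
        if (gap >= bw[1] && gap <= bw[2]) {
          confs["b"] <- min(confs["b"], max(dx[i], dx[j]))
        }
      }
    }
  }
  if (length(mono)) confs["c"] <- min(mono)
  for (m in mem) for (x in dx) {
    gap <- abs(m - x)
    if (gap >= mw[1] && gap <= mw[2]) {
      confs["d"] <- min(confs["d"], max(m, x))
    }
  }
  if (all(!is.finite(confs))) {
    return(list(is_case = FALSE, index_date = as.Date(NA),
                confirmation_date = as.Date(NA), rule = NA_character_))
  }
  best <- which.min(confs)  # ties resolved a > b > c > d by position
  list(
    is_case = TRUE,
    index_date = as.Date(min(d), origin = "1970-01-01"),
    confirmation_date = as.Date(confs[[best]], origin = "1970-01-01"),
    rule = names(confs)[best]
  )
}

# random event sequence (<= max_len events) for property tests
random_event_sequence <- function(max_len = 8L, origin = as.Date("2008-01-01"),
                                  horizon = 1500L) {
  n <- sample.int(max_len, 1L)
  kinds <- sample(c("inpatient_dx", "outpatient_dx", "other_dx", "mono", "mem"),
                  n, replace = TRUE)
  dates <- origin + sample.int(horizon, n, replace = TRUE)
  list(dates = dates, kinds = kinds)
}

# ---- all-pairs AUC oracle ---------------------------------------------------

oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# ---- feature-matrix builder for model tests --------------------------------

fm_from_matrix <- function(x, y) {
  x <- Matrix::Matrix(x, sparse = TRUE)
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%04d", seq_len(ncol(x)))
  structure(
    list(matrix = methods::as(x, "CsparseMatrix"), vocabulary = colnames(x),
         member_id = as.character(seq_len(nrow(x))), label = as.integer(y)),
    class = "feature_matrix"
  )
}

# tiny cohort dataset wrapper for feature tests
mini_dataset <- function(members, spans, medical = no_med(), pharmacy = no_rx()) {
  structure(list(members = members, spans = spans, medical_claims = medical,
                 pharmacy_claims = pharmacy), class = "claims_dataset")
}
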