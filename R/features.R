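#' Restrict claims to the pre-index feature window
#'
#' The model looks at the fourth and fifth years before each member's index
#' date, i.e. claims dated between 1825 and 1096 days before the index,
#' both bounds inclusive (365-day years; leap days are ignored for window
#' arithmetic so the window is a fixed 730-day block).
#'
#' @param claims a claims table with a `member_id` and a date column.
#' @param index_dates `data.table` with `member_id`, `index_date`.
#' @param date_col name of the claim date column (`"service_date"` or
#'   `"fill_date"`).
#' @param window inclusive day-offset bounds before the index date.
#' @return The windowed subset of `claims` (one row per claim-index match).
#' @export
window_claims <- function(claims, index_dates, date_col = "service_date",
                          window = c(1096L, 1825L)) {
  claims <- as.data.table(claims)
  index_dates <- as.data.table(index_dates)[, .(member_id, index_date)]
  if (nrow(claims) == 0L || nrow(index_dates) == 0L) return(claims[0L])
  x <- merge(claims, index_dates, by = "member_id", allow.cartesian = TRUE)
  off <- as.integer(x$index_date - x[[date_col]])
  x[off >= window[1] & off <= window[2]][, index_date := NULL][]
}

#' Build the sparse binary feature matrix
#'
#' One row per cohort member, one column per feature, entries in \{0, 1\}.
#' Clinical indicators are 1 iff the member has at least one windowed claim
#' with the code (diagnosis codes, drug names, and CPT procedure codes
#' restricted to a radiology range); counts are never used. Demographic
#' indicators are 5-year age bins at the index date (ages above 89 mapped
#' to 89; 65-69 is the reference and carries no indicator) and a female
#' indicator (male reference).
#'
#' When `vocabulary` is `NULL` the vocabulary is built from the supplied
#' rows: clinical features observed at least once (all-zero columns never
#' enter) plus the fixed demographic block (age bins 40-44 through 85-89
#' minus the reference, then `FEMALE`). Pass a training vocabulary when
#' building a test matrix: features outside it are dropped, never added,
#' and training features unseen in test yield all-zero columns.
#'
#' @param cohort `data.table` with `member_id`, `index_date` and a `label`
#'   column (1 = case, 0 = control).
#' @param dataset the `claims_dataset` supplying claims and demographics.
#' @param vocabulary optional frozen feature vocabulary (character).
#' @param cpt_range inclusive numeric CPT range kept as procedure features
#'   (default 70000-79999, the radiology chapter).
#' @return An object of class `feature_matrix`: list with `matrix` (a
#'   `dgCMatrix`), `vocabulary`, `member_id`, `label`.
#' @export
build_feature_matrix <- function(cohort, dataset, vocabulary = NULL,
                                 cpt_range = c(70000, 79999)) {
  cohort <- as.data.table(cohort)
  stopifnot(all(c("member_id", "index_date", "label") %in% names(cohort)))
  if (anyNA(cohort$index_date)) stop("every cohort member needs an index date")
  members <- as.data.table(dataset$members)
  missing_demo <- setdiff(cohort$member_id, members$member_id)
  if (length(missing_demo)) {
    stop("no demographics for member(s): ",
         paste(head(missing_demo, 5L), collapse = ", "))
  }

  med <- window_claims(dataset$medical_claims, cohort, "service_date")
  phr <- window_claims(dataset$pharmacy_claims, cohort, "fill_date")

  clin <- rbind(
    if (nrow(med)) {
      m <- copy(med)
      m[, feature := fifelse(code_type == "CPT", paste0("CPT_", code),
                             paste0("DX_", code))]
      keep <- m$code_type != "CPT" |
        (suppressWarnings(as.numeric(m$code)) >= cpt_range[1] &
         suppressWarnings(as.numeric(m$code)) <= cpt_range[2] &
         !is.na(suppressWarnings(as.numeric(m$code))))
      m[keep, .(member_id, feature)]
    } else data.table(member_id = character(0), feature = character(0)),
    if (nrow(phr)) {
      phr[, .(member_id, feature = paste0("RX_", toupper(norm_drug(drug_name))))]
    } else data.table(member_id = character(0), feature = character(0))
  )
  clin <- unique(clin)

  # demographics at index
  demo <- members[match(cohort$member_id, member_id),
                  .(member_id, birth_year, gender)]
  age <- data.table::year(cohort$index_date) - demo$birth_year
  bins <- gsub("-", "_", paste0("AGE_", age_bin(age)))
  demo_rows <- rbind(
    data.table(member_id = cohort$member_id, feature = bins)[
      feature != "AGE_65_69"],
    data.table(member_id = cohort$member_id,
               feature = "FEMALE")[demo$gender == "female"]
  )

  all_bins <- gsub("-", "_", paste0("AGE_", age_bin(seq(40, 89, by = 5))))
  demo_vocab <- c(setdiff(all_bins, "AGE_65_69"), "FEMALE")

  if (is.null(vocabulary)) {
    vocabulary <- c(sort(unique(clin$feature)), demo_vocab)
  }
  entries <- rbind(clin, demo_rows)[feature %chin% vocabulary]
  entries <- entries[member_id %chin% cohort$member_id]

  mat <- Matrix::sparseMatrix(
    i = match(entries$member_id, cohort$member_id),
    j = match(entries$feature, vocabulary),
    x = 1,
    dims = c(nrow(cohort), length(vocabulary)),
    dimnames = list(cohort$member_id, vocabulary)
  )
  mat@x[] <- 1  # duplicates collapse by summation; force binary

  structure(
    list(matrix = mat, vocabulary = vocabulary,
         member_id = cohort$member_id, label = as.integer(cohort$label)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d, %.3f%% nonzero, %d cases / %d controls\n",
              nrow(x$matrix), ncol(x$matrix),
              100 * Matrix::nnzero(x$matrix) / max(1, prod(dim(x$matrix))),
              sum(x$label == 1L), sum(x$label == 0L)))
  invisible(x)
}

# clinical (non-demographic) column indices of a feature matrix
clinical_columns <- function(fm) {
  which(!grepl("^AGE_", fm$vocabulary) & fm$vocabulary != "FEMALE")
}

#' Data-sparsity profile: cumulative distribution of per-member code counts
#'
#' For each label, tabulates the number of distinct clinical codes per
#' member (demographic indicators excluded) and the cumulative percentage
#' of members with at most that many codes. Reproduces the classic
#' "most members have fewer than a handful of codes" sparsity picture.
#'
#' @param fm a [build_feature_matrix()] result.
#' @return `data.table` with `label`, `n_codes`, `n_members`, `cum_pct`.
#' @export
sparsity_profile <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  cc <- clinical_columns(fm)
  counts <- if (length(cc)) {
    as.integer(Matrix::rowSums(fm$matrix[, cc, drop = FALSE]))
  } else rep(0L, nrow(fm$matrix))
  dt <- data.table(label = fm$label, n_codes = counts)
  prof <- dt[, .(n_members = .N), keyby = .(label, n_codes)]
  prof[, cum_pct := 100 * cumsum(n_members) / sum(n_members), by = label]
  prof[]
}
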