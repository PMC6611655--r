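#' ADRD code set: diagnosis codes, qualifying drugs and confirmation windows
#'
#' Bundles everything the phenotyper needs to recognise a qualifying ADRD
#' event: the ICD-9 diagnosis code list, the four cholinesterase-inhibitor
#' monotherapy drugs whose fill alone qualifies, the confirmation drug
#' (memantine hydrochloride, which requires a diagnosis claim nearby because
#' it is also used outside dementia), and the day windows for the
#' two-claim-confirmation and memantine-confirmation rules.
#'
#' The default diagnosis list covers the classic ICD-9 dementia families
#' (senile/presenile dementias 290.x, persisting amnestic/dementia states
#' 294.1x/294.2x, Alzheimer's 331.0, frontotemporal 331.1, Lewy body
#' 331.82). Production users should supply the code list mandated by their
#' own protocol; every function in the package takes the code set as an
#' argument and nothing downstream depends on the default membership.
#'
#' @param dx_codes character vector of ICD-9 diagnosis codes (dotted form).
#' @param monotherapy_drugs drug names (ingredient level) whose fill alone
#'   qualifies a member as a case.
#' @param confirm_drug drug name requiring diagnosis confirmation.
#' @param confirm_window_days length-2 integer, inclusive day-gap bounds
#'   between the two diagnosis claims of the two-claim rule.
#' @param memantine_window_days length-2 integer, inclusive absolute day-gap
#'   bounds between a `confirm_drug` fill and a diagnosis claim.
#' @return An object of class `adrd_code_set`.
#' @examples
#' cs <- adrd_code_set()
#' cs$confirm_window_days
#' @export
adrd_code_set <- function(dx_codes = c(
                            "290.0", "290.10", "290.11", "290.12", "290.13",
                            "290.20", "290.21", "290.3",
                            "290.40", "290.41", "290.42", "290.43",
                            "294.10", "294.11", "294.20", "294.21",
                            "331.0", "331.1", "331.82"
                          ),
                          monotherapy_drugs = c(
                            "donepezil hydrochloride",
                            "galantamine hydrobromide",
                            "rivastigmine tartrate",
                            "tacrine hydrochloride"
                          ),
                          confirm_drug = "memantine hydrochloride",
                          confirm_window_days = c(1L, 730L),
                          memantine_window_days = c(0L, 730L)) {
  dx_codes <- as.character(dx_codes)
  if (length(dx_codes) == 0L) stop("`dx_codes` must be non-empty")
  check_window <- function(w, what) {
    if (length(w) != 2L || anyNA(w) || w[1] < 0 || w[1] > w[2]) {
      stop(sprintf("`%s` must satisfy 0 <= lower <= upper", what))
    }
    as.integer(w)
  }
  structure(
    list(
      dx_codes = unique(dx_codes),
      monotherapy_drugs = tolower(trimws(monotherapy_drugs)),
      confirm_drug = tolower(trimws(confirm_drug)),
      confirm_window_days = check_window(confirm_window_days, "confirm_window_days"),
      memantine_window_days = check_window(memantine_window_days, "memantine_window_days")
    ),
    class = "adrd_code_set"
  )
}

#' @export
print.adrd_code_set <- function(x, ...) {
  cat("<adrd_code_set>\n")
  cat("  dx codes:          ", length(x$dx_codes), "\n")
  cat("  monotherapy drugs: ", paste(x$monotherapy_drugs, collapse = ", "), "\n")
  cat("  confirm drug:      ", x$confirm_drug, "\n")
  cat(sprintf("  two-claim window:   [%d, %d] days\n",
              x$confirm_window_days[1], x$confirm_window_days[2]))
  cat(sprintf("  memantine window:   [%d, %d] days\n",
              x$memantine_window_days[1], x$memantine_window_days[2]))
  invisible(x)
}

# normalise a drug name for matching
norm_drug <- function(x) tolower(trimws(x))
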