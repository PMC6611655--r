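# Calendar helpers.
#
# Month arithmetic uses lubridate's rollback semantics: subtracting 60
# months from 2012-02-29 gives 2007-02-28 (clamped at month end), never an
# invalid date. Year arithmetic likewise.

add_months <- function(date, n) {
  date %m+% lubridate::period(month = as.integer(n))
}

add_years <- function(date, n) {
  date %m+% lubridate::period(year = as.integer(n))
}
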