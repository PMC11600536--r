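## Calendar helpers.  All registry dates are day-resolution `Date`s; trial
## months are derived, never stored (the prescribed drug register is daily).

`%||%` <- function(a, b) if (is.null(a)) b else a

## year*12 + (month-1), an integer month index useful for month arithmetic
year_month <- function(x) {
  lt <- as.POSIXlt(x)
  (lt$year + 1900L) * 12L + lt$mon
}

ym_to_date <- function(ym) {
  as.Date(sprintf("%d-%02d-01", ym %/% 12L, ym %% 12L + 1L))
}

#' First day of the calendar month containing `x`
#' @param x a `Date` vector
#' @return a `Date` vector
#' @keywords internal
month_start <- function(x) ym_to_date(year_month(x))

is_month_aligned <- function(x) {
  all(as.POSIXlt(x)$mday == 1L)
}

#' Add calendar months to a date (day-of-month kept at 1)
#' @keywords internal
add_months <- function(x, k) ym_to_date(year_month(x) + as.integer(k))

#' Age in completed years at a reference date
#'
#' Birthday arithmetic (registry convention), not division by 365.25: a woman
#' is aged 50 from her 50th birthday until the day before her 51st.
#'
#' @param birth,at `Date` vectors (recycled)
#' @return integer vector of completed years
#' @export
completed_years <- function(birth, at) {
  b <- as.POSIXlt(birth)
  a <- as.POSIXlt(at)
  age <- (a$year - b$year) -
    ((a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday))
  as.integer(age)
}

## parse dates from text columns; unparseable non-missing values are an error
## naming the offending line numbers (header is line 1)
parse_date_column <- function(x, column, file = "") {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unparseable date(s) in column '%s'%s at line(s) %s",
                 column,
                 if (nzchar(file)) paste0(" of ", file) else "",
                 paste(which(bad) + 1L, collapse = ", ")),
         call. = FALSE)
  }
  out
}
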