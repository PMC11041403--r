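#' Year-month date handling
#'
#' Corpus records carry month-resolution dates. Internally a date is a single
#' integer "ym" counting months on an absolute scale (`year * 12 + month - 1`),
#' which makes span filtering and time binning trivial arithmetic.
#'
#' @param year,month integer vectors.
#' @return integer ym value(s).
#' @keywords internal
ym <- function(year, month) {
  as.integer(year) * 12L + as.integer(month) - 1L
}

ym_year <- function(x) x %/% 12L
ym_month <- function(x) x %% 12L + 1L

#' Parse a year-month string
#'
#' Accepts `"YYYY-MM"`, `"YYYY-MM-DD"` (day ignored) or `"YYYY"`.
#' Year-only dates are assigned July, the mid-year month, so that binning
#' stays deterministic.
#'
#' @param x character vector of date strings.
#' @return integer ym vector; `NA` where unparseable.
#' @export
parse_ym <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  full <- grepl("^\\d{4}-\\d{1,2}(-\\d{1,2})?$", x)
  yonly <- grepl("^\\d{4}$", x)
  if (any(full)) {
    parts <- strsplit(x[full], "-", fixed = TRUE)
    y <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    m <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    bad <- m < 1L | m > 12L
    v <- ym(y, m)
    v[bad] <- NA_integer_
    out[full] <- v
  }
  out[yonly] <- ym(as.integer(x[yonly]), 7L)
  out
}

format_ym <- function(x) sprintf("%04d-%02d", ym_year(x), ym_month(x))
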