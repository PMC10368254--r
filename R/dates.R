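# Calendar-date helpers. All interval arithmetic in this package is
# closed-start / half-open-end on integer day counts; human-facing dates
# always print the last *included* day.

#' Parse ISO-8601 dates strictly
#'
#' Parses `YYYY-MM-DD` strings; anything else (including impossible dates such
#' as `"2010-13-01"` or `"2010-02-30"`) yields `NA` rather than a
#' locale-dependent guess. Empty strings are treated as absent.
#'
#' @param x Character vector of date strings.
#' @return A `Date` vector with `NA` for empty or unparseable entries.
#' @export
parse_iso_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)] <- NA_character_
  out <- as.Date(x, format = "%Y-%m-%d")
  # as.Date() rolls nothing, but guard against platform leniency by
  # round-tripping the text.
  bad <- !is.na(out) & format(out, "%Y-%m-%d") != x
  out[bad] <- as.Date(NA)
  out
}

year_start <- function(year) as.Date(sprintf("%04d-01-01", year))
year_end <- function(year) as.Date(sprintf("%04d-12-31", year))

#' Mid-year index date
#'
#' The point-prevalence index date: 30 June of the given calendar year.
#'
#' @param year Integer calendar year(s).
#' @return A `Date` vector.
#' @export
midyear <- function(year) as.Date(sprintf("%04d-06-30", year))

# Whole days in the half-open interval [a, b); negative spans clamp to zero.
days_between <- function(a, b) pmax(0L, as.integer(b) - as.integer(a))

# Elementwise min/max over date vectors where NA means "absent" and is
# ignored (all-absent yields NA). Scalars recycle.
date_min <- function(...) {
  args <- lapply(list(...), function(x) as.numeric(as.Date(x)))
  n <- if (min(lengths(args)) == 0) 0L else max(lengths(args))
  args <- lapply(args, rep_len, n)
  as.Date(do.call(pmin, c(args, na.rm = TRUE)), origin = "1970-01-01")
}

date_max <- function(...) {
  args <- lapply(list(...), function(x) as.numeric(as.Date(x)))
  n <- if (min(lengths(args)) == 0) 0L else max(lengths(args))
  args <- lapply(args, rep_len, n)
  as.Date(do.call(pmax, c(args, na.rm = TRUE)), origin = "1970-01-01")
}

#' Observation window
#'
#' The maximum calendar span over which annual estimates are computed.
#' Defaults to 1 January 2004 through 31 December 2020.
#'
#' @param start_date,end_date Window bounds (`Date` or ISO-8601 strings),
#'   both inclusive.
#' @return An `observation_window` object.
#' @export
observation_window <- function(start_date = "2004-01-01",
                               end_date = "2020-12-31") {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(!is.na(start_date), !is.na(end_date))
  if (start_date > end_date) {
    stop("observation window start must not be after its end", call. = FALSE)
  }
  structure(list(start_date = start_date, end_date = end_date),
            class = "observation_window")
}

window_years <- function(window) {
  seq.int(as.integer(format(window$start_date, "%Y")),
          as.integer(format(window$end_date, "%Y")))
}
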