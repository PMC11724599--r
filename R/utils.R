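# Shared internal helpers: regions, UTC time handling, small validators.

#' Region labels used throughout the package
#'
#' The study system distinguishes exactly three aquatic regions: the focal
#' coastal sea (`"wadden_sea"`), adjacent marine arrays (`"north_sea"`), and
#' fresh water (`"fresh_water"`). Every station must carry one of these labels
#' and no downstream stage ever sees a fourth.
#'
#' @return Character vector of the three region labels.
#' @export
regions <- function() c("wadden_sea", "north_sea", "fresh_water")

# All timestamps are UTC; a "detection day" is the UTC calendar date.
utc_date <- function(t) as.Date(t, tz = "UTC")

utc_year <- function(t) as.integer(format(t, "%Y", tz = "UTC"))

# Parse ISO-8601-ish timestamps: "YYYY-mm-dd HH:MM:SS", optional "T"
# separator and trailing "Z". Date-only strings get 00:00:00.
parse_timestamp <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  date_only <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  x[date_only] <- paste(x[date_only], "00:00:00")
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  out
}

fmt_timestamp <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mt <- function(...) stop(..., call. = FALSE)

# deterministic CSV writer used by write_dataset() and the pipeline
write_csv_strict <- function(x, path) {
  is_time <- vapply(x, inherits, logical(1), what = "POSIXct")
  x[is_time] <- lapply(x[is_time], fmt_timestamp)
  is_date <- vapply(x, inherits, logical(1), what = "Date")
  x[is_date] <- lapply(x[is_date], format, "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
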