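#' Construct a monthly visit series
#'
#' A `monthly_series` is a tibble with two columns: `month` (a `Date`, always
#' the first day of the month) and `visits` (positive counts). Consecutive
#' rows are consecutive calendar months with no gaps, which is what every
#' fitting routine in the package assumes.
#'
#' @param values Numeric vector of monthly visit counts; all finite and > 0.
#' @param start Integer vector `c(year, month)` giving the calendar position
#'   of the first value (month in 1..12).
#' @return A tibble of class `monthly_series` with columns `month`, `visits`.
#' @examples
#' monthly_series(c(100, 120, 130), start = c(2015, 1))
#' @export
monthly_series <- function(values, start = c(2000, 1)) {
  values <- as.numeric(values)
  if (length(values) < 1) abort("`values` must contain at least one month.")
  if (length(start) != 2 || start[2] < 1 || start[2] > 12) {
    abort("`start` must be c(year, month) with month in 1..12.")
  }
  months <- seq(as.Date(sprintf("%04d-%02d-01", start[1], start[2])),
                by = "month", length.out = length(values))
  out <- tibble::tibble(month = months, visits = values)
  validate_monthly_series(out)
}

#' Coerce a data frame to a monthly series
#'
#' Accepts a data frame with a month column (either `Date` or `"YYYY-MM"`
#' strings) and a numeric count column, sorts it chronologically, and
#' validates the calendar structure. Rows may arrive in any order.
#'
#' @param x A data frame.
#' @param month_col,visits_col Column names holding the month stamp and the
#'   visit count.
#' @return A validated `monthly_series` tibble.
#' @export
as_monthly_series <- function(x, month_col = "month", visits_col = "visits") {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  for (col in c(month_col, visits_col)) {
    if (!col %in% names(x)) abort(paste0("Column `", col, "` not found."))
  }
  month_raw <- x[[month_col]]
  if (inherits(month_raw, "Date")) {
    months <- as.Date(format(month_raw, "%Y-%m-01"))
  } else {
    stamp <- trimws(as.character(month_raw))
    bad <- which(is.na(stamp) | !grepl("^\\d{4}-\\d{2}$", stamp))
    if (length(bad) > 0) {
      abort(paste0("Row ", bad[1], ": month stamp `", stamp[bad[1]],
                   "` is not in YYYY-MM format."))
    }
    months <- as.Date(paste0(stamp, "-01"))
  }
  visits <- x[[visits_col]]
  if (!is.numeric(visits)) {
    suppressWarnings(visits <- as.numeric(as.character(visits)))
  }
  out <- tibble::tibble(month = months, visits = as.numeric(visits))
  out <- dplyr::arrange(out, .data$month)
  validate_monthly_series(out)
}

#' Validate the monthly-series invariants
#'
#' Checks finiteness and positivity of the counts and that the month stamps
#' form a gap-free run of consecutive calendar months. Errors name the first
#' offending row.
#'
#' @param x A data frame with `month` (Date) and `visits` columns.
#' @return `x`, classed as `monthly_series`, invisibly usable in pipes.
#' @export
validate_monthly_series <- function(x) {
  bad <- which(!is.finite(x$visits) | x$visits <= 0)
  if (length(bad) > 0) {
    abort(paste0("Row ", bad[1], " (", format(x$month[bad[1]], "%Y-%m"),
                 "): visit count must be a positive number, got `",
                 x$visits[bad[1]], "`."))
  }
  if (anyNA(x$month)) abort("Missing month stamp.")
  if (nrow(x) > 1) {
    expected <- seq(x$month[1], by = "month", length.out = nrow(x))
    dup <- which(duplicated(x$month))
    if (length(dup) > 0) {
      abort(paste0("Duplicate month ", format(x$month[dup[1]], "%Y-%m"),
                   " at row ", dup[1], "."))
    }
    gap <- which(x$month != expected)
    if (length(gap) > 0) {
      abort(paste0("Calendar gap before ", format(x$month[gap[1]], "%Y-%m"),
                   " (row ", gap[1], "): months must be consecutive."))
    }
  }
  class(x) <- unique(c("monthly_series", class(tibble::as_tibble(x))))
  x
}

#' Read a monthly series from CSV
#'
#' The expected dialect is a header row and two columns, `month` in
#' `YYYY-MM` and a numeric `visits` count; rows may be in any order.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_monthly_series
#' @return A `monthly_series` tibble.
#' @seealso [write_series()] for the inverse.
#' @export
read_series <- function(path, month_col = "month", visits_col = "visits") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  as_monthly_series(raw, month_col = month_col, visits_col = visits_col)
}

#' Write a monthly series to CSV
#'
#' Emits the same two-column dialect that [read_series()] reads
#' (`month` as `YYYY-MM`, numeric `visits`), so write-then-read is the
#' identity on valid series.
#'
#' @param series A `monthly_series`.
#' @param path Output file path.
#' @return `series`, invisibly.
#' @export
write_series <- function(series, path) {
  series <- ensure_series(series)
  out <- tibble::tibble(month = format(series$month, "%Y-%m"),
                        visits = series$visits)
  readr::write_csv(out, path)
  invisible(series)
}

#' Split a series chronologically into training and test sets
#'
#' The training set is the anterior `floor(train_fraction * length)` months
#' and the test set is the remainder, so concatenating the two pieces
#' reproduces the input and the test months can never influence fitting.
#'
#' @param series A `monthly_series` (length >= 5).
#' @param train_fraction Fraction of months assigned to training, in (0, 1).
#' @return A list with elements `train` and `test`, both `monthly_series`.
#' @examples
#' s <- monthly_series(seq(100, length.out = 60), start = c(2015, 1))
#' parts <- split_series(s, 0.8)
#' nrow(parts$train)  # 48
#' @export
split_series <- function(series, train_fraction = 0.8) {
  series <- ensure_series(series)
  n <- nrow(series)
  if (n < 5) abort("Series must have at least 5 months to split.")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  n_train <- floor(train_fraction * n)
  if (n_train < 1) abort("Training fraction yields an empty training set.")
  if (n_train >= n) abort("Training fraction yields an empty test set.")
  if (n_train < 4) {
    abort(paste0("Training set of ", n_train,
                 " months is too short; at least 4 are needed for an order search."))
  }
  list(
    train = validate_monthly_series(series[seq_len(n_train), ]),
    test  = validate_monthly_series(series[(n_train + 1):n, ])
  )
}

# Accept either a monthly_series or a bare numeric vector (treated as an
# undated series); always return a monthly_series tibble.
ensure_series <- function(x) {
  if (inherits(x, "monthly_series")) return(x)
  if (is.data.frame(x)) return(as_monthly_series(x))
  if (is.numeric(x)) return(monthly_series(x))
  abort("Expected a monthly_series, a data frame, or a numeric vector.")
}

series_values <- function(x) ensure_series(x)$visits
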