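#' Column-mapping dialect for delimited AWS files
#'
#' AWS exports differ in column naming; a dialect maps the columns the
#' pipeline consumes onto the names present in a particular file. Only the
#' four fields the algorithm uses are mapped; extra columns are ignored.
#'
#' @param animal_id name of the animal-identifier column.
#' @param timestamp name of the measurement date-time column (ISO-8601;
#'   date-only values are taken as midnight).
#' @param weight name of the body-weight column, in kg.
#' @param concurrent_forage name of the logical column flagging records taken
#'   while the forage-intake monitoring system was active, or `NULL` if the
#'   file has no such column (the flag then defaults to `FALSE`).
#' @param date name of the calendar-date column (reference files).
#' @return A named list of class `aws_dialect`.
#' @export
aws_dialect <- function(animal_id = "animal_id",
                        timestamp = "timestamp",
                        weight = "weight_kg",
                        concurrent_forage = "concurrent_forage",
                        date = "date") {
  structure(
    list(animal_id = animal_id, timestamp = timestamp, weight = weight,
         concurrent_forage = concurrent_forage, date = date),
    class = "aws_dialect"
  )
}

# Parse ISO-8601 date-times, accepting date-only strings as midnight UTC.
parse_timestamp <- function(x) {
  out <- suppressWarnings(readr::parse_datetime(x))
  date_only <- is.na(out) & !is.na(suppressWarnings(readr::parse_date(x)))
  if (any(date_only)) {
    out[date_only] <- as.POSIXct(
      suppressWarnings(readr::parse_date(x[date_only])), tz = "UTC"
    )
  }
  out
}

parse_logical_flag <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "n", "")] <- FALSE
  out[is.na(x)] <- FALSE
  as.logical(out)
}

read_delim_raw <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

require_columns <- function(raw, cols, path) {
  missing <- setdiff(unlist(cols), names(raw))
  if (length(missing) > 0) {
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read raw AWS weight records
#'
#' Each row of the file becomes one weight record or an entry in the
#' malformed-row report; rows are never silently dropped. The function fails
#' only when no row at all is valid.
#'
#' @param path path to a delimited text file (CSV, UTF-8, header row).
#' @param dialect an [aws_dialect()] mapping the required columns.
#' @return A tibble with columns `animal_id` (character), `timestamp`
#'   (POSIXct, UTC), `weight` (kg) and `concurrent_forage` (logical), in file
#'   order, with the malformed-row report attached as attribute `"malformed"`
#'   (a tibble of `row`, `reason`).
#' @export
read_weight_records <- function(path, dialect = aws_dialect()) {
  raw <- read_delim_raw(path)
  require_columns(raw, dialect[c("animal_id", "timestamp", "weight")], path)

  animal_id <- trimws(raw[[dialect$animal_id]])
  timestamp <- parse_timestamp(raw[[dialect$timestamp]])
  weight <- suppressWarnings(as.numeric(raw[[dialect$weight]]))
  if (!is.null(dialect$concurrent_forage) &&
      dialect$concurrent_forage %in% names(raw)) {
    concurrent_forage <- parse_logical_flag(raw[[dialect$concurrent_forage]])
  } else {
    warning("no concurrent-forage column found in ", path,
            "; flag defaults to FALSE (screening becomes a no-op)",
            call. = FALSE)
    concurrent_forage <- rep(FALSE, nrow(raw))
  }

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(weight) | weight <= 0] <- "weight not a positive number"
  reason[is.na(timestamp)] <- "unparseable timestamp"
  reason[is.na(animal_id) | animal_id == ""] <- "empty animal_id"
  reason[is.na(concurrent_forage)] <- "unparseable concurrent_forage flag"

  ok <- is.na(reason)
  malformed <- tibble::tibble(row = which(!ok), reason = reason[!ok])
  if (!any(ok)) {
    stop("zero valid rows in ", path, call. = FALSE)
  }

  out <- tibble::tibble(
    animal_id = animal_id[ok],
    timestamp = timestamp[ok],
    weight = weight[ok],
    concurrent_forage = concurrent_forage[ok]
  )
  attr(out, "malformed") <- malformed
  out
}

#' Read static-scale reference weights
#'
#' One row per animal per measurement campaign: the weight measured on the
#' window mid-date with a conventional static scale, serving as ground truth
#' for evaluation.
#'
#' @inheritParams read_weight_records
#' @return A tibble with columns `animal_id`, `date` (Date) and `weight`
#'   (kg), with a `"malformed"` attribute as in [read_weight_records()].
#'   Duplicate (animal, date) pairs are an error.
#' @export
read_reference_weights <- function(path, dialect = aws_dialect()) {
  raw <- read_delim_raw(path)
  require_columns(raw, dialect[c("animal_id", "date", "weight")], path)

  animal_id <- trimws(raw[[dialect$animal_id]])
  date <- suppressWarnings(readr::parse_date(raw[[dialect$date]]))
  weight <- suppressWarnings(as.numeric(raw[[dialect$weight]]))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(weight) | weight <= 0] <- "weight not a positive number"
  reason[is.na(date)] <- "unparseable date"
  reason[is.na(animal_id) | animal_id == ""] <- "empty animal_id"

  ok <- is.na(reason)
  malformed <- tibble::tibble(row = which(!ok), reason = reason[!ok])
  if (!any(ok)) {
    stop("zero valid rows in ", path, call. = FALSE)
  }
  out <- tibble::tibble(animal_id = animal_id[ok], date = date[ok],
                        weight = weight[ok])
  if (anyDuplicated(out[c("animal_id", "date")]) > 0) {
    dup <- out[duplicated(out[c("animal_id", "date")]), ]
    stop("duplicate reference for animal/date: ",
         paste(paste(dup$animal_id, dup$date), collapse = "; "),
         call. = FALSE)
  }
  attr(out, "malformed") <- malformed
  out
}

#' Read a target average-daily-gain (ADG) table
#'
#' The table lists target daily gain (kg/day) by body-weight class, as
#' published in national feeding standards; it parameterises the
#' post-processing threshold (see [adg_threshold()]). Users supply their own
#' breed- and sex-appropriate table.
#'
#' @param path CSV with columns `class_lower_kg` (strictly increasing lower
#'   bounds of the weight classes) and `adg_kg_per_day` (positive targets).
#' @return A tibble with columns `class_lower_kg`, `adg_kg_per_day`, sorted
#'   by class bound.
#' @export
read_adg_table <- function(path) {
  raw <- read_delim_raw(path)
  require_columns(raw, list("class_lower_kg", "adg_kg_per_day"), path)
  out <- tibble::tibble(
    class_lower_kg = as.numeric(raw$class_lower_kg),
    adg_kg_per_day = as.numeric(raw$adg_kg_per_day)
  )
  validate_adg_table(out)
}

validate_adg_table <- function(tab) {
  if (nrow(tab) == 0) stop("ADG table is empty", call. = FALSE)
  if (anyNA(tab$class_lower_kg) || anyNA(tab$adg_kg_per_day)) {
    stop("ADG table contains non-numeric entries", call. = FALSE)
  }
  tab <- tab[order(tab$class_lower_kg), ]
  if (any(diff(tab$class_lower_kg) <= 0)) {
    stop("ADG table class bounds must be strictly increasing", call. = FALSE)
  }
  if (any(tab$adg_kg_per_day <= 0)) {
    stop("ADG targets must be positive", call. = FALSE)
  }
  tab
}

#' Define the measurement windows of a study
#'
#' A measurement window is a short run of consecutive days (default 7) during
#' which the AWS records continuously; the reference static-scale weight is
#' taken on the window's mid-day (default the 4th day).
#'
#' @param label character vector of window names (e.g. month tags).
#' @param start_date first day of each window (`Date` or ISO string).
#' @param length_days window length in days (recycled), default 7.
#' @param mid_day_index 1-based day-of-window of the reference measurement
#'   (recycled), default 4.
#' @return A tibble with one row per window: `label`, `start_date`,
#'   `length_days`, `mid_day_index`, `mid_date`, `end_date`.
#' @export
measurement_windows <- function(label, start_date, length_days = 7L,
                                mid_day_index = 4L) {
  start_date <- as.Date(start_date)
  n <- length(label)
  length_days <- rep_len(as.integer(length_days), n)
  mid_day_index <- rep_len(as.integer(mid_day_index), n)
  if (any(length_days < 1)) stop("length_days must be >= 1", call. = FALSE)
  if (any(mid_day_index < 1 | mid_day_index > length_days)) {
    stop("mid_day_index must lie within the window", call. = FALSE)
  }
  if (anyDuplicated(label) > 0) stop("window labels must be unique", call. = FALSE)
  tibble::tibble(
    label = as.character(label),
    start_date = start_date,
    length_days = length_days,
    mid_day_index = mid_day_index,
    mid_date = start_date + mid_day_index - 1L,
    end_date = start_date + length_days - 1L
  )
}

#' Default study windows
#'
#' Three 7-day mid-month windows (February--April 2019), the cadence of a
#' monthly on-farm campaign: recording for one week each month with the
#' static-scale reference taken on the 4th day.
#'
#' @return A [measurement_windows()] tibble with three rows.
#' @export
default_windows <- function() {
  measurement_windows(
    label = c("Feb", "Mar", "Apr"),
    start_date = as.Date(c("2019-02-12", "2019-03-12", "2019-04-12"))
  )
}

#' Tag each record or daily weight with its window and day index
#'
#' @param x a tibble with a `timestamp` (POSIXct) or `date` (Date) column.
#' @param windows a [measurement_windows()] tibble.
#' @param drop_outside drop rows falling in no window (default `TRUE`; they
#'   are counted in a message when any are dropped).
#' @return `x` with added columns `date` (if absent), `window` and
#'   `day_index` (1-based day of window).
#' @export
assign_windows <- function(x, windows, drop_outside = TRUE) {
  if (!"date" %in% names(x)) {
    x$date <- as.Date(x$timestamp, tz = "UTC")
  }
  x$window <- NA_character_
  x$day_index <- NA_integer_
  for (i in seq_len(nrow(windows))) {
    in_w <- x$date >= windows$start_date[i] & x$date <= windows$end_date[i]
    x$window[in_w] <- windows$label[i]
    x$day_index[in_w] <- as.integer(x$date[in_w] - windows$start_date[i]) + 1L
  }
  if (drop_outside) {
    n_out <- sum(is.na(x$window))
    if (n_out > 0) {
      message(n_out, " row(s) outside all measurement windows dropped")
      x <- x[!is.na(x$window), ]
    }
  }
  x
}

#' Write a domain table to CSV
#'
#' Full-precision CSV writer used for every emitted table so that a write /
#' read round trip is value-identical. Dates and date-times are written in
#' ISO-8601.
#'
#' @param rows a data frame.
#' @param path output path; the directory must exist.
#' @export
write_table <- function(rows, path) {
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  }
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
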