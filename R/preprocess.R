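#' Screen out records concurrent with forage-intake monitoring
#'
#' Initial screening step: AWS weights captured while the forage-intake
#' monitoring system was active are unreliable (the animal is interacting
#' with a second device) and are excluded before any statistical filtering.
#'
#' @param records a weight-record tibble (see [read_weight_records()]).
#' @return The records with `concurrent_forage == FALSE`, order preserved.
#' @export
screen_concurrent <- function(records) {
  out <- records[!records$concurrent_forage, , drop = FALSE]
  if (nrow(out) == 0 && nrow(records) > 0) {
    warning("all records flagged as concurrent with forage intake; ",
            "nothing left after screening", call. = FALSE)
  }
  out
}

#' Tukey's fences outlier rule
#'
#' Classifies values against the interval `[Q1 - k*IQR, Q3 + k*IQR]` with
#' quartiles by linear interpolation of order statistics
#' (`stats::quantile(type = 7)`). Fences are inclusive: boundary values are
#' kept; removal requires strict exceedance.
#'
#' @param values numeric vector (kg), at least one value.
#' @param k fence multiplier, default 1.5.
#' @return A list with `kept`, `removed` (values), `keep` (logical mask in
#'   input order) and the `lower`/`upper` fences.
#' @export
tukey_fences <- function(values, k = 1.5) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  keep <- values >= lower & values <= upper
  list(kept = values[keep], removed = values[!keep], keep = keep,
       lower = lower, upper = upper)
}

#' Standard-deviation outlier rule
#'
#' Classifies values against `|v - mean| <= k * s`, with `s` the sample
#' (n-1) standard deviation. Inclusive bound; a singleton (s undefined) is
#' always kept.
#'
#' @inheritParams tukey_fences
#' @param k SD multiplier, default 1.5.
#' @return As [tukey_fences()], with `lower`/`upper` the band limits.
#' @export
sd_filter <- function(values, k = 1.5) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  m <- mean(values)
  s <- if (length(values) < 2) 0 else stats::sd(values)
  keep <- abs(values - m) <= k * s
  list(kept = values[keep], removed = values[!keep], keep = keep,
       lower = m - k * s, upper = m + k * s)
}

#' Detect outliers in screened weight records
#'
#' Applies one of the two statistical rules independently within each group
#' of records. Groups smaller than `min_group_size` pass through unfiltered
#' (quartiles and standard deviations are too unstable there) and are listed
#' in the summary.
#'
#' @param records screened records carrying a `window` column when
#'   `grouping = "animal_window"` (see [assign_windows()]).
#' @param rule `"tukey"` ([tukey_fences()]) or `"sd"` ([sd_filter()]).
#' @param grouping `"animal_window"` (default: per animal within each
#'   window) or `"animal_global"` (per animal over all its records).
#' @param k rule multiplier, default 1.5.
#' @param min_group_size groups with fewer records bypass filtering,
#'   default 4.
#' @return A list with tibbles `kept` and `removed` (partitioning the
#'   input; original row order preserved within each) and `summary` (one row
#'   per group: counts and whether the group was bypassed).
#' @export
detect_outliers <- function(records, rule = c("tukey", "sd"),
                            grouping = c("animal_window", "animal_global"),
                            k = 1.5, min_group_size = 4L) {
  rule <- match.arg(rule)
  grouping <- match.arg(grouping)
  fn <- switch(rule, tukey = tukey_fences, sd = sd_filter)

  if (grouping == "animal_window" && !"window" %in% names(records)) {
    stop("grouping = \"animal_window\" needs a 'window' column; ",
         "run assign_windows() first", call. = FALSE)
  }
  group_key <- if (grouping == "animal_window") {
    paste(records$animal_id, records$window, sep = "\r")
  } else {
    records$animal_id
  }

  keep <- rep(TRUE, nrow(records))
  idx_by_group <- split(seq_len(nrow(records)), group_key)
  summary <- vector("list", length(idx_by_group))
  for (g in seq_along(idx_by_group)) {
    idx <- idx_by_group[[g]]
    bypass <- length(idx) < min_group_size
    if (!bypass) {
      keep[idx] <- fn(records$weight[idx], k = k)$keep
    }
    key <- strsplit(names(idx_by_group)[g], "\r", fixed = TRUE)[[1]]
    summary[[g]] <- tibble::tibble(
      animal_id = key[1],
      window = if (grouping == "animal_window") key[2] else NA_character_,
      n_input = length(idx),
      n_removed = sum(!keep[idx]),
      bypassed = bypass
    )
  }
  summary <- dplyr::bind_rows(summary)
  n_bypassed <- sum(summary$bypassed)
  if (n_bypassed > 0) {
    message(n_bypassed, " group(s) below min_group_size passed through unfiltered")
  }
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       summary = summary)
}

#' Per-animal daily averages
#'
#' Collapses the (possibly many) surviving visits of each animal on each
#' calendar day into one arithmetic mean, preventing animals with frequent
#' feeder visits from dominating downstream statistics.
#'
#' @param records filtered weight records; `window`/`day_index` columns, if
#'   present, are carried through.
#' @return A tibble with one row per (animal, date): `animal_id`, `date`,
#'   `weight` (mean kg), `n_records`, plus `window` and `day_index` when
#'   available.
#' @export
daily_average <- function(records) {
  if (!"date" %in% names(records)) {
    records$date <- as.Date(records$timestamp, tz = "UTC")
  }
  extra <- intersect(c("window", "day_index"), names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("animal_id", "date", extra)))) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      weight = mean(.data$weight),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(c("animal_id", "date", extra, "weight", "n_records"))) |>
    dplyr::arrange(.data$animal_id, .data$date)
}
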