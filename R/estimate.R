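#' Representative weight of one animal-window by mean
#'
#' Arithmetic mean of the daily-average weights over the window (the
#' mid-date's daily value included when present).
#'
#' @param weights daily-average weights (kg) of one animal in one window.
#' @return A list with `weight` (kg, `NA` when the window is empty) and
#'   `n_days` (daily points used).
#' @export
estimate_mean <- function(weights) {
  if (length(weights) == 0) return(list(weight = NA_real_, n_days = 0L))
  list(weight = mean(weights), n_days = length(weights))
}

#' Representative weight of one animal-window by median
#'
#' Sample median of the daily-average weights; an even count yields the mean
#' of the two central values.
#'
#' @inheritParams estimate_mean
#' @return As [estimate_mean()].
#' @export
estimate_median <- function(weights) {
  if (length(weights) == 0) return(list(weight = NA_real_, n_days = 0L))
  list(weight = stats::median(weights), n_days = length(weights))
}

#' Mid-date weight by linear-regression prediction
#'
#' Ordinary least squares of daily weight on the 1-based day-of-window
#' index, fitted on every day of the window EXCEPT the mid-date, then
#' evaluated at the mid-date index. Requires at least `min_points` non-mid
#' daily points (default 4) with day-index variance; otherwise the estimate
#' is missing.
#'
#' @param weights daily-average weights (kg) of one animal in one window.
#' @param day_index 1-based day-of-window indices matching `weights`.
#' @param mid_day_index day index to predict at (the reference day),
#'   default 4.
#' @param min_points minimum fitting points, default 4.
#' @return As [estimate_mean()]; `n_days` counts the points used in the fit.
#' @export
estimate_linear <- function(weights, day_index, mid_day_index = 4L,
                            min_points = 4L) {
  stopifnot(length(weights) == length(day_index))
  use <- day_index != mid_day_index
  w <- weights[use]
  d <- day_index[use]
  if (length(w) < min_points || length(unique(d)) < 2) {
    return(list(weight = NA_real_, n_days = length(w)))
  }
  fit <- stats::lm(w ~ d, data = data.frame(w = w, d = d))
  pred <- unname(stats::predict(fit, newdata = data.frame(d = mid_day_index)))
  list(weight = pred, n_days = length(w))
}

#' Window estimates for every animal, window and method
#'
#' Produces the full grid of (animal x window x method) representative
#' weights from daily averages; combinations with no usable data appear
#' with a missing weight rather than being dropped.
#'
#' @param daily a [daily_average()] tibble carrying `window` and `day_index`
#'   columns ([assign_windows()]).
#' @param windows a [measurement_windows()] tibble.
#' @param methods subset of `c("mean", "median", "linear_regression")`.
#' @param min_regression_points minimum non-mid-date points for the
#'   regression method, default 4.
#' @return A tibble with one row per (animal, window, method): `animal_id`,
#'   `window`, `method`, `weight` (kg or `NA`), `n_days`.
#' @export
estimate_all <- function(daily, windows,
                         methods = c("mean", "median", "linear_regression"),
                         min_regression_points = 4L) {
  methods <- match.arg(methods, several.ok = TRUE)
  animals <- sort(unique(daily$animal_id))
  grid <- tidyr::expand_grid(
    animal_id = animals,
    window = windows$label,
    method = methods
  )
  mid_of <- stats::setNames(windows$mid_day_index, windows$label)

  groups <- split(daily, paste(daily$animal_id, daily$window, sep = "\r"))
  one <- function(animal_id, window, method) {
    g <- groups[[paste(animal_id, window, sep = "\r")]]
    if (is.null(g)) g <- daily[0, , drop = FALSE]
    switch(method,
      mean = estimate_mean(g$weight),
      median = estimate_median(g$weight),
      linear_regression = estimate_linear(
        g$weight, g$day_index,
        mid_day_index = mid_of[[window]],
        min_points = min_regression_points
      )
    )
  }
  res <- Map(one, grid$animal_id, grid$window, grid$method)
  grid$weight <- vapply(res, function(x) x$weight, numeric(1))
  grid$n_days <- vapply(res, function(x) as.integer(x$n_days), integer(1))
  grid
}
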