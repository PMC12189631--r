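#' Physiology-bounded threshold from an ADG table
#'
#' The post-processing band half-width: the maximum target average daily
#' gain in the table times a day factor (default 30, bounding plausible
#' monthly weight change and preventing over-filtering within shorter
#' windows).
#'
#' @param adg_table an ADG table ([read_adg_table()]): columns
#'   `class_lower_kg`, `adg_kg_per_day`.
#' @param factor_days day multiplier, default 30.
#' @return A list of class `threshold_spec`: `max_adg` (kg/day),
#'   `factor_days`, `threshold` (kg).
#' @export
adg_threshold <- function(adg_table, factor_days = 30) {
  adg_table <- validate_adg_table(adg_table)
  max_adg <- max(adg_table$adg_kg_per_day)
  structure(
    list(max_adg = max_adg, factor_days = factor_days,
         threshold = max_adg * factor_days),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("ADG threshold: +/- %.2f kg (max ADG %.2f kg/day x %g days)\n",
              x$threshold, x$max_adg, x$factor_days))
  invisible(x)
}

#' Apply the ADG threshold band to daily weights
#'
#' Keeps daily weights inside `[baseline - threshold, baseline + threshold]`
#' (inclusive: removal requires strict exceedance) and partitions the rest
#' out.
#'
#' @param daily daily-weight tibble of one animal in one window.
#' @param baseline anchor weight in kg (see [baseline_weight()]).
#' @param spec a [adg_threshold()] result.
#' @return A list of tibbles `kept` and `removed` partitioning `daily`.
#' @export
apply_threshold <- function(daily, baseline, spec) {
  stopifnot(is.numeric(baseline), baseline > 0)
  keep <- daily$weight >= baseline - spec$threshold &
    daily$weight <= baseline + spec$threshold
  list(kept = daily[keep, , drop = FALSE],
       removed = daily[!keep, , drop = FALSE])
}

#' Baseline weight anchoring the post-processing band
#'
#' Chooses the weight against which the ADG band is centred for one animal
#' and window:
#' \describe{
#'   \item{`window_median`}{median of the animal's daily weights in the
#'     current window (self-anchored, default).}
#'   \item{`previous_reference`}{the animal's most recent static-scale
#'     weight dated before the window start.}
#'   \item{`previous_estimate`}{the animal's accepted estimate from the
#'     preceding window.}
#' }
#' When history is absent the fallback order is previous_reference then
#' window_median.
#'
#' @param animal_id animal identifier.
#' @param window window label.
#' @param windows a [measurement_windows()] tibble.
#' @param daily the animal's daily weights in the current window.
#' @param references reference-weight tibble, or `NULL`.
#' @param prior_estimates tibble of accepted estimates from earlier windows
#'   (`animal_id`, `window`, `weight`), or `NULL`.
#' @param policy one of `"window_median"`, `"previous_reference"`,
#'   `"previous_estimate"`.
#' @return Baseline weight in kg.
#' @export
baseline_weight <- function(animal_id, window, windows, daily,
                            references = NULL, prior_estimates = NULL,
                            policy = c("window_median", "previous_reference",
                                       "previous_estimate")) {
  policy <- match.arg(policy)
  w <- windows[windows$label == window, ]
  if (nrow(w) != 1) stop("unknown window: ", window, call. = FALSE)

  from_median <- function() {
    if (nrow(daily) == 0) {
      stop("no data at all for animal ", animal_id, " in window ", window,
           call. = FALSE)
    }
    stats::median(daily$weight)
  }
  from_reference <- function() {
    if (is.null(references)) return(NA_real_)
    prev <- references[references$animal_id == animal_id &
                         references$date < w$start_date, ]
    if (nrow(prev) == 0) return(NA_real_)
    prev$weight[which.max(prev$date)]
  }
  from_estimate <- function() {
    if (is.null(prior_estimates)) return(NA_real_)
    earlier <- windows$label[windows$start_date < w$start_date]
    prev <- prior_estimates[prior_estimates$animal_id == animal_id &
                              prior_estimates$window %in% earlier &
                              !is.na(prior_estimates$weight), ]
    if (nrow(prev) == 0) return(NA_real_)
    last_label <- earlier[max(match(prev$window, earlier))]
    prev$weight[prev$window == last_label][1]
  }

  b <- switch(policy,
    window_median = from_median(),
    previous_reference = from_reference(),
    previous_estimate = from_estimate()
  )
  if (is.na(b)) b <- from_reference()
  if (is.na(b)) b <- from_median()
  b
}

#' Post-process daily weights with the ADG band
#'
#' Stage 3 of the pipeline: for every (animal, window) group, anchors the
#' ADG band at the group's baseline and removes daily weights outside it.
#' Downstream estimates should be recomputed on the kept set (the pipeline
#' does this; see [run_pipeline()]).
#'
#' @param daily a [daily_average()] tibble carrying `window` columns.
#' @param windows a [measurement_windows()] tibble.
#' @param spec a [adg_threshold()] result.
#' @param references reference weights for the `previous_reference` policy
#'   or fallback, or `NULL`.
#' @param prior_estimates estimates for the `previous_estimate` policy, or
#'   `NULL`.
#' @param policy baseline policy, see [baseline_weight()].
#' @return A list of tibbles `kept` and `removed` partitioning `daily`.
#' @export
postprocess_daily <- function(daily, windows, spec, references = NULL,
                              prior_estimates = NULL,
                              policy = "window_median") {
  groups <- split(seq_len(nrow(daily)),
                  paste(daily$animal_id, daily$window, sep = "\r"))
  keep <- rep(TRUE, nrow(daily))
  for (idx in groups) {
    g <- daily[idx, , drop = FALSE]
    b <- baseline_weight(g$animal_id[1], g$window[1], windows, g,
                         references = references,
                         prior_estimates = prior_estimates, policy = policy)
    keep[idx] <- apply_threshold_mask(g$weight, b, spec)
  }
  list(kept = daily[keep, , drop = FALSE],
       removed = daily[!keep, , drop = FALSE])
}

apply_threshold_mask <- function(weights, baseline, spec) {
  weights >= baseline - spec$threshold & weights <= baseline + spec$threshold
}
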