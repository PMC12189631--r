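#' Root mean square error of estimates against references
#'
#' @param estimate,reference paired numeric vectors (kg); missing estimates
#'   must be dropped (and counted) upstream.
#' @return RMSE in kg.
#' @export
rmse <- function(estimate, reference) {
  stopifnot(length(estimate) == length(reference))
  if (length(estimate) == 0) stop("empty pairs", call. = FALSE)
  sqrt(mean((estimate - reference)^2))
}

#' Percentage of animals within a relative error margin
#'
#' The margin-of-error ratio: the share of pairs whose relative error
#' `|estimate - reference| / reference` does not exceed `pct` percent
#' (inclusive boundary).
#'
#' @inheritParams rmse
#' @param pct margin in percent, typically 5 or 10.
#' @return Percentage in `[0, 100]`.
#' @export
margin_ratio <- function(estimate, reference, pct) {
  stopifnot(length(estimate) == length(reference))
  if (length(estimate) == 0) stop("empty pairs", call. = FALSE)
  if (any(reference <= 0)) stop("reference weights must be positive", call. = FALSE)
  100 * mean(abs(estimate - reference) / reference <= pct / 100)
}

as_group_list <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)), length(groups) >= 2)
  groups
}

#' Pairwise F-tests of variance homogeneity against a reference group
#'
#' Two-sided variance-ratio F-test of each group against the reference
#' group, the usual gate before parametric multiple comparisons.
#'
#' @param groups named list of numeric vectors (kg), each of length >= 2.
#' @param reference name of the reference group in `groups`.
#' @return A tibble with one row per non-reference group: `group`,
#'   `statistic` (variance ratio group/reference), `df1`, `df2`, `p_value`.
#' @export
variance_homogeneity <- function(groups, reference) {
  groups <- as_group_list(groups)
  if (!reference %in% names(groups)) {
    stop("reference group absent: ", reference, call. = FALSE)
  }
  if (any(lengths(groups) < 2)) {
    stop("every group needs n >= 2 for a variance ratio", call. = FALSE)
  }
  ref <- groups[[reference]]
  others <- setdiff(names(groups), reference)
  rows <- lapply(others, function(g) {
    ft <- stats::var.test(groups[[g]], ref)
    tibble::tibble(group = g,
                   statistic = unname(ft$statistic),
                   df1 = unname(ft$parameter[1]),
                   df2 = unname(ft$parameter[2]),
                   p_value = ft$p.value)
  })
  dplyr::bind_rows(rows)
}

groups_to_long <- function(groups, reference = NULL) {
  lv <- names(groups)
  if (!is.null(reference)) lv <- c(reference, setdiff(lv, reference))
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = lv)
  )
}

#' Dunnett many-to-one comparisons against a reference group
#'
#' Compares each method group against the reference static-scale group with
#' Dunnett's multiplicity adjustment (two-sided), via a one-way fit.
#'
#' @inheritParams variance_homogeneity
#' @return A tibble with one row per non-reference group: `group`,
#'   `estimate` (difference vs reference, kg), `p_adj`.
#' @export
dunnett_vs_reference <- function(groups, reference) {
  groups <- as_group_list(groups)
  if (!reference %in% names(groups)) {
    stop("reference group absent: ", reference, call. = FALSE)
  }
  dat <- groups_to_long(groups, reference)
  if (stats::var(dat$value) == 0) {
    # all observations identical: no differences to test
    others <- setdiff(names(groups), reference)
    return(tibble::tibble(group = others, estimate = 0, p_adj = 1))
  }
  fit <- stats::aov(value ~ group, data = dat)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(glht)
  tibble::tibble(
    group = sub(paste0(" - ", reference, "$"), "", names(sm$test$coefficients)),
    estimate = unname(sm$test$coefficients),
    p_adj = unname(sm$test$pvalues)
  )
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons with the studentized-range (honestly significant
#' difference) adjustment.
#'
#' @param groups named list of numeric vectors (kg).
#' @return A tibble with one row per pair: `pair`, `estimate` (difference,
#'   kg), `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  groups <- as_group_list(groups)
  dat <- groups_to_long(groups)
  if (stats::var(dat$value) == 0) {
    pairs <- utils::combn(names(groups), 2, paste, collapse = "-")
    return(tibble::tibble(pair = pairs, estimate = 0, p_adj = 1))
  }
  th <- stats::TukeyHSD(stats::aov(value ~ group, data = dat))$group
  tibble::tibble(pair = rownames(th),
                 estimate = unname(th[, "diff"]),
                 p_adj = unname(th[, "p adj"]))
}

#' Kruskal--Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Rank-based omnibus H test (tie-corrected) followed by Dunn's pairwise
#' z-tests on mean ranks with a multiplicity adjustment. When every
#' observation across all groups is identical, H is defined as 0 with
#' p = 1 (no rank information).
#'
#' @param groups named list of numeric vectors.
#' @param p_adjust adjustment for Dunn's pairwise p-values: `"holm"`
#'   (default), `"bonferroni"` or `"none"`.
#' @return A list with `h` (H statistic), `df`, `p_value`, and `dunn`, a
#'   tibble of `pair`, `z`, `p_value` (raw), `p_adj`.
#' @export
kruskal_dunn <- function(groups, p_adjust = c("holm", "bonferroni", "none")) {
  groups <- as_group_list(groups)
  p_adjust <- match.arg(p_adjust)
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))

  if (stats::var(values) == 0) {
    pairs <- utils::combn(names(groups), 2, paste, collapse = "-")
    return(list(h = 0, df = length(groups) - 1L, p_value = 1,
                dunn = tibble::tibble(pair = pairs, z = 0, p_value = 1,
                                      p_adj = 1)))
  }

  kw <- stats::kruskal.test(values, factor(labels))

  # Dunn: z-tests on mean ranks with tie correction
  n_total <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  cmb <- utils::combn(names(groups), 2)
  z <- apply(cmb, 2, function(pr) {
    se <- sqrt((n_total * (n_total + 1) / 12 - tie_term) *
                 (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  list(
    h = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value,
    dunn = tibble::tibble(
      pair = apply(cmb, 2, paste, collapse = "-"),
      z = z,
      p_value = p_raw,
      p_adj = stats::p.adjust(p_raw, method = p_adjust)
    )
  )
}

#' Full statistical battery comparing method groups to the reference
#'
#' Runs the variance-homogeneity F-tests, Dunnett's many-to-one test,
#' Tukey HSD and the Kruskal--Wallis + Dunn battery on the same groups, and
#' additionally the non-parametric battery on per-animal paired differences
#' (estimate minus reference) to absorb the between-animal weight spread.
#'
#' @param estimates tibble of `animal_id`, `group` (method label),
#'   `weight`, and optionally `window`; one reference row set is supplied
#'   via `reference_values`.
#' @param reference_values tibble of `animal_id`, `weight` (plus `window`
#'   when references are per-window) for the static-scale reference group;
#'   one row per animal (and window).
#' @param alpha significance level recorded in the result, default 0.05.
#' @param p_adjust Dunn adjustment, see [kruskal_dunn()].
#' @return A list: `f_test`, `dunnett`, `tukey`, `kruskal` (on absolute
#'   weights incl. the reference group), `kruskal_paired` (on per-animal
#'   differences across method groups), `alpha`.
#' @export
test_battery <- function(estimates, reference_values, alpha = 0.05,
                         p_adjust = "holm") {
  stopifnot(all(c("animal_id", "group", "weight") %in% names(estimates)))
  est <- estimates[!is.na(estimates$weight), ]
  groups <- split(est$weight, est$group)
  groups <- groups[lengths(groups) >= 2]
  groups[["reference"]] <- reference_values$weight
  if (length(groups) < 2) stop("need at least one method group with n >= 2",
                               call. = FALSE)

  keys <- intersect(c("animal_id", "window"),
                    intersect(names(est), names(reference_values)))
  diffs <- dplyr::inner_join(est, reference_values, by = keys,
                             suffix = c("", "_ref"),
                             relationship = "many-to-one")
  diff_groups <- split(diffs$weight - diffs$weight_ref, diffs$group)
  diff_groups <- diff_groups[lengths(diff_groups) >= 2]

  list(
    f_test = variance_homogeneity(groups, "reference"),
    dunnett = dunnett_vs_reference(groups, "reference"),
    tukey = tukey_hsd(groups),
    kruskal = kruskal_dunn(groups, p_adjust = p_adjust),
    kruskal_paired = if (length(diff_groups) >= 2) {
      kruskal_dunn(diff_groups, p_adjust = p_adjust)
    } else NULL,
    alpha = alpha
  )
}

#' Accuracy report per combination and window
#'
#' Joins window estimates to static-scale references at the window mid-dates
#' and scores every (rule x method x post-processing) combination per window
#' and pooled ("Total"): paired n, predicted and reference means with SDs,
#' RMSE, mean absolute difference, and the 5%/10% margin ratios. Pairs with
#' a missing estimate are excluded from the metrics and counted in
#' `n_missing`.
#'
#' @param estimates tibble with columns `animal_id`, `window`, `method`,
#'   `weight`, plus identification columns `rule` and `post` (logical).
#' @param references reference-weight tibble (`animal_id`, `date`,
#'   `weight`).
#' @param windows a [measurement_windows()] tibble.
#' @return A tibble with one row per (rule, method, post, window-or-Total).
#' @export
build_report <- function(estimates, references, windows) {
  refs <- dplyr::inner_join(references,
                            windows[, c("label", "mid_date")],
                            by = c(date = "mid_date")) |>
    dplyr::rename(window = "label", reference = "weight")
  joined <- dplyr::left_join(estimates, refs[, c("animal_id", "window", "reference")],
                             by = c("animal_id", "window"))
  joined <- joined[!is.na(joined$reference), , drop = FALSE]
  if (nrow(joined) == 0) stop("no joinable estimate/reference pairs", call. = FALSE)

  score <- function(d) {
    ok <- !is.na(d$weight)
    tibble::tibble(
      n = sum(ok),
      n_missing = sum(!ok),
      predicted_mean = if (any(ok)) mean(d$weight[ok]) else NA_real_,
      predicted_sd = if (sum(ok) > 1) stats::sd(d$weight[ok]) else NA_real_,
      reference_mean = if (any(ok)) mean(d$reference[ok]) else NA_real_,
      reference_sd = if (sum(ok) > 1) stats::sd(d$reference[ok]) else NA_real_,
      rmse = if (any(ok)) rmse(d$weight[ok], d$reference[ok]) else NA_real_,
      mean_abs_diff = if (any(ok)) mean(abs(d$weight[ok] - d$reference[ok])) else NA_real_,
      pct_within_5 = if (any(ok)) margin_ratio(d$weight[ok], d$reference[ok], 5) else NA_real_,
      pct_within_10 = if (any(ok)) margin_ratio(d$weight[ok], d$reference[ok], 10) else NA_real_
    )
  }

  per_window <- joined |>
    dplyr::group_by(.data$rule, .data$method, .data$post, .data$window) |>
    dplyr::group_modify(~ score(.x)) |>
    dplyr::ungroup()
  pooled <- joined |>
    dplyr::group_by(.data$rule, .data$method, .data$post) |>
    dplyr::group_modify(~ score(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(window = "Total", .after = "post")
  dplyr::bind_rows(per_window, pooled) |>
    dplyr::arrange(.data$rule, .data$method, .data$post)
}
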