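#' Run the full three-stage weight-estimation pipeline
#'
#' Orchestrates screen -> outlier filter -> daily average -> estimate ->
#' ADG post-process -> re-estimate -> evaluate for every requested
#' (filter rule x estimator) combination, always producing both the
#' with- and without-post-processing estimates so the before/after contrast
#' is a first-class output.
#'
#' @param records raw AWS weight records ([read_weight_records()] layout).
#' @param references static-scale reference weights.
#' @param adg_table ADG table ([read_adg_table()] layout); required unless
#'   `postprocess = FALSE`.
#' @param windows a [measurement_windows()] tibble, default
#'   [default_windows()].
#' @param rules filter rules to run, subset of `c("tukey", "sd")`.
#' @param methods estimators to run, subset of
#'   `c("mean", "median", "linear_regression")`.
#' @param k outlier-rule multiplier, default 1.5.
#' @param grouping outlier grouping scope, see [detect_outliers()].
#' @param min_group_size see [detect_outliers()], default 4.
#' @param min_regression_points see [estimate_all()], default 4.
#' @param postprocess run stage 3 (default `TRUE`); stage-2 estimates are
#'   reported either way.
#' @param factor_days ADG threshold day factor, default 30.
#' @param baseline_policy see [baseline_weight()], default
#'   `"window_median"`.
#' @param alpha significance level for the test battery, default 0.05.
#' @param output_dir if non-`NULL`, per-stage audit CSVs, the report and
#'   the battery JSON are written there.
#' @return A list of class `aws_run`: `report` ([build_report()] tibble),
#'   `estimates` (all window estimates with `rule` and `post` columns),
#'   `battery` (per rule: [test_battery()] result on pooled post-processed
#'   estimates), `audit` (per-stage record counts per rule) and `removed`
#'   (per-stage removed-record tables).
#' @export
run_pipeline <- function(records, references, adg_table = NULL,
                         windows = default_windows(),
                         rules = c("tukey", "sd"),
                         methods = c("mean", "median", "linear_regression"),
                         k = 1.5,
                         grouping = "animal_window",
                         min_group_size = 4L,
                         min_regression_points = 4L,
                         postprocess = TRUE,
                         factor_days = 30,
                         baseline_policy = "window_median",
                         alpha = 0.05,
                         output_dir = NULL) {
  rules <- match.arg(rules, c("tukey", "sd"), several.ok = TRUE)
  if (postprocess && is.null(adg_table)) {
    stop("post-processing is enabled but no ADG table was supplied; ",
         "pass adg_table or set postprocess = FALSE", call. = FALSE)
  }
  spec <- if (postprocess) adg_threshold(adg_table, factor_days = factor_days)

  screened <- screen_concurrent(records)
  screened <- assign_windows(screened, windows)

  all_estimates <- list()
  audit <- list()
  removed <- list()
  battery <- list()

  refs_windowed <- dplyr::inner_join(
    references, windows[, c("label", "mid_date")], by = c(date = "mid_date")
  ) |> dplyr::rename(window = "label")

  for (rule in rules) {
    filt <- detect_outliers(screened, rule = rule, grouping = grouping,
                            k = k, min_group_size = min_group_size)
    daily <- daily_average(filt$kept)
    est_pre <- estimate_all(daily, windows, methods = methods,
                            min_regression_points = min_regression_points)
    est_pre$rule <- rule
    est_pre$post <- FALSE
    all_estimates[[paste0(rule, "_pre")]] <- est_pre

    daily_post_removed <- daily[0, , drop = FALSE]
    if (postprocess) {
      pp <- postprocess_daily(daily, windows, spec, references = references,
                              policy = baseline_policy)
      est_post <- estimate_all(pp$kept, windows, methods = methods,
                               min_regression_points = min_regression_points)
      est_post$rule <- rule
      est_post$post <- TRUE
      all_estimates[[paste0(rule, "_post")]] <- est_post
      daily_post_removed <- pp$removed

      batt_est <- est_post |>
        dplyr::rename(group = "method") |>
        dplyr::inner_join(refs_windowed[, c("animal_id", "window")],
                          by = c("animal_id", "window"))
      battery[[rule]] <- test_battery(
        batt_est[, c("animal_id", "window", "group", "weight")],
        refs_windowed[, c("animal_id", "window", "weight")],
        alpha = alpha
      )
    }

    audit[[rule]] <- tibble::tibble(
      rule = rule,
      n_raw = nrow(records),
      n_screened = nrow(screened),
      n_outliers_removed = nrow(filt$removed),
      n_after_filter = nrow(filt$kept),
      n_daily = nrow(daily),
      n_daily_removed_post = nrow(daily_post_removed),
      n_daily_after_post = nrow(daily) - nrow(daily_post_removed)
    )
    removed[[rule]] <- list(outliers = filt$removed,
                            post = daily_post_removed)
  }

  estimates <- dplyr::bind_rows(all_estimates)
  report <- build_report(estimates, references, windows)
  out <- structure(
    list(report = report, estimates = estimates, battery = battery,
         audit = dplyr::bind_rows(audit), removed = removed),
    class = "aws_run"
  )
  if (!is.null(output_dir)) write_run(out, output_dir)
  out
}

#' @export
print.aws_run <- function(x, ...) {
  cat("AWS weight pipeline run\n")
  pooled <- x$report[x$report$window == "Total", ]
  cat(sprintf("  %d combination(s), pooled RMSE %.2f-%.2f kg\n",
              nrow(pooled), min(pooled$rmse, na.rm = TRUE),
              max(pooled$rmse, na.rm = TRUE)))
  print(x$audit)
  invisible(x)
}

write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(run$report, file.path(output_dir, "report.csv"))
  write_table(run$estimates, file.path(output_dir, "estimates.csv"))
  write_table(run$audit, file.path(output_dir, "audit.csv"))
  for (rule in names(run$removed)) {
    write_table(run$removed[[rule]]$outliers,
                file.path(output_dir, paste0("removed_outliers_", rule, ".csv")))
    write_table(run$removed[[rule]]$post,
                file.path(output_dir, paste0("removed_post_", rule, ".csv")))
  }
  if (length(run$battery) > 0) {
    jsonlite::write_json(
      lapply(run$battery, battery_to_list),
      file.path(output_dir, "battery.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(output_dir)
}

battery_to_list <- function(b) {
  list(
    alpha = b$alpha,
    f_test = b$f_test,
    dunnett = b$dunnett,
    tukey = b$tukey,
    kruskal = list(h = b$kruskal$h, df = b$kruskal$df,
                   p_value = b$kruskal$p_value, dunn = b$kruskal$dunn),
    kruskal_paired = if (is.null(b$kruskal_paired)) NULL else {
      list(h = b$kruskal_paired$h, df = b$kruskal_paired$df,
           p_value = b$kruskal_paired$p_value, dunn = b$kruskal_paired$dunn)
    }
  )
}

#' Rank pipeline configurations by pooled accuracy
#'
#' Ranks (rule x method x post) combinations by pooled RMSE ascending,
#' breaking ties by the 5% margin ratio descending.
#'
#' @param report a [build_report()] tibble, or several row-bound together
#'   (they must share window labels).
#' @return The pooled ("Total") rows ordered best-first with a `rank`
#'   column.
#' @export
compare_configurations <- function(report) {
  pooled <- report[report$window == "Total", , drop = FALSE]
  if (nrow(pooled) == 0) stop("report contains no pooled rows", call. = FALSE)
  pooled <- pooled[order(pooled$rmse, -pooled$pct_within_5), , drop = FALSE]
  pooled$rank <- seq_len(nrow(pooled))
  pooled
}
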