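test_that("RMSE and margin ratios follow their definitions", {
  expect_equal(rmse(c(310, 320), c(300, 330)), 10)
  expect_equal(rmse(c(300, 350), c(300, 350)), 0)
  expect_equal(rmse(305, 300), 5)
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  # exactly 5% relative error counts as inside (inclusive boundary)
  expect_equal(margin_ratio(315, 300, 5), 100)
  expect_equal(margin_ratio(331, 300, 10), 0)  # 10.33% -> outside
  expect_equal(margin_ratio(c(300, 301, 299, 400), rep(300, 4), 5), 75)
  expect_error(margin_ratio(300, -1, 5), "positive")
})

test_that("margin ratios are nested and RMSE dominates the mean absolute error", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(3:40, 1)
    ref <- runif(n, 300, 400)
    est <- ref + rnorm(n, 0, runif(1, 1, 60))
    expect_lte(margin_ratio(est, ref, 5), margin_ratio(est, ref, 10))
    expect_gte(rmse(est, ref), mean(abs(est - ref)))
  }
})

test_that("variance-ratio F-test matches its closed form", {
  set.seed(12)
  a <- rnorm(25, 350, 10)
  g <- list(m = a, reference = a)
  ft <- variance_homogeneity(g, "reference")
  expect_equal(ft$statistic, 1)
  expect_equal(ft$p_value, 1)

  # doubling the scale quadruples the variance ratio
  b <- 2 * (a - mean(a)) + mean(a)
  ft2 <- variance_homogeneity(list(m = b, reference = a), "reference")
  expect_equal(ft2$statistic, 4, tolerance = 1e-12)
  p_closed <- 2 * min(pf(4, 24, 24), 1 - pf(4, 24, 24))
  expect_equal(ft2$p_value, p_closed, tolerance = 1e-9)

  expect_error(variance_homogeneity(list(m = 1, reference = a), "reference"),
               "n >= 2")
  expect_error(variance_homogeneity(list(m = a, n = a), "reference"), "absent")
})

test_that("Dunnett comparisons flag a large shift and spare identical groups", {
  set.seed(42)
  base <- rnorm(30, 350, 5)
  g <- list(mean = base + rnorm(30, 0, 5),
            shifted = base + 50 + rnorm(30, 0, 5),
            reference = base + rnorm(30, 0, 5))
  d <- dunnett_vs_reference(g, "reference")
  expect_lt(d$p_adj[d$group == "shifted"], 0.05)
  expect_gt(d$p_adj[d$group == "mean"], 0.05)
  expect_true(all(d$p_adj >= 0 & d$p_adj <= 1))

  const <- list(a = rep(350, 10), b = rep(350, 10), reference = rep(350, 10))
  dc <- dunnett_vs_reference(const, "reference")
  expect_true(all(dc$p_adj == 1))
  expect_error(dunnett_vs_reference(g, "nope"), "absent")
})

test_that("Tukey HSD flags exactly the shifted group's pairs on a strong effect", {
  set.seed(43)
  g <- list(a = rnorm(30, 350, 5), b = rnorm(30, 350, 5),
            c = rnorm(30, 400, 5))
  th <- tukey_hsd(g)
  sig <- th$pair[th$p_adj < 0.05]
  expect_setequal(sig, c("c-a", "c-b"))

  const <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  expect_true(all(tukey_hsd(const)$p_adj == 1))
})

test_that("two-group Tukey HSD agrees with the pooled-variance t-test", {
  set.seed(44)
  g <- list(a = rnorm(20, 350, 8), b = rnorm(25, 354, 8))
  th <- tukey_hsd(g)
  tt <- t.test(g$b, g$a, var.equal = TRUE)
  # with k = 2 the studentized-range adjustment reduces to the t-test
  expect_equal(th$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(th$estimate, unname(tt$estimate[1] - tt$estimate[2]),
               tolerance = 1e-9)
})

test_that("Kruskal-Wallis H matches the hand rank computation", {
  kw <- kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 21
  expect_equal(kw$h, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-12)
  expect_equal(round(kw$h, 3), 3.857)

  same <- kruskal_dunn(list(a = rep(5, 4), b = rep(5, 4)))
  expect_equal(same$h, 0)
  expect_equal(same$p_value, 1)
})

test_that("tie correction never lowers H and Dunn p-values are sane", {
  set.seed(45)
  for (i in 1:20) {
    vals <- sample(1:5, 30, replace = TRUE)  # heavy ties
    g <- split(vals, rep(1:3, each = 10))
    names(g) <- c("a", "b", "c")
    kw <- kruskal_dunn(g)
    # uncorrected H from the same ranks
    r <- rank(vals)
    n <- lengths(g)
    h_raw <- 12 / (30 * 31) *
      sum(tapply(r, rep(1:3, each = 10), sum)^2 / n) - 3 * 31
    expect_gte(kw$h + 1e-12, h_raw)
    expect_true(all(kw$dunn$p_adj >= kw$dunn$p_value - 1e-12))
    expect_true(all(kw$dunn$p_adj >= 0 & kw$dunn$p_adj <= 1))
  }
})

test_that("Dunn z-tests separate a clearly shifted group", {
  set.seed(46)
  g <- list(a = rnorm(30, 350, 5), b = rnorm(30, 350, 5),
            c = rnorm(30, 420, 5))
  kw <- kruskal_dunn(g)
  expect_lt(kw$p_value, 0.001)
  sig <- kw$dunn$pair[kw$dunn$p_adj < 0.05]
  expect_true(all(grepl("c", sig)))
  expect_length(sig, 2)
})

test_that("the battery reports unbiased estimators as indistinguishable from reference", {
  set.seed(47)
  animals <- sprintf("A%02d", 1:36)
  truth <- rnorm(36, 350, 20)
  est <- tibble::tibble(
    animal_id = rep(animals, 3),
    group = rep(c("mean", "median", "linear_regression"), each = 36),
    weight = rep(truth, 3) + rnorm(108, 0, 2)
  )
  refs <- tibble::tibble(animal_id = animals, weight = truth)
  b <- test_battery(est, refs)
  expect_true(all(b$dunnett$p_adj > 0.05))
  expect_true(all(b$tukey$p_adj > 0.05))
  expect_gt(b$kruskal$p_value, 0.05)
  expect_false(is.null(b$kruskal_paired))
})

test_that("build_report scores every combination per window plus pooled totals", {
  w <- default_windows()
  refs <- tibble::tibble(
    animal_id = rep(c("A001", "A002"), 3),
    date = rep(w$mid_date, each = 2),
    weight = c(326, 330, 348, 352, 375, 379)
  )
  est <- tidyr::expand_grid(
    animal_id = c("A001", "A002"), window = w$label,
    method = c("mean", "median"), rule = "tukey", post = FALSE
  )
  est <- dplyr::left_join(
    est, dplyr::rename(refs, window_ref = "weight") |>
      dplyr::mutate(window = rep(w$label, each = 2)) |>
      dplyr::select("animal_id", "window", "window_ref"),
    by = c("animal_id", "window")
  )
  est$weight <- est$window_ref + 5
  est$n_days <- 7L
  rep_ <- build_report(est[, c("animal_id", "window", "method", "weight",
                               "rule", "post")], refs, w)
  expect_equal(nrow(rep_), 2 * (3 + 1))  # 2 methods x (3 windows + Total)
  expect_true(all(abs(rep_$rmse - 5) < 1e-9))
  expect_true(all(rep_$n == 2 | rep_$window == "Total"))
  tot <- rep_[rep_$window == "Total", ]
  expect_equal(tot$n, c(6, 6))
  expect_equal(tot$pct_within_5, c(100, 100))

  # all-missing method stays present with n = 0
  est2 <- est
  est2$weight[est2$method == "median"] <- NA_real_
  rep2 <- build_report(est2[, c("animal_id", "window", "method", "weight",
                                "rule", "post")], refs, w)
  med_tot <- rep2[rep2$method == "median" & rep2$window == "Total", ]
  expect_equal(med_tot$n, 0)
  expect_equal(med_tot$n_missing, 6)
  expect_true(is.na(med_tot$rmse))
})
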