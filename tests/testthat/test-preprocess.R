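test_that("concurrent-forage screening keeps exactly the unflagged records", {
  rec <- tibble::tibble(
    animal_id = rep("A", 10),
    timestamp = as.POSIXct("2019-02-12", tz = "UTC") + 1:10,
    weight = 300 + 1:10,
    concurrent_forage = rep(c(TRUE, FALSE, FALSE, TRUE, TRUE), 2)
  )
  out <- screen_concurrent(rec)
  expect_equal(nrow(out), sum(!rec$concurrent_forage))
  expect_true(all(!out$concurrent_forage))
  expect_equal(out$weight, rec$weight[!rec$concurrent_forage])

  expect_warning(screen_concurrent(rec[rec$concurrent_forage, ]),
                 "all records flagged")
  expect_identical(screen_concurrent(rec[!rec$concurrent_forage, ]),
                   rec[!rec$concurrent_forage, ])
})

test_that("Tukey fences classify the worked examples", {
  r <- tukey_fences(c(1, 2, 3, 4, 100))
  expect_equal(r$kept, c(1, 2, 3, 4))
  expect_equal(r$removed, 100)

  # zero IQR: fences collapse onto the value, inclusive -> all kept
  r <- tukey_fences(c(5, 5, 5, 5))
  expect_equal(r$kept, c(5, 5, 5, 5))
  expect_length(r$removed, 0)

  r <- tukey_fences(7)
  expect_equal(r$kept, 7)

  expect_error(tukey_fences(numeric(0)), "empty")
})

test_that("SD filter classifies the worked examples", {
  # mean 2, s = sqrt(20) ~ 4.472, bound 6.708; |10 - 2| = 8 > bound
  r <- sd_filter(c(0, 0, 0, 0, 10))
  expect_equal(r$kept, c(0, 0, 0, 0))
  expect_equal(r$removed, 10)

  r <- sd_filter(c(10, 10, 10))
  expect_length(r$removed, 0)

  # for n = 2 the bound 1.5*|a-b|/sqrt(2) always exceeds |a-b|/2
  for (pair in list(c(1, 2), c(300, 450), c(-5, 5))) {
    expect_length(sd_filter(pair)$removed, 0)
  }

  expect_error(sd_filter(numeric(0)), "empty")
})

test_that("both rules agree with the brute-force oracle on random vectors", {
  set.seed(202)
  for (i in 1:200) {
    x <- random_weight_vector()
    expect_identical(tukey_fences(x)$keep, oracle_tukey(x))
    expect_identical(sd_filter(x)$keep, oracle_sd(x))
  }
})

test_that("boundary values sit inside inclusive fences", {
  # sorted (0,4,8,12,24): Q1 = 4, Q3 = 12 by linear interpolation, so the
  # upper fence is 12 + 1.5*8 = 24 -- the maximum lies exactly on it
  x <- c(0, 4, 8, 12, 24)
  expect_true(all(tukey_fences(x)$keep))
  expect_false(tukey_fences(c(0, 4, 8, 12, 24.001))$keep[5])

  # (0, 0, 0, c): |max - mean| = 3c/4 = 1.5 * (c/2) = 1.5 * s exactly
  expect_true(all(sd_filter(c(0, 0, 0, 8))$keep))
  expect_equal(sd_filter(c(0, 0, 0, 8))$upper, 8)
})

test_that("grouped detection applies the rule per group and bypasses small groups", {
  w <- default_windows()
  mk <- function(id, weights, day0 = as.Date("2019-02-12")) {
    tibble::tibble(
      animal_id = id,
      timestamp = as.POSIXct(day0, tz = "UTC") + seq_along(weights) * 3600,
      weight = weights, concurrent_forage = FALSE
    )
  }
  rec <- rbind(mk("A", c(300, 301, 302, 303, 500)),
               mk("B", c(350, 351, 352, 353, 120)))
  rec <- assign_windows(rec, w)
  res <- detect_outliers(rec, rule = "tukey")
  expect_equal(nrow(res$removed), 2)
  expect_setequal(res$removed$weight, c(500, 120))
  # partition property
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(rec))
  expect_equal(sort(c(res$kept$weight, res$removed$weight)), sort(rec$weight))

  # group of 3 records bypasses filtering
  small <- assign_windows(mk("C", c(300, 301, 9000)), w)
  expect_message(res2 <- detect_outliers(small, rule = "tukey"),
                 "min_group_size")
  expect_equal(nrow(res2$removed), 0)
  expect_true(res2$summary$bypassed)

  expect_error(detect_outliers(rec, rule = "mad"))
})

test_that("animal_global grouping pools a animal's records across windows", {
  w <- default_windows()
  rec <- tibble::tibble(
    animal_id = "A",
    timestamp = as.POSIXct(c(rep("2019-02-12", 3), rep("2019-03-12", 3)),
                           tz = "UTC") + 1:6,
    weight = c(300, 301, 302, 303, 304, 800),
    concurrent_forage = FALSE
  )
  rec <- assign_windows(rec, w)
  res_g <- detect_outliers(rec, rule = "tukey", grouping = "animal_global")
  expect_equal(res_g$removed$weight, 800)
  expect_true(is.na(res_g$summary$window[1]))
  # per-window grouping bypasses both 3-record groups instead
  res_w <- suppressMessages(detect_outliers(rec, rule = "tukey"))
  expect_equal(nrow(res_w$removed), 0)
})

test_that("contamination monotonicity: a farther value never lowers removals", {
  set.seed(99)
  for (i in 1:50) {
    x <- random_weight_vector(sample(4:30, 1))
    base_removed <- sum(!tukey_fences(x)$keep)
    far <- max(abs(x - median(x))) + runif(1, 1, 500)
    x2 <- c(x, median(x) + sample(c(-1, 1), 1) * far)
    expect_gte(sum(!tukey_fences(x2)$keep), base_removed)
  }
})

test_that("daily averaging buckets by calendar day and counts records", {
  rec <- tibble::tibble(
    animal_id = c("A", "A", "B", "A", "A"),
    timestamp = as.POSIXct(c("2019-02-12 08:00", "2019-02-12 18:00",
                             "2019-02-12 09:00", "2019-02-12 23:59",
                             "2019-02-13 00:01"), tz = "UTC"),
    weight = c(300, 310, 400, 305, 330),
    concurrent_forage = FALSE
  )
  d <- daily_average(rec)
  expect_equal(nrow(d), 3)  # distinct (animal, date) pairs
  a12 <- d[d$animal_id == "A" & d$date == as.Date("2019-02-12"), ]
  expect_equal(a12$weight, mean(c(300, 310, 305)))
  expect_equal(a12$n_records, 3L)
  # day boundary at midnight splits records
  expect_equal(d[d$animal_id == "A" & d$date == as.Date("2019-02-13"), ]$weight,
               330)
})

test_that("daily_average emits one row per distinct (animal, date) pair", {
  set.seed(5)
  rec <- tibble::tibble(
    animal_id = sample(LETTERS[1:4], 200, replace = TRUE),
    timestamp = as.POSIXct("2019-02-12", tz = "UTC") +
      runif(200, 0, 6 * 86400),
    weight = runif(200, 300, 400),
    concurrent_forage = FALSE
  )
  d <- daily_average(rec)
  expect_equal(nrow(d),
               nrow(unique(data.frame(rec$animal_id,
                                      as.Date(rec$timestamp, tz = "UTC")))))
})
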