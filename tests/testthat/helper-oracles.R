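# Independent brute-force classifiers: sort, interpolate order statistics,
# enumerate the fences, classify every value by direct comparison. Kept
# deliberately naive and separate from the package implementation.

oracle_quartile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_tukey <- function(x, k = 1.5) {
  q1 <- oracle_quartile(x, 0.25)
  q3 <- oracle_quartile(x, 0.75)
  lo <- q1 - k * (q3 - q1)
  hi <- q3 + k * (q3 - q1)
  vapply(x, function(v) v >= lo && v <= hi, logical(1))
}

oracle_sd <- function(x, k = 1.5) {
  m <- sum(x) / length(x)
  s <- if (length(x) < 2) 0 else sqrt(sum((x - m)^2) / (length(x) - 1))
  vapply(x, function(v) abs(v - m) <= k * s, logical(1))
}

random_weight_vector <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:50, 1)
  round(runif(n, 100, 600), 3)
}

# Small-herd simulator settings used where full scale is unnecessary
small_config <- function(...) {
  sim_config(n_animals = 6L, ...)
}

synthetic_adg_table <- function() {
  read_adg_table(system.file("extdata", "adg_table_synthetic.csv",
                             package = "awsproc"))
}

# Hand-built daily-weight tibble for one animal across one window
make_daily <- function(weights, day_index = seq_along(weights),
                       animal_id = "A001", window = "Feb",
                       start = as.Date("2019-02-12")) {
  tibble::tibble(
    animal_id = animal_id,
    date = start + day_index - 1L,
    window = window,
    day_index = as.integer(day_index),
    weight = weights,
    n_records = 1L
  )
}
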