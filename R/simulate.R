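#' Configuration of the synthetic herd / AWS simulator
#'
#' The simulator emulates a monthly on-farm campaign: a herd of growing
#' steers visiting a feeder-station scale several times a day during short
#' measurement windows, with Gaussian measurement noise and sparse
#' large-magnitude contamination (positive offsets from residual feed or
#' manure on the platform; large negative readings from partial stance).
#'
#' @param n_animals herd size, default 36.
#' @param windows a [measurement_windows()] tibble, default
#'   [default_windows()].
#' @param initial_weight_mean,initial_weight_sd herd weight distribution at
#'   the first window's first day (kg), defaults 330 / 20.
#' @param adg_mean,adg_sd per-animal average daily gain distribution
#'   (kg/day), defaults 0.8 / 0.15.
#' @param visits_per_day_mean Poisson mean of scale visits per animal per
#'   window day, default 4.
#' @param visit_process `"poisson"` (default) draws per-day visit counts
#'   from Poisson(`visits_per_day_mean`); `"fixed"` gives every animal
#'   exactly `visits_per_day_mean` visits per day (a complete, balanced
#'   schedule for controlled degenerate-limit experiments).
#' @param noise_sd Gaussian measurement noise SD (kg), default 5.
#' @param contamination_rate per-record contamination probability, default
#'   0.05.
#' @param positive_offset_range uniform range (kg) of positive offsets,
#'   default `c(20, 80)`.
#' @param negative_offset_range uniform range (kg) of negative offsets,
#'   default `c(60, 200)`.
#' @param reference_noise_sd static-scale noise SD (kg), default 0.
#' @param seed RNG seed, default 1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 36L,
                       windows = default_windows(),
                       initial_weight_mean = 330,
                       initial_weight_sd = 20,
                       adg_mean = 0.8,
                       adg_sd = 0.15,
                       visits_per_day_mean = 4,
                       visit_process = c("poisson", "fixed"),
                       noise_sd = 5,
                       contamination_rate = 0.05,
                       positive_offset_range = c(20, 80),
                       negative_offset_range = c(60, 200),
                       reference_noise_sd = 0,
                       seed = 1L) {
  stopifnot(
    n_animals >= 1,
    contamination_rate >= 0, contamination_rate <= 1,
    initial_weight_sd >= 0, adg_sd >= 0, noise_sd >= 0,
    reference_noise_sd >= 0, visits_per_day_mean >= 0,
    length(positive_offset_range) == 2, length(negative_offset_range) == 2,
    diff(positive_offset_range) >= 0, diff(negative_offset_range) >= 0
  )
  visit_process <- match.arg(visit_process)
  structure(
    list(n_animals = as.integer(n_animals), windows = windows,
         initial_weight_mean = initial_weight_mean,
         initial_weight_sd = initial_weight_sd,
         adg_mean = adg_mean, adg_sd = adg_sd,
         visits_per_day_mean = visits_per_day_mean,
         visit_process = visit_process, noise_sd = noise_sd,
         contamination_rate = contamination_rate,
         positive_offset_range = positive_offset_range,
         negative_offset_range = negative_offset_range,
         reference_noise_sd = reference_noise_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate per-animal growth trajectories (ground truth)
#'
#' Each animal grows linearly: `weight(t) = initial + adg * days_elapsed`,
#' with the animal's initial weight and ADG drawn once from the herd
#' distributions. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list of class `ground_truth`: `animals` (tibble `animal_id`,
#'   `initial_weight`, `adg`), `mid_weights` (tibble `animal_id`, `window`,
#'   `date`, `true_weight` at each window mid-date), `origin` (Date of day
#'   zero) and `config`.
#' @export
simulate_trajectories <- function(config, seed = config$seed) {
  set.seed(seed)
  ids <- sprintf("A%03d", seq_len(config$n_animals))
  animals <- tibble::tibble(
    animal_id = ids,
    initial_weight = stats::rnorm(config$n_animals,
                                  config$initial_weight_mean,
                                  config$initial_weight_sd),
    adg = stats::rnorm(config$n_animals, config$adg_mean, config$adg_sd)
  )
  origin <- min(config$windows$start_date)
  mid <- tidyr::expand_grid(animal_id = ids, window = config$windows$label) |>
    dplyr::left_join(config$windows[, c("label", "mid_date")],
                     by = c(window = "label")) |>
    dplyr::left_join(animals, by = "animal_id") |>
    dplyr::mutate(
      date = .data$mid_date,
      true_weight = .data$initial_weight +
        .data$adg * as.numeric(.data$date - origin)
    ) |>
    dplyr::select("animal_id", "window", "date", "true_weight")
  structure(list(animals = animals, mid_weights = mid, origin = origin,
                 config = config),
            class = "ground_truth")
}

true_weight_at <- function(truth, animal_id, date) {
  a <- truth$animals[match(animal_id, truth$animals$animal_id), ]
  a$initial_weight + a$adg * as.numeric(date - truth$origin)
}

#' Simulate AWS visit records and static-scale references
#'
#' Per animal and window day, a Poisson number of scale visits is drawn;
#' each visit records the day's true weight plus Gaussian measurement
#' noise, at a uniformly drawn time of day. One static-scale reference per
#' animal is emitted at every window mid-date (true weight plus
#' `reference_noise_sd` noise).
#'
#' @param truth a [simulate_trajectories()] result.
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return A list with `records` (weight-record tibble, uncontaminated) and
#'   `references` (reference-weight tibble).
#' @export
simulate_visits <- function(truth, config = truth$config,
                            seed = config$seed + 1L) {
  set.seed(seed)
  days <- config$windows |>
    dplyr::rowwise() |>
    dplyr::reframe(window = .data$label,
                   date = .data$start_date + seq_len(.data$length_days) - 1L)
  grid <- tidyr::expand_grid(animal_id = truth$animals$animal_id,
                             date = days$date)
  n_visits <- if (identical(config$visit_process, "fixed")) {
    rep(as.integer(round(config$visits_per_day_mean)), nrow(grid))
  } else {
    stats::rpois(nrow(grid), config$visits_per_day_mean)
  }
  rec <- grid[rep(seq_len(nrow(grid)), n_visits), ]
  if (nrow(rec) > 0) {
    secs <- round(stats::runif(nrow(rec), 0, 86399))
    rec$timestamp <- as.POSIXct(rec$date, tz = "UTC") + secs
    rec$weight <- true_weight_at(truth, rec$animal_id, rec$date) +
      stats::rnorm(nrow(rec), 0, config$noise_sd)
    rec$concurrent_forage <- FALSE
    rec <- rec[order(rec$animal_id, rec$timestamp),
               c("animal_id", "timestamp", "weight", "concurrent_forage")]
  } else {
    rec <- tibble::tibble(animal_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          weight = numeric(), concurrent_forage = logical())
  }

  refs <- truth$mid_weights
  refs$weight <- refs$true_weight +
    stats::rnorm(nrow(refs), 0, config$reference_noise_sd)
  refs <- tibble::as_tibble(refs[, c("animal_id", "date", "weight")])

  list(records = tibble::as_tibble(rec), references = refs)
}

#' Inject sparse large-magnitude contamination into AWS records
#'
#' Each record is independently contaminated with probability
#' `contamination_rate`; a contaminated record receives, with equal
#' probability, a positive offset uniform on `positive_offset_range`
#' (residual feed / manure on the platform) or a negative offset uniform on
#' `negative_offset_range` (partial stance on the load cell). The
#' `contaminated` flag is returned for scoring detector recall and is not
#' part of the record schema the pipeline consumes.
#'
#' @param records a weight-record tibble.
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed + 2`.
#' @return `records` with perturbed `weight` and an added logical
#'   `contaminated` column.
#' @export
contaminate <- function(records, config, seed = config$seed + 2L) {
  set.seed(seed)
  n <- nrow(records)
  hit <- stats::runif(n) < config$contamination_rate
  sign_pos <- stats::runif(n) < 0.5
  offset <- ifelse(sign_pos,
                   stats::runif(n, config$positive_offset_range[1],
                                config$positive_offset_range[2]),
                   -stats::runif(n, config$negative_offset_range[1],
                                 config$negative_offset_range[2]))
  records$weight <- records$weight + ifelse(hit, offset, 0)
  records$contaminated <- hit
  records
}

#' Simulate a complete synthetic AWS campaign
#'
#' Convenience wrapper chaining [simulate_trajectories()],
#' [simulate_visits()] and [contaminate()].
#'
#' @param config a [sim_config()].
#' @return A list with `records` (contaminated AWS stream incl. the
#'   `contaminated` scoring flag), `references`, and `truth` (ground
#'   truth).
#' @export
simulate_aws <- function(config = sim_config()) {
  truth <- simulate_trajectories(config)
  vis <- simulate_visits(truth, config)
  records <- contaminate(vis$records, config)
  list(records = records, references = vis$references, truth = truth)
}
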