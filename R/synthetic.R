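#' Calibrate a sleep-bout-count distribution to a target mean and SD
#'
#' Sleep bout counts are supported on 1, 2, ... and are over-dispersed in
#' real cohorts (e.g. SD 4.2 on mean 4.9 at night in controls), so the
#' family used is a shifted negative binomial: `X = 1 + NB(size, mu)` with
#' `mu = count_mean - 1` and `size = mu^2 / (count_sd^2 - mu)` (exact moment
#' match). When the target SD is too small for that family
#' (`count_sd^2 <= mu`) the calibration falls back to a shifted Poisson with
#' a warning, and a near-zero SD degenerates to a point mass at
#' `round(count_mean)`.
#'
#' @param count_mean Target mean bout count (>= 1).
#' @param count_sd Target bout-count SD (>= 0).
#' @return A list describing the calibrated family (`family` one of
#'   `"shifted_nbinom"`, `"shifted_poisson"`, `"point"`, plus its
#'   parameters), for use with [draw_bout_counts()].
#' @export
calibrate_count_distribution <- function(count_mean, count_sd) {
  if (count_mean < 1) abort("count_mean must be >= 1 (support starts at one bout)")
  if (count_sd < 0) abort("count_sd must be >= 0")
  mu <- count_mean - 1
  if (count_sd < 1e-8 || mu <= 0) {
    return(list(family = "point", at = round(count_mean),
                mean = count_mean, sd = count_sd))
  }
  if (count_sd^2 <= mu) {
    warn("target SD too small for a shifted negative binomial; using shifted Poisson")
    return(list(family = "shifted_poisson", lambda = mu,
                mean = count_mean, sd = count_sd))
  }
  list(family = "shifted_nbinom", mu = mu, size = mu^2 / (count_sd^2 - mu),
       mean = count_mean, sd = count_sd)
}

#' Draw bout counts from a calibrated distribution
#'
#' Draws are truncated to `[1, 120]`; 120 is the largest count for which a
#' 12-hour period can hold that many 5-minute bouts separated by single
#' awake minutes.
#'
#' @param n Number of draws.
#' @param calib A calibration from [calibrate_count_distribution()].
#' @return Integer vector of length `n`.
#' @export
draw_bout_counts <- function(n, calib) {
  x <- switch(calib$family,
    point = rep(calib$at, n),
    shifted_poisson = 1L + rpois(n, calib$lambda),
    shifted_nbinom = 1L + rnbinom(n, size = calib$size, mu = calib$mu),
    abort("unknown count family")
  )
  as.integer(pmin(pmax(x, 1L), 120L))
}

#' Specify a simulated genotype/period cohort
#'
#' Bundles the generator parameters for one genotype-period condition. In
#' regulated mode each animal-period draws a bout count x from the
#' calibrated count distribution and a total sleep T from a normal
#' distribution truncated to the feasible range `[5x, 720 - (x - 1)]`; mean
#' bout length is then exactly `T/x`, so all scatter about the power-law
#' curve comes from variation in total sleep. In unregulated mode mean bout
#' length is drawn log-normally, independent of x (median
#' `mean_total_sleep / count_mean`, log-SD 1), emulating a line whose bout
#' structure no longer defends a total-sleep set point.
#'
#' @param genotype,period Labels (period `"day"` or `"night"`).
#' @param mean_total_sleep,sd_total_sleep Total-sleep distribution, minutes
#'   (mean in (0, 720]).
#' @param count_mean,count_sd Bout-count distribution targets.
#' @param n_animals,n_periods Cohort dimensions (pairs = animals x periods).
#' @param regulation `"regulated"` or `"unregulated"`.
#' @param activity_rate Expected beam-break counts per awake minute (used
#'   when realizing traces).
#' @param seed Default RNG seed for this cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(genotype, period, mean_total_sleep, sd_total_sleep,
                        count_mean, count_sd, n_animals = 31L, n_periods = 4L,
                        regulation = c("regulated", "unregulated"),
                        activity_rate = 2, seed = 20160104L) {
  regulation <- match.arg(regulation)
  if (mean_total_sleep <= 0 || mean_total_sleep > PERIOD_MIN) {
    abort("mean_total_sleep must be in (0, 720] minutes")
  }
  if (sd_total_sleep < 0) abort("sd_total_sleep must be >= 0")
  structure(list(
    genotype = genotype, period = period,
    mean_total_sleep = mean_total_sleep, sd_total_sleep = sd_total_sleep,
    count_mean = count_mean, count_sd = count_sd,
    n_animals = as.integer(n_animals), n_periods = as.integer(n_periods),
    regulation = regulation, activity_rate = activity_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# inverse-CDF truncated normal draw; deterministic given the RNG stream
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate animal-period summaries for a cohort
#'
#' Draws `n_animals * n_periods` animal-period pairs from a [cohort_spec()].
#' Totals are rounded to whole minutes (traces are minute-resolution) and
#' every emitted row satisfies the structural identity
#' `total_sleep == bout_count * mean_bout_length` exactly, as scored data
#' does. Deterministic given the seed.
#'
#' @param spec A `cohort_spec`.
#' @param seed Override of the spec's seed.
#' @return Summary tibble: `animal_id`, `genotype`, `day_index`, `period`,
#'   `total_sleep`, `bout_count`, `mean_bout_length`.
#' @examples
#' s <- make_cohort(cohort_preset("control_night"))
#' nrow(s)  # 31 animals x 4 nights = 124 pairs
#' @export
make_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr_seed(seed %||% spec$seed)
  n <- spec$n_animals * spec$n_periods
  calib <- calibrate_count_distribution(spec$count_mean, spec$count_sd)
  x <- draw_bout_counts(n, calib)
  lower <- 5 * x
  upper <- PERIOD_MIN - (x - 1)
  if (spec$regulation == "regulated") {
    T <- rtruncnorm1(n, spec$mean_total_sleep, spec$sd_total_sleep, lower, upper)
  } else {
    y <- rlnorm(n, meanlog = log(spec$mean_total_sleep / spec$count_mean),
                sdlog = 1)
    T <- pmin(pmax(x * y, lower), upper)
  }
  T <- pmin(pmax(round(T), lower), upper)
  tibble::tibble(
    animal_id = sprintf("%s_a%02d", spec$genotype,
                        rep(seq_len(spec$n_animals), each = spec$n_periods)),
    genotype = spec$genotype,
    day_index = rep(seq_len(spec$n_periods), times = spec$n_animals),
    period = spec$period,
    total_sleep = as.numeric(T),
    bout_count = x,
    mean_bout_length = T / x
  )
}

#' Realize a minute-level activity trace from an animal-period summary
#'
#' Places `bout_count` zero-count runs, each at least 5 minutes, summing to
#' `total_sleep`, separated by at least one active minute, uniformly at
#' random among all feasible arrangements within the 12-hour period (uniform
#' compositions for both bout lengths and awake gaps). Awake minutes receive
#' counts from a zero-truncated Poisson with mean driven by `activity_rate`,
#' so re-scoring the trace with [score_sleep()] reproduces the summary
#' exactly.
#'
#' @param summary_row One-row summary tibble (`animal_id`, `day_index`,
#'   `period`, `total_sleep`, `bout_count`); must be feasible:
#'   `total_sleep + bout_count - 1 <= 720` and `total_sleep >= 5 * bout_count`.
#' @param activity_rate Poisson rate for awake-minute counts (> 0).
#' @param period_minutes Window length in minutes (default 720; smaller
#'   windows are allowed for testing).
#' @param seed Optional RNG seed; by default the ambient RNG stream is used.
#' @return Trace tibble for the one period, zeitgeber minutes `0..719` for a
#'   day or `720..1439` for a night.
#' @export
realize_trace <- function(summary_row, activity_rate = 2,
                          period_minutes = PERIOD_MIN, seed = NULL) {
  if (!is.null(seed)) withr_seed(seed)
  S <- as.integer(round(summary_row$total_sleep))
  k <- as.integer(summary_row$bout_count)
  if (k > 0 && (S < 5L * k || S + (k - 1L) > period_minutes)) {
    abort(sprintf("infeasible summary: %d bouts totalling %d min cannot fit a %d-min period",
                  k, S, period_minutes))
  }
  if (k == 0L && S != 0L) abort("infeasible summary: sleep minutes but no bout")

  lens <- if (k > 0L) 5L + runif_composition(S - 5L * k, k) else integer()
  awake <- period_minutes - S
  inner <- max(k - 1L, 0L)
  gaps <- if (k > 0L) {
    g <- runif_composition(awake - inner, k + 1L)
    if (k > 1L) g[2:k] <- g[2:k] + 1L  # >= 1 active minute between bouts
    g
  } else awake

  counts <- integer(0)
  for (i in seq_len(k)) {
    counts <- c(counts, rztpois(gaps[i], activity_rate), integer(lens[i]))
  }
  counts <- c(counts, rztpois(gaps[length(gaps)], activity_rate))
  stopifnot(length(counts) == period_minutes)

  offset <- if (summary_row$period == "day") 0L else PERIOD_MIN
  tibble::tibble(
    animal_id = summary_row$animal_id,
    day_index = as.integer(summary_row$day_index),
    zt_minute = offset + seq_len(period_minutes) - 1L,
    lights_on = summary_row$period == "day",
    count = counts
  )
}

# uniform composition of `total` into `parts` non-negative integers
runif_composition <- function(total, parts) {
  if (parts == 1L) return(as.integer(total))
  if (total == 0L) return(integer(parts))
  dividers <- sort(sample.int(total + parts - 1L, parts - 1L))
  as.integer(diff(c(0L, dividers, total + parts)) - 1L)
}

# zero-truncated Poisson via inverse CDF
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer())
  p0 <- ppois(0, lambda)
  as.integer(qpois(p0 + runif(n) * (1 - p0), lambda))
}

#' Simulate minute-level traces for a whole cohort
#'
#' Generates summaries with [make_cohort()] and realizes each as a trace.
#' The complementary period of each day (the day half for a night cohort,
#' and vice versa) is filled with sleepless wakeful activity so every animal
#' has a contiguous full-day trace, writable with [write_dam_file()] (in
#' batches of 32) and re-scorable with [score_sleep()].
#'
#' @inheritParams make_cohort
#' @param n_animals Optional override of the spec's animal count.
#' @return Trace tibble covering all animals, minutes 0-1439 of each day.
#' @export
simulate_trace_cohort <- function(spec, seed = NULL, n_animals = NULL) {
  if (!is.null(n_animals)) spec$n_animals <- as.integer(n_animals)
  sm <- make_cohort(spec, seed = seed)
  other <- if (spec$period == "day") "night" else "day"
  purrr::map_dfr(seq_len(nrow(sm)), function(i) {
    main <- realize_trace(sm[i, ], activity_rate = spec$activity_rate)
    awake <- tibble::tibble(
      animal_id = sm$animal_id[i],
      day_index = sm$day_index[i],
      zt_minute = (if (other == "day") 0L else PERIOD_MIN) +
        seq_len(PERIOD_MIN) - 1L,
      lights_on = other == "day",
      count = rztpois(PERIOD_MIN, spec$activity_rate)
    )
    dplyr::arrange(dplyr::bind_rows(main, awake), .data$zt_minute)
  })
}

#' Simulate a sleep-deprivation / rebound scenario
#'
#' Emulates a deprivation experiment: days 1-4 and nights 1-3 follow the
#' baseline day/night cohorts; on night 4 total sleep collapses to a
#' truncated-normal draw near zero (deprivation is modelled only through
#' its outcome, not the mechanical stimulus); day 5 is a regulated rebound
#' day with elevated mean and its own (tighter, relative to mean) SD.
#' Night-4 bout counts are capped at `floor(total/5)` so every row stays
#' realizable; totals under 5 minutes yield zero bouts.
#'
#' @param baseline_day,baseline_night `cohort_spec`s for the pre-deprivation
#'   days and nights.
#' @param deprivation_mean,deprivation_sd Night-4 total-sleep distribution
#'   (minutes; mean near zero).
#' @param rebound_mean,rebound_sd Day-5 total-sleep distribution (minutes;
#'   mean above the baseline day mean).
#' @param n_animals Number of animals followed through the scenario.
#' @param seed RNG seed.
#' @return Summary tibble over days 1-5 and nights 1-4, with a `phase`
#'   column (`"baseline"`, `"deprivation"`, `"rebound"`).
#' @export
make_rebound_scenario <- function(baseline_day, baseline_night,
                                  deprivation_mean, deprivation_sd,
                                  rebound_mean, rebound_sd,
                                  n_animals = 7L, seed = 20160104L) {
  if (deprivation_mean >= 30) abort("deprivation mean should be near zero (< 30 min)")
  if (rebound_mean <= baseline_day$mean_total_sleep) {
    abort("rebound mean must exceed the baseline day mean")
  }
  withr_seed(seed)
  n_animals <- as.integer(n_animals)

  day_spec <- baseline_day; day_spec$n_animals <- n_animals; day_spec$n_periods <- 4L
  night_spec <- baseline_night; night_spec$n_animals <- n_animals; night_spec$n_periods <- 3L
  days <- make_cohort(day_spec, seed = sample.int(2^31 - 1, 1))
  nights <- make_cohort(night_spec, seed = sample.int(2^31 - 1, 1))

  calib <- calibrate_count_distribution(baseline_night$count_mean,
                                        baseline_night$count_sd)
  T4 <- round(rtruncnorm1(n_animals, deprivation_mean, deprivation_sd,
                          0, PERIOD_MIN))
  x4 <- pmin(draw_bout_counts(n_animals, calib), pmax(T4 %/% 5L, 0L))
  x4[T4 < 5] <- 0L
  T4[x4 == 0L] <- 0
  night4 <- tibble::tibble(
    animal_id = sprintf("%s_a%02d", baseline_night$genotype, seq_len(n_animals)),
    genotype = baseline_night$genotype, day_index = 4L, period = "night",
    total_sleep = as.numeric(T4), bout_count = as.integer(x4),
    mean_bout_length = ifelse(x4 > 0, T4 / x4, NA_real_)
  )

  reb_spec <- baseline_day
  reb_spec$mean_total_sleep <- rebound_mean
  reb_spec$sd_total_sleep <- rebound_sd
  reb_spec$n_animals <- n_animals; reb_spec$n_periods <- 1L
  day5 <- make_cohort(reb_spec, seed = sample.int(2^31 - 1, 1)) |>
    dplyr::mutate(day_index = 5L)

  fix_id <- function(d) dplyr::mutate(
    d, animal_id = sprintf("%s_a%02d", .data$genotype,
                           as.integer(sub(".*_a", "", .data$animal_id))))
  dplyr::bind_rows(
    dplyr::mutate(fix_id(days), phase = "baseline"),
    dplyr::mutate(fix_id(nights), phase = "baseline"),
    dplyr::mutate(night4, phase = "deprivation"),
    dplyr::mutate(fix_id(day5), phase = "rebound")
  ) |>
    dplyr::arrange(.data$animal_id, .data$day_index, dplyr::desc(.data$period))
}

# local seed helper: set the RNG deterministically without touching
# the caller's stream
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% (2^31 - 1))
}
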