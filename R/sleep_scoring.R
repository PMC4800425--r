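#' Score sleep and activity bouts from an activity trace
#'
#' Applies the standard five-minute inactivity rule: a sleep bout is a
#' maximal run of consecutive zero-count minutes lasting at least
#' `min_sleep_minutes`; an activity bout is a maximal run of minutes with
#' count > 0 (no minimum length). Inactive runs shorter than the threshold
#' are quiet wake and belong to neither kind.
#'
#' A run that crosses a day/night boundary (zeitgeber minute 0 or 720) is
#' split at the boundary and each segment is assigned to its own period,
#' keeping the parent run's sleep/activity state; the five-minute threshold
#' is applied to the whole run before splitting, since the animal was asleep
#' throughout. Split segments carry `truncated = TRUE`. This convention
#' preserves additivity of total sleep across periods.
#'
#' @param trace Trace tibble as returned by [read_dam_file()] or
#'   [simulate_trace_cohort()]; each animal's minutes must be contiguous.
#' @param min_sleep_minutes Minimum inactive run length counted as sleep
#'   (default 5).
#' @return A bout tibble: `animal_id`, `day_index`, `period` ("day"/"night"),
#'   `kind` ("sleep"/"activity"), `start_zt_minute`, `length`, `truncated`.
#' @export
score_sleep <- function(trace, min_sleep_minutes = 5L) {
  check_trace(trace)
  if (nrow(trace) == 0L) abort("empty trace")
  if (min_sleep_minutes < 1L) abort("min_sleep_minutes must be >= 1")
  trace |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(~ score_one(.x, min_sleep_minutes)) |>
    dplyr::ungroup()
}

score_one <- function(tr, min_sleep) {
  tr <- dplyr::arrange(tr, .data$day_index, .data$zt_minute)
  abs_min <- (tr$day_index - 1L) * DAY_MIN + tr$zt_minute
  if (nrow(tr) > 1L && any(diff(abs_min) != 1L)) {
    abort("trace minutes are not contiguous")
  }
  r <- rle(tr$count == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- purrr::pmap_dfr(
    list(starts, ends, r$values),
    function(s, e, inactive) {
      len <- e - s + 1L
      if (inactive && len < min_sleep) return(NULL)
      kind <- if (inactive) "sleep" else "activity"
      # split at every period boundary (multiple of 720 abs minutes) inside the run
      seg_start <- s
      cuts <- s + which(abs_min[s:e] %% PERIOD_MIN == 0L) - 1L
      cuts <- cuts[cuts > s]
      bounds <- c(cuts, e + 1L)
      purrr::map_dfr(bounds, function(b) {
        seg <- tibble::tibble(
          day_index = tr$day_index[seg_start],
          period = if (tr$zt_minute[seg_start] < PERIOD_MIN) "day" else "night",
          kind = kind,
          start_zt_minute = tr$zt_minute[seg_start],
          length = b - seg_start,
          truncated = (b - seg_start) < len
        )
        seg_start <<- b
        seg
      })
    }
  )
  if (nrow(out) == 0L) {
    out <- tibble::tibble(day_index = integer(), period = character(),
                          kind = character(), start_zt_minute = integer(),
                          length = integer(), truncated = logical())
  }
  out
}

#' Summarize one animal-period from its bouts
#'
#' Collapses the sleep bouts of one animal in one day or night into the
#' animal-period record used as a regression point: total sleep, sleep bout
#' count, and mean bout length (total / count; `NA` when the animal slept no
#' bouts). The identity `total_sleep == bout_count * mean_bout_length` holds
#' exactly whenever `bout_count > 0`.
#'
#' @param bouts Bout tibble from [score_sleep()].
#' @param animal_id,day_index,period The animal-period to summarize; all
#'   bouts passed in must belong to this animal.
#' @return One-row tibble: `animal_id`, `day_index`, `period`, `total_sleep`,
#'   `bout_count`, `mean_bout_length`.
#' @export
summarize_period <- function(bouts, animal_id, day_index, period) {
  if (nrow(bouts) > 0L && any(bouts$animal_id != animal_id)) {
    abort("bouts from more than one animal passed to summarize_period()")
  }
  sl <- dplyr::filter(bouts, .data$kind == "sleep",
                      .data$day_index == !!day_index, .data$period == !!period)
  total <- sum(sl$length)
  n <- nrow(sl)
  tibble::tibble(
    animal_id = animal_id, day_index = as.integer(day_index), period = period,
    total_sleep = as.numeric(total), bout_count = n,
    mean_bout_length = if (n > 0L) total / n else NA_real_
  )
}

#' Score a trace cohort into animal-period summaries
#'
#' Convenience wrapper: scores sleep with [score_sleep()] and emits one
#' summary row per animal and complete 12-hour period covered by the trace
#' (periods with fewer than 720 recorded minutes are dropped). Periods in
#' which an animal slept nothing appear with `total_sleep = 0`,
#' `bout_count = 0` and `mean_bout_length = NA`.
#'
#' @inheritParams score_sleep
#' @param genotype Optional genotype label attached to every row.
#' @return Summary tibble: `animal_id`, (`genotype`,) `day_index`, `period`,
#'   `total_sleep`, `bout_count`, `mean_bout_length`.
#' @export
sleep_summary <- function(trace, min_sleep_minutes = 5L, genotype = NULL) {
  bouts <- score_sleep(trace, min_sleep_minutes)
  complete <- trace |>
    dplyr::mutate(period = ifelse(.data$lights_on, "day", "night")) |>
    dplyr::count(.data$animal_id, .data$day_index, .data$period) |>
    dplyr::filter(.data$n == PERIOD_MIN) |>
    dplyr::select(-"n")
  sums <- bouts |>
    dplyr::filter(.data$kind == "sleep") |>
    dplyr::group_by(.data$animal_id, .data$day_index, .data$period) |>
    dplyr::summarise(total_sleep = sum(.data$length),
                     bout_count = dplyr::n(), .groups = "drop")
  out <- complete |>
    dplyr::left_join(sums, by = c("animal_id", "day_index", "period")) |>
    dplyr::mutate(
      total_sleep = as.numeric(tidyr::replace_na(.data$total_sleep, 0)),
      bout_count = as.integer(tidyr::replace_na(.data$bout_count, 0L)),
      mean_bout_length = ifelse(.data$bout_count > 0,
                                .data$total_sleep / .data$bout_count, NA_real_)
    ) |>
    dplyr::arrange(.data$animal_id, .data$day_index, .data$period)
  if (!is.null(genotype)) {
    out <- dplyr::mutate(out, genotype = genotype, .after = "animal_id")
  }
  out
}

#' Exclude unhealthy animals from a trace cohort
#'
#' Drops animals, in toto, that fail a health rule. The default rule mimics
#' a dead-fly filter: an animal with zero activity counts throughout the
#' final 12 hours of its recording is excluded with reason
#' `"no-terminal-activity"`. A custom rule is a function taking one animal's
#' trace tibble and returning `NULL` (healthy) or a reason string.
#'
#' @param trace Trace tibble covering the full experiment.
#' @param rule `NULL` for the default terminal-inactivity rule, or a
#'   function as described above.
#' @param window_minutes Length of the terminal window inspected by the
#'   default rule (default 720).
#' @return A list with elements `kept` (trace tibble of surviving animals)
#'   and `excluded` (tibble `animal_id`, `reason`).
#' @export
health_filter <- function(trace, rule = NULL, window_minutes = PERIOD_MIN) {
  rule <- rule %||% function(tr) {
    last <- tail(dplyr::arrange(tr, .data$day_index, .data$zt_minute),
                 window_minutes)
    if (all(last$count == 0L)) "no-terminal-activity" else NULL
  }
  if (nrow(trace) == 0L) {
    return(list(kept = trace,
                excluded = tibble::tibble(animal_id = character(),
                                          reason = character())))
  }
  verdicts <- trace |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_map(~ tibble::tibble(animal_id = .y$animal_id,
                                      reason = rule(.x) %||% NA_character_)) |>
    dplyr::bind_rows()
  excluded <- dplyr::filter(verdicts, !is.na(.data$reason))
  list(
    kept = dplyr::filter(trace, !.data$animal_id %in% excluded$animal_id),
    excluded = excluded
  )
}

#' Aggregate animal-period summaries into cohort statistics
#'
#' Mean-of-means aggregation: `mean_bout_length` is the unweighted mean of
#' the per-pair mean bout lengths over pairs with at least one bout (an
#' average of averages, not the pooled-bout mean), while total-sleep and
#' bout-count statistics run over all pairs. SDs are sample SDs; the SD of a
#' single observation is reported as 0 with a warning.
#'
#' @param summaries Summary tibble (one genotype-period condition).
#' @param genotype,period Optional labels recorded in the output; defaults
#'   taken from the data when unambiguous.
#' @return One-row tibble of cohort means, SDs and `n_pairs`.
#' @export
aggregate_cohort <- function(summaries, genotype = NULL, period = NULL) {
  if (nrow(summaries) == 0L) abort("no summaries to aggregate")
  genotype <- genotype %||% (if ("genotype" %in% names(summaries))
    paste(unique(summaries$genotype), collapse = "+") else NA_character_)
  period <- period %||% paste(unique(summaries$period), collapse = "+")
  warned <- FALSE
  sd1 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) {
      if (!warned) warn("SD of a single observation reported as 0")
      warned <<- TRUE
      return(0)
    }
    sd(x)
  }
  withbouts <- dplyr::filter(summaries, .data$bout_count > 0)
  tibble::tibble(
    genotype = genotype, period = period,
    mean_total_sleep = mean(summaries$total_sleep),
    sd_total_sleep = sd1(summaries$total_sleep),
    mean_bout_length = mean(withbouts$mean_bout_length),
    sd_bout_length = sd1(withbouts$mean_bout_length),
    mean_bout_count = mean(summaries$bout_count),
    sd_bout_count = sd1(summaries$bout_count),
    n_pairs = nrow(summaries)
  )
}
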