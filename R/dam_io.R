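#' Read a TriKinetics-style DAM monitor file
#'
#' Parses a tab-delimited DAM2 monitor file (one row per minute; columns:
#' reading index, date, time, status code, then 32 per-channel beam-break
#' counts) into a long activity-trace tibble, one row per animal-minute.
#' Minutes are annotated with zeitgeber time relative to the lights-on clock
#' time and with a day index that increments at each lights-on.
#'
#' Rows whose status code is not 1 ("valid") are dropped with a warning.
#' After dropping, timestamps must be strictly increasing at an exact
#' 1-minute cadence: a gap or duplicate is an error, since downstream sleep
#' scoring assumes contiguous traces.
#'
#' @param path Path to a DAM monitor file.
#' @param lights_on Clock time of lights-on as `"HH:MM"` (default `"08:00"`).
#'   Zeitgeber minute 0 is aligned to this time; minutes 0-719 are the light
#'   phase.
#' @param channels Integer vector of channels (1-32) to keep, or `NULL`
#'   (default) to keep every non-empty channel (at least one nonzero count).
#' @param monitor Label used to build animal ids (`"<monitor>_ch<nn>"`);
#'   defaults to the file name without extension.
#' @param animal_ids Optional character vector naming the kept channels in
#'   order (the DAM format itself carries no animal ids); overrides the
#'   monitor-based ids. [write_dam_file()] lays animals out on channels in
#'   their order of first appearance, so passing that order here makes
#'   read-after-write reproduce a trace exactly.
#' @return A trace tibble with columns `animal_id`, `day_index`,
#'   `zt_minute` (0-1439), `lights_on` (logical), `count`.
#' @examples
#' tr <- simulate_trace_cohort(cohort_preset("control_night"), n_animals = 2)
#' f <- tempfile(fileext = ".txt")
#' write_dam_file(tr, f)
#' tr2 <- read_dam_file(f)
#' @export
read_dam_file <- function(path, lights_on = "08:00", channels = NULL,
                          monitor = NULL, animal_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("empty DAM file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 4L + N_CHANNELS)
  if (length(bad) > 0L) {
    abort(sprintf("malformed DAM row at line %d: expected %d tab-separated fields, found %d",
                  bad[1], 4L + N_CHANNELS, nf[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 4L + N_CHANNELS, byrow = TRUE)
  ts <- as.POSIXct(paste(m[, 2], m[, 3]), format = "%d %b %y %H:%M:%S", tz = "UTC")
  if (anyNA(ts)) {
    abort(sprintf("malformed DAM timestamp at line %d: '%s %s'",
                  which(is.na(ts))[1], m[which(is.na(ts))[1], 2], m[which(is.na(ts))[1], 3]))
  }
  status <- suppressWarnings(as.integer(m[, 4]))
  counts <- suppressWarnings(matrix(as.numeric(m[, -(1:4)]), nrow = nrow(m)))
  if (anyNA(status) || anyNA(counts) || any(counts < 0)) {
    abort("malformed DAM row: non-numeric or negative count/status field")
  }
  drop <- status != 1L
  if (any(drop)) {
    warn(sprintf("dropping %d DAM row(s) with non-valid status code", sum(drop)))
    ts <- ts[!drop]; counts <- counts[!drop, , drop = FALSE]
  }
  if (length(ts) == 0L) abort("no valid rows in DAM file")
  step <- diff(as.numeric(ts))
  if (any(step != 60)) {
    i <- which(step != 60)[1]
    abort(sprintf("non-contiguous timestamps between rows %d and %d (step %g s, expected 60)",
                  i, i + 1L, step[i]))
  }

  lo <- parse_clock_minutes(lights_on)
  clock_min <- as.integer(as.numeric(ts) %/% 60 %% DAY_MIN)
  zt <- (clock_min - lo) %% DAY_MIN
  day_index <- 1L + cumsum(zt == 0L) - as.integer(zt[1] == 0L)

  monitor <- monitor %||% sub("\\.[^.]*$", "", basename(path))
  keep <- channels %||% which(colSums(counts) > 0)
  if (length(keep) == 0L) {
    return(tibble::tibble(animal_id = character(), day_index = integer(),
                          zt_minute = integer(), lights_on = logical(),
                          count = integer()))
  }
  if (!is.null(animal_ids) && length(animal_ids) != length(keep)) {
    abort(sprintf("%d animal_ids supplied for %d kept channel(s)",
                  length(animal_ids), length(keep)))
  }
  purrr::map_dfr(seq_along(keep), function(j) {
    ch <- keep[j]
    tibble::tibble(
      animal_id = animal_ids[j] %||% sprintf("%s_ch%02d", monitor, ch),
      day_index = day_index,
      zt_minute = as.integer(zt),
      lights_on = zt < PERIOD_MIN,
      count = as.integer(counts[, ch])
    )
  })
}

#' Write activity traces as a DAM monitor file
#'
#' Inverse of [read_dam_file()]: lays the traces out on channels 1..k (k <=
#' 32, remaining channels written as zero) at 1-minute cadence with status
#' code 1, so that reading the file back with the same `lights_on` reproduces
#' the traces exactly.
#'
#' @param trace Trace tibble (columns `animal_id`, `day_index`, `zt_minute`,
#'   `lights_on`, `count`); all animals must cover the same aligned minutes.
#' @param path Output path.
#' @param lights_on Lights-on clock time `"HH:MM"`; must match the value the
#'   reader will use.
#' @param start_date Calendar date of the first recorded day (`Date` or
#'   string); only affects the timestamp column.
#' @return `path`, invisibly.
#' @export
write_dam_file <- function(trace, path, lights_on = "08:00",
                           start_date = as.Date("2016-01-04")) {
  check_trace(trace)
  ids <- unique(trace$animal_id)
  if (length(ids) == 0L) abort("no traces to write")
  if (length(ids) > N_CHANNELS) {
    abort(sprintf("a DAM monitor has %d channels; got %d traces", N_CHANNELS, length(ids)))
  }
  wide <- trace |>
    dplyr::arrange(.data$day_index, .data$zt_minute) |>
    tidyr::pivot_wider(id_cols = c("day_index", "zt_minute"),
                       names_from = "animal_id", values_from = "count")
  if (anyNA(wide)) abort("traces are not aligned on the same minutes")
  abs_min <- (wide$day_index - 1L) * DAY_MIN + wide$zt_minute
  if (nrow(wide) > 1L && any(diff(abs_min) != 1L)) {
    abort("trace minutes are not contiguous; DAM files are 1-minute cadence")
  }
  counts <- as.matrix(wide[ids])
  counts <- cbind(counts, matrix(0L, nrow(counts), N_CHANNELS - length(ids)))

  lo <- parse_clock_minutes(lights_on)
  t0 <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC") +
    60 * (lo + wide$zt_minute[1] + DAY_MIN * (wide$day_index[1] - 1L))
  ts <- t0 + 60 * (seq_len(nrow(wide)) - 1L)
  rows <- paste(seq_len(nrow(wide)),
                format(ts, "%d %b %y"), format(ts, "%H:%M:%S"), 1L,
                apply(counts, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Export or import an activity trace as CSV
#'
#' Plain-CSV serialization of the trace tibble (columns `animal_id`,
#' `day_index`, `zt_minute`, `lights_on`, `count`).
#'
#' @param trace Trace tibble.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns the trace tibble.
#' @export
write_trace_csv <- function(trace, path) {
  check_trace(trace)
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(),
    day_index = readr::col_integer(),
    zt_minute = readr::col_integer(),
    lights_on = readr::col_logical(),
    count = readr::col_integer()
  ))
}

parse_clock_minutes <- function(x) {
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(p) < 2L) abort("clock time must be 'HH:MM'")
  60L * as.integer(p[1]) + as.integer(p[2])
}

check_trace <- function(trace) {
  need <- c("animal_id", "day_index", "zt_minute", "lights_on", "count")
  if (!all(need %in% names(trace))) {
    abort(paste("trace must have columns:", paste(need, collapse = ", ")))
  }
  if (any(trace$count < 0)) abort("negative activity counts")
  invisible(trace)
}
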