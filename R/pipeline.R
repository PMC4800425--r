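#' Run the full sleep-architecture analysis
#'
#' Orchestrates the whole pipeline: ingest (DAM files, a pre-scored summary
#' table, or simulator specs), health filtering, sleep scoring, per-condition
#' pooling of animal-period pairs across days, the power-law fit with R^2,
#' confidence intervals, band and dependency, normality diagnostics on the
#' pooled residuals, and Welch genotype-comparison tables.
#'
#' Daytime pairs are analysed separately from nighttime pairs; within a
#' condition, pairs are pooled across the days of the experiment. Pairs with
#' no sleep bout are ineligible for regression (the response is undefined)
#' but still count in cohort statistics and comparisons. Conditions with
#' fewer than 3 eligible pairs are reported as unfittable and the pipeline
#' continues. No multiple-testing correction is applied to the comparison
#' table.
#'
#' @param input One of: a list of [cohort_spec()]s (simulated input), a
#'   summary tibble (columns `animal_id`, `genotype`, `day_index`, `period`,
#'   `total_sleep`, `bout_count`, `mean_bout_length`), or a character vector
#'   of DAM file paths (one genotype per file; the file name is the
#'   genotype label).
#' @param control Genotype label used as reference in comparisons; defaults
#'   to the first genotype encountered.
#' @param lights_on Lights-on clock time for DAM input.
#' @param min_sleep_minutes Sleep threshold for scoring (default 5).
#' @param weighting Passed to [fit_powerlaw()].
#' @param band_points Number of grid points for each condition's confidence
#'   band.
#' @param seed Seed used when `input` is a list of specs.
#' @return A `sleep_analysis` object: `summaries`, `cohorts` (one row per
#'   condition), `reports` (fit + K2 per condition), `fits` (named list of
#'   `powerlaw_fit`), `bands` (named list of band tibbles), `comparisons`
#'   (Welch table), `excluded`.
#' @examples
#' an <- run_analysis(list(cohort_preset("control_night", seed = 7)))
#' an$reports
#' @export
run_analysis <- function(input, control = NULL, lights_on = "08:00",
                         min_sleep_minutes = 5L,
                         weighting = c("none", "inverse_y2"),
                         band_points = 50L, seed = NULL) {
  weighting <- match.arg(weighting)
  excluded <- tibble::tibble(animal_id = character(), reason = character())

  if (is.data.frame(input)) {
    summaries <- input
  } else if (is.list(input) && all(purrr::map_lgl(input, inherits, "cohort_spec"))) {
    if (!is.null(seed)) {
      input <- purrr::imap(input, function(sp, i) {
        sp$seed <- (as.integer(seed) + 977L * (if (is.character(i)) match(i, names(input)) else i)) %% (2^31 - 1)
        sp
      })
    }
    summaries <- purrr::map_dfr(input, make_cohort)
  } else if (is.character(input)) {
    traces <- purrr::map_dfr(input, function(p) {
      tr <- read_dam_file(p, lights_on = lights_on)
      dplyr::mutate(tr, genotype = sub("\\.[^.]*$", "", basename(p)))
    })
    hf <- health_filter(dplyr::select(traces, -"genotype"))
    excluded <- hf$excluded
    geno <- dplyr::distinct(traces, .data$animal_id, .data$genotype)
    summaries <- sleep_summary(hf$kept, min_sleep_minutes) |>
      dplyr::left_join(geno, by = "animal_id") |>
      dplyr::relocate("genotype", .after = "animal_id")
  } else {
    abort("input must be a summary data frame, a list of cohort_specs, or DAM file paths")
  }
  if (!"genotype" %in% names(summaries)) {
    summaries <- dplyr::mutate(summaries, genotype = "all", .after = "animal_id")
  }
  control <- control %||% summaries$genotype[1]

  conds <- dplyr::distinct(summaries, .data$genotype, .data$period)
  fits <- list(); bands <- list()
  reports <- purrr::pmap_dfr(conds, function(genotype, period) {
    d <- dplyr::filter(summaries, .data$genotype == !!genotype,
                       .data$period == !!period)
    eligible <- dplyr::filter(d, .data$bout_count >= 1)
    key <- paste(genotype, period, sep = "_")
    row <- tibble::tibble(genotype = genotype, period = period,
                          n_pairs = nrow(d), n_eligible = nrow(eligible))
    if (nrow(eligible) < 3L || length(unique(eligible$bout_count)) < 2L) {
      inform(sprintf("condition %s: unfittable (%d eligible pairs)", key,
                     nrow(eligible)))
      return(dplyr::mutate(row, fittable = FALSE))
    }
    fit <- fit_powerlaw(eligible, weighting = weighting, label = key)
    fits[[key]] <<- fit
    bands[[key]] <<- confidence_band(
      fit, x_grid = seq(min(fit$data$x), max(fit$data$x),
                        length.out = band_points))
    k2 <- if (fit$n >= 20) k2_residuals(fit) else NULL
    dplyr::mutate(
      row, fittable = TRUE,
      a = fit$a, b = fit$b, r_squared = fit$r_squared,
      ci_a_low = fit$ci_a[1], ci_a_high = fit$ci_a[2],
      ci_b_low = fit$ci_b[1], ci_b_high = fit$ci_b[2],
      dependency = fit$dependency, converged = fit$converged,
      k2_statistic = if (is.null(k2)) NA_real_ else k2$statistic,
      k2_p_value = if (is.null(k2)) NA_real_ else k2$p_value
    )
  })

  cohorts <- summaries |>
    dplyr::group_by(.data$genotype, .data$period) |>
    dplyr::group_map(~ aggregate_cohort(.x, genotype = .y$genotype,
                                        period = .y$period)) |>
    dplyr::bind_rows()

  comparisons <- comparison_table(summaries, control)

  structure(list(
    summaries = summaries, cohorts = cohorts, reports = reports,
    fits = fits, bands = bands, comparisons = comparisons,
    excluded = excluded, control = control,
    config = list(min_sleep_minutes = min_sleep_minutes,
                  weighting = weighting, lights_on = lights_on, seed = seed)
  ), class = "sleep_analysis")
}

#' @export
print.sleep_analysis <- function(x, ...) {
  cat(sprintf("Sleep-architecture analysis: %d condition(s), control = %s\n",
              nrow(x$reports), x$control))
  print(x$reports)
  invisible(x)
}

comparison_table <- function(summaries, control) {
  genos <- setdiff(unique(summaries$genotype), control)
  ctrl <- dplyr::filter(summaries, .data$genotype == control)
  purrr::map_dfr(genos, function(g) {
    mut <- dplyr::filter(summaries, .data$genotype == g)
    per_period <- purrr::map_dfr(unique(summaries$period), function(p) {
      a <- dplyr::filter(ctrl, .data$period == p)
      b <- dplyr::filter(mut, .data$period == p)
      if (nrow(a) < 2L || nrow(b) < 2L) return(NULL)
      purrr::map_dfr(
        c("total_sleep", "mean_bout_length", "bout_count"),
        function(metric) compare_genotypes(a, b, metric) |>
          dplyr::mutate(period = p, .before = 1)
      )
    })
    c24 <- total_sleep_24h(ctrl); m24 <- total_sleep_24h(mut)
    t24 <- if (nrow(c24) >= 2L && nrow(m24) >= 2L) {
      dplyr::mutate(compare_genotypes(c24, m24, "total_sleep_24h"),
                    period = "24h", .before = 1)
    } else NULL
    dplyr::bind_rows(per_period, t24) |>
      dplyr::mutate(genotype = g, control = control, .before = 1)
  })
}

#' Welch comparison of a sleep metric between two groups
#'
#' Two-tailed heteroscedastic t-test on the per-pair values of a metric
#' between two summary tables (typically a mutant and its control). A group
#' with degenerate (zero) variance yields a flagged row with `p_value = NA`
#' rather than an error.
#'
#' @param summaries_a,summaries_b Summary tibbles for the two groups.
#' @param metric Column to compare: `"total_sleep"`, `"mean_bout_length"`,
#'   `"bout_count"`, or `"total_sleep_24h"` (computed by
#'   [total_sleep_24h()]).
#' @return One-row tibble: `metric`, Welch `statistic`, `p_value`, `df`,
#'   group sizes and means, `flag`. A group with fewer than 2 finite values
#'   for the metric yields a flagged `"insufficient-data"` row.
#' @export
compare_genotypes <- function(summaries_a, summaries_b, metric = "total_sleep") {
  a <- summaries_a[[metric]]
  b <- summaries_b[[metric]]
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be nonempty")
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  flag <- NA_character_
  if (length(a) < 2L || length(b) < 2L) {
    return(tibble::tibble(
      metric = metric, statistic = NA_real_, p_value = NA_real_,
      df = NA_real_, n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b), flag = "insufficient-data"))
  }
  if (sd(a) == 0 || sd(b) == 0) flag <- "degenerate-variance"
  res <- if (sd(a) == 0 && sd(b) == 0) {
    tibble::tibble(name = "welch_t", statistic = NA_real_,
                   p_value = NA_real_, df = NA_real_,
                   n_a = length(a), n_b = length(b),
                   mean_a = mean(a), mean_b = mean(b))
  } else {
    welch_t_test(a, b)
  }
  dplyr::mutate(dplyr::select(res, -"name"), metric = metric, .before = 1) |>
    dplyr::mutate(flag = flag)
}

#' Per-animal-day 24-hour total sleep
#'
#' Sums each animal-day's day and night totals; only animal-days with both
#' periods present contribute.
#'
#' @param summaries Summary tibble.
#' @return Tibble `animal_id`, `day_index`, `total_sleep_24h`.
#' @export
total_sleep_24h <- function(summaries) {
  summaries |>
    dplyr::group_by(.data$animal_id, .data$day_index) |>
    dplyr::filter(dplyr::n_distinct(.data$period) == 2L) |>
    dplyr::summarise(total_sleep_24h = sum(.data$total_sleep), .groups = "drop")
}

#' Export fit results
#'
#' Writes the per-condition report table as CSV and, optionally, each
#' condition's confidence band.
#'
#' @param analysis A `sleep_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "sleep_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(analysis$reports, file.path(dir, "condition_reports.csv"))
  readr::write_csv(analysis$cohorts, file.path(dir, "cohort_summaries.csv"))
  readr::write_csv(analysis$comparisons, file.path(dir, "comparisons.csv"))
  readr::write_csv(analysis$summaries, file.path(dir, "animal_period_summaries.csv"))
  purrr::iwalk(analysis$bands, function(b, key) {
    readr::write_csv(b, file.path(dir, sprintf("band_%s.csv", key)))
  })
  invisible(dir)
}
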