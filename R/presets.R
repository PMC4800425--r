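#' Shipped cohort presets
#'
#' Ready-made [cohort_spec()]s for the genotype/period conditions the
#' simulator is calibrated to: a wild-type control (w1118-like), a
#' fragmented hyposomnolent mutant (insomniac-like), a quasi-wildtype iso31
#' line, and a severely hyposomnolent fumin-like line. Total-sleep and
#' bout-count means/SDs follow published cohort statistics for these lines;
#' the fumin presets run in unregulated mode (mean bout length independent
#' of bout count), the regime in which the power-law fit collapses.
#'
#' The insomniac day total is derived as the 24-h total minus the night
#' total (means 770.1 - 394.7, SDs combined in quadrature); count
#' distributions for iso31 reuse the control values and fumin reuses the
#' insomniac (fragmented) values, since per-line counts are not published.
#'
#' @param name One of `"control_day"`, `"control_night"`, `"insomniac_day"`,
#'   `"insomniac_night"`, `"iso31_day"`, `"iso31_night"`, `"fumin_day"`,
#'   `"fumin_night"`.
#' @param ... Overrides passed to [cohort_spec()] (e.g. `seed`,
#'   `n_animals`).
#' @return A `cohort_spec`.
#' @examples
#' cohort_preset("control_night")
#' @export
cohort_preset <- function(name, ...) {
  p <- list(
    control_day     = list("control",   "day",   396.4,  82.9, 12.6, 4.6, regulation = "regulated"),
    control_night   = list("control",   "night", 672.6,  29.9,  4.9, 4.2, regulation = "regulated"),
    insomniac_day   = list("insomniac", "day",   375.4, 148.3, 23.1, 8.1, regulation = "regulated"),
    insomniac_night = list("insomniac", "night", 394.7, 148.7, 16.8, 7.5, regulation = "regulated"),
    iso31_day       = list("iso31",     "day",   500.1,  56.1, 12.6, 4.6, regulation = "regulated"),
    iso31_night     = list("iso31",     "night", 559.5,  49.5,  4.9, 4.2, regulation = "regulated"),
    fumin_day       = list("fumin",     "day",   199.4,  80.3, 23.1, 8.1, regulation = "unregulated"),
    fumin_night     = list("fumin",     "night", 142.1, 115.4, 16.8, 7.5, regulation = "unregulated")
  )[[name]]
  if (is.null(p)) abort(sprintf("unknown preset '%s'", name))
  args <- c(setNames(p[1:6], c("genotype", "period", "mean_total_sleep",
                               "sd_total_sleep", "count_mean", "count_sd")),
            p[-(1:6)])
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_spec, args)
}

#' Shipped deprivation/rebound presets
#'
#' Scenario parameters for the fourth-night full deprivation and fifth-day
#' rebound: control (7 animals; night-4 mean 9.1 min, SD 21.6; day-5 mean
#' 496 min, SD 50.2) and insomniac (9 animals; night-4 mean 3.4 min, SD not
#' published, 10 min used; day-5 mean 496 min, SD 126). Rebound day-5 sleep
#' is tighter, relative to its mean, than baseline daytime sleep, which is
#' what drives the higher rebound R-squared.
#'
#' @param genotype `"control"` or `"insomniac"`.
#' @param n_animals,seed Overrides.
#' @return Summary tibble from [make_rebound_scenario()].
#' @export
rebound_preset <- function(genotype = c("control", "insomniac"),
                           n_animals = NULL, seed = 20160104L) {
  genotype <- match.arg(genotype)
  if (genotype == "control") {
    make_rebound_scenario(
      cohort_preset("control_day"), cohort_preset("control_night"),
      deprivation_mean = 9.1, deprivation_sd = 21.6,
      rebound_mean = 496, rebound_sd = 50.2,
      n_animals = n_animals %||% 7L, seed = seed
    )
  } else {
    make_rebound_scenario(
      cohort_preset("insomniac_day"), cohort_preset("insomniac_night"),
      deprivation_mean = 3.4, deprivation_sd = 10,
      rebound_mean = 496, rebound_sd = 126,
      n_animals = n_animals %||% 9L, seed = seed
    )
  }
}
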