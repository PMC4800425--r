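test_that("count calibration reproduces the target moments", {
  cal <- calibrate_count_distribution(4.9, 4.2)
  expect_equal(cal$family, "shifted_nbinom")
  # exact moment match of the family itself
  expect_equal(1 + cal$mu, 4.9)
  expect_equal(sqrt(cal$mu + cal$mu^2 / cal$size), 4.2, tolerance = 1e-9)
  withr::local_seed(1)
  x <- draw_bout_counts(10000, cal)
  expect_lt(abs(mean(x) - 4.9) / 4.9, 0.05)
  expect_lt(abs(sd(x) - 4.2) / 4.2, 0.05)
  expect_true(all(x >= 1))
})

test_that("calibration limit cases degrade gracefully", {
  point <- calibrate_count_distribution(4.9, 0)
  expect_equal(point$family, "point")
  expect_true(all(draw_bout_counts(50, point) == 5L))

  ones <- calibrate_count_distribution(1, 1e-12)
  expect_true(all(draw_bout_counts(50, ones) == 1L))

  expect_warning(pois <- calibrate_count_distribution(6, 1),
                 "shifted Poisson")
  expect_equal(pois$family, "shifted_poisson")
})

test_that("a cohort is animals x periods pairs satisfying the summary invariants", {
  s <- make_cohort(cohort_preset("control_night", seed = 11))
  expect_equal(nrow(s), 124L)
  expect_equal(dplyr::n_distinct(s$animal_id), 31L)
  expect_true(all(s$total_sleep <= 720 & s$total_sleep >= 5 * s$bout_count))
  expect_true(all(s$total_sleep + s$bout_count - 1 <= 720))
  expect_identical(s$total_sleep, s$bout_count * s$mean_bout_length)
  # deterministic given the seed
  expect_identical(s, make_cohort(cohort_preset("control_night", seed = 11)))
})

test_that("a noiseless regulated cohort sits exactly on y = T0/x", {
  spec <- cohort_spec("g", "night", mean_total_sleep = 600, sd_total_sleep = 0,
                      count_mean = 5, count_sd = 3, seed = 2)
  s <- make_cohort(spec)
  expect_true(all(s$total_sleep == 600))
  f <- fit_powerlaw(s)
  expect_equal(f$a, 600, tolerance = 1e-6)
  expect_equal(f$b, -1, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
})

test_that("the control-night preset hits its calibrated total-sleep mean", {
  s <- make_cohort(cohort_preset("control_night", seed = 4))
  # per-pair expectation under feasibility truncation to [5x, 720 - (x-1)]
  tn_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  pop <- mean(tn_mean(672.6, 29.9, 5 * s$bout_count, 720 - (s$bout_count - 1)))
  # the feasibility truncation biases the generator by well under 1%
  expect_lt(abs(pop - 672.6) / 672.6, 0.01)
  expect_lt(abs(mean(s$total_sleep) - pop), 3 * 29.9 / sqrt(124))
  expect_lt(abs(mean(s$bout_count) - 4.9), 3 * 4.2 / sqrt(124))
})

test_that("regulation mode controls the bout-count dependence of the summaries", {
  # regulated: total sleep is drawn independently of bout count
  reg <- make_cohort(cohort_preset("control_night", seed = 6))
  ct_reg <- stats::cor.test(reg$bout_count, reg$total_sleep)
  expect_gt(ct_reg$p.value, 0.01)
  # regulated: mean bout length falls steeply with count
  expect_lt(stats::cor(log(reg$bout_count + 1), log(reg$mean_bout_length)), -0.8)
  # unregulated: mean bout length carries no negative count dependence
  unreg <- make_cohort(cohort_preset("fumin_night", seed = 6))
  ct_un <- stats::cor.test(unreg$bout_count, unreg$mean_bout_length,
                           alternative = "less")
  expect_gt(ct_un$p.value, 0.05)
})

test_that("realize_trace round-trips through score_sleep", {
  withr::local_seed(14)
  s <- make_cohort(cohort_preset("control_night", seed = 14, n_animals = 4L))
  for (i in seq_len(nrow(s))) {
    tr <- realize_trace(s[i, ])
    expect_equal(nrow(tr), 720L)
    b <- score_sleep(tr)
    got <- summarize_period(b, s$animal_id[i], s$day_index[i], s$period[i])
    expect_equal(got$total_sleep, s$total_sleep[i])
    expect_equal(got$bout_count, s$bout_count[i])
  }
})

test_that("realize_trace forced and windowed arrangements", {
  full <- tibble::tibble(animal_id = "a", day_index = 1L, period = "night",
                         total_sleep = 720, bout_count = 1L)
  tr <- realize_trace(full)
  expect_true(all(tr$count == 0L))

  withr::local_seed(30)
  small <- tibble::tibble(animal_id = "a", day_index = 1L, period = "day",
                          total_sleep = 12, bout_count = 2L)
  for (rep in 1:10) {
    tr <- realize_trace(small, period_minutes = 30L)
    r <- rle(tr$count == 0L)
    zeros <- r$lengths[r$values]
    expect_equal(sort(zeros), sort(as.integer(zeros)))
    expect_equal(sum(zeros), 12L)
    expect_length(zeros, 2L)
    expect_true(all(zeros >= 5L))
  }

  bad <- tibble::tibble(animal_id = "a", day_index = 1L, period = "day",
                        total_sleep = 700, bout_count = 30L)
  expect_error(realize_trace(bad), "infeasible")
})

test_that("rebound scenarios deprive night 4 and rebound above baseline day sleep", {
  rb <- rebound_preset("control", seed = 1)
  n4 <- dplyr::filter(rb, day_index == 4, period == "night")
  d5 <- dplyr::filter(rb, day_index == 5, period == "day")
  base_days <- dplyr::filter(rb, period == "day", day_index <= 4)
  expect_equal(nrow(n4), 7L)
  expect_equal(nrow(d5), 7L)
  expect_lt(mean(n4$total_sleep), 30)
  expect_lt(abs(mean(d5$total_sleep) - 496), 3 * 50.2 / sqrt(7))
  # every row realizable and identity-consistent
  expect_true(all(rb$total_sleep >= 5 * rb$bout_count))
  ok <- rb$bout_count > 0
  expect_identical(rb$total_sleep[ok], rb$bout_count[ok] * rb$mean_bout_length[ok])

  for (seed in 1:20) {
    r <- rebound_preset("control", seed = seed)
    expect_gt(mean(r$total_sleep[r$day_index == 5 & r$period == "day"]),
              mean(r$total_sleep[r$period == "day" & r$day_index <= 4]))
  }

  degen <- make_rebound_scenario(
    cohort_preset("control_day"), cohort_preset("control_night"),
    deprivation_mean = 0, deprivation_sd = 0,
    rebound_mean = 496, rebound_sd = 50.2, n_animals = 5, seed = 3)
  expect_true(all(degen$total_sleep[degen$day_index == 4 &
                                      degen$period == "night"] == 0))
})

test_that("regulated fits recover the generator parameters at low noise", {
  spec <- cohort_spec("g", "night", mean_total_sleep = 672.6,
                      sd_total_sleep = 0.05 * 672.6 / 2,  # 2.5% CV
                      count_mean = 4.9, count_sd = 4.2, seed = 77)
  f <- fit_powerlaw(make_cohort(spec))
  expect_gte(f$b, -1.2); expect_lte(f$b, -0.8)
  expect_lt(abs(f$a - 672.6) / 672.6, 0.10)
})
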