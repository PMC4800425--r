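pts <- function(x, y) tibble::tibble(bout_count = x, mean_bout_length = y)

test_that("exact power-law points are recovered exactly", {
  f <- fit_powerlaw(pts(c(1, 2, 4), c(100, 50, 25)))
  expect_equal(f$a, 100, tolerance = 1e-6)
  expect_equal(f$b, -1, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_lt(f$ss_res, 1e-12)
  expect_true(f$converged)
})

test_that("the three-point fit matches the grid-search oracle", {
  # frozen from an independent dense grid + simplex refinement of the SSE
  f <- fit_powerlaw(pts(c(1, 2, 4), c(10, 6, 3)))
  expect_equal(f$a, 10.079368, tolerance = 1e-4)
  expect_equal(f$b, -0.81724203, tolerance = 1e-4)
  expect_equal(f$r_squared, 0.9941113758, tolerance = 1e-6)
  # R^2 reported by the fit equals the independent formula evaluation
  res <- c(10, 6, 3) - f$a * c(1, 2, 4)^f$b
  expect_equal(f$r_squared,
               1 - sum(res^2) / sum((c(10, 6, 3) - mean(c(10, 6, 3)))^2))
  expect_equal(r_squared(f), f$r_squared)

  w <- weighted_fit_1_over_y2(pts(c(1, 2, 4), c(10, 6, 3)))
  expect_equal(w$a, 10.28072094, tolerance = 1e-4)
  expect_equal(w$b, -0.8684828, tolerance = 1e-4)
})

test_that("scaling y scales a and leaves b and R^2 unchanged", {
  withr::local_seed(5)
  x <- sample(1:20, 10, replace = TRUE)
  y <- 300 * x^-0.9 * exp(rnorm(10, 0, 0.1))
  f1 <- fit_powerlaw(pts(x, y))
  f2 <- fit_powerlaw(pts(x, 3.5 * y))
  expect_equal(f2$a, 3.5 * f1$a, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
})

test_that("the fit matches the grid-search oracle on random small inputs", {
  withr::local_seed(99)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    x <- sample(1:30, n, replace = TRUE)
    if (length(unique(x)) < 2) next
    y <- runif(1, 50, 700) * x^runif(1, -1.5, -0.5) * exp(rnorm(n, 0, 0.25))
    f <- fit_powerlaw(pts(x, y))
    o <- oracle_powerlaw(x, y)
    expect_lt(abs(f$ss_res - o$sse) / max(o$sse, 1e-12), 1e-3)
  }
})

test_that("fixing b at -1 gives the closed-form scale estimate", {
  withr::local_seed(31)
  x <- sample(1:15, 20, replace = TRUE)
  y <- 500 / x * exp(rnorm(20, 0, 0.2))
  f <- fit_powerlaw(pts(x, y), fix_b = -1)
  expect_equal(f$b, -1)
  expect_equal(f$a, sum(y / x) / sum(1 / x^2), tolerance = 1e-12)
  expect_equal(f$df, 19L)
})

test_that("weighted and unweighted fits coincide on exact data and constant weights", {
  f0 <- fit_powerlaw(pts(c(1, 2, 4), c(100, 50, 25)))
  fw <- weighted_fit_1_over_y2(pts(c(1, 2, 4), c(100, 50, 25)))
  expect_equal(c(fw$a, fw$b), c(f0$a, f0$b), tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_powerlaw(pts(c(1, 2), c(3, 4))), "at least 3 points")
  expect_error(fit_powerlaw(pts(c(3, 3, 3), c(1, 2, 3))), "unidentifiable")
  expect_message(fit_powerlaw(pts(c(0.5, 1, 2, 4), c(9, 10, 6, 3))),
                 "ineligible")
})

test_that("dependency is the squared parameter correlation, in [0, 1]", {
  fake <- structure(list(covariance = matrix(c(4, 2, 2, 4), 2)),
                    class = "powerlaw_fit")
  expect_equal(dependency(fake), 0.25)
  diag_only <- structure(list(covariance = diag(c(1, 2))),
                         class = "powerlaw_fit")
  expect_equal(dependency(diag_only), 0)
  degen <- structure(list(covariance = matrix(0, 2, 2)),
                     class = "powerlaw_fit")
  expect_warning(expect_true(is.na(dependency(degen))), "undefined")

  withr::local_seed(8)
  for (rep in 1:8) {
    x <- sample(1:25, 30, replace = TRUE)
    y <- 400 * x^-1 * exp(rnorm(30, 0, 0.3))
    f <- fit_powerlaw(pts(x, y))
    expect_gte(f$dependency, 0)
    expect_lte(f$dependency, 1)
  }
})

test_that("the confidence band is the delta-method band around the curve", {
  withr::local_seed(21)
  x <- rep(1:8, 3)
  y <- 200 * x^-0.95 * exp(rnorm(24, 0, 0.15))
  f <- fit_powerlaw(pts(x, y))
  cb <- confidence_band(f, x_grid = c(1, 2, 5))
  # contains the fitted curve
  expect_true(all(cb$lower <= cb$fit & cb$fit <= cb$upper))
  # at x = 1 the gradient is (1, 0): half-width = t * se(a)
  tq <- qt(0.975, f$df)
  expect_equal(cb$upper[1] - cb$fit[1], tq * sqrt(f$covariance[1, 1]),
               tolerance = 1e-10)
  # independent delta-method arithmetic at x = 5
  g <- c(5^f$b, f$a * 5^f$b * log(5))
  expect_equal(cb$upper[3] - cb$fit[3],
               tq * sqrt(drop(t(g) %*% f$covariance %*% g)), tolerance = 1e-10)
  expect_error(confidence_band(f, x_grid = c(-1, 2)), "x > 0")

  exact <- fit_powerlaw(pts(c(1, 2, 4), c(100, 50, 25)))
  cbe <- confidence_band(exact, x_grid = c(1, 3))
  expect_lt(max(cbe$upper - cbe$lower), 1e-4)
})

test_that("R^2 is 0 for the mean line and NA when all responses are equal", {
  x <- c(1, 2, 4, 8); y <- c(10, 6, 3, 2)
  mean_fit <- structure(list(a = mean(y), b = 0,
                             data = tibble::tibble(x = x, y = y,
                                                   w = rep(1, 4))),
                        class = "powerlaw_fit")
  expect_equal(r_squared(mean_fit), 0)
  flat <- structure(list(a = 5, b = 0,
                         data = tibble::tibble(x = x, y = rep(7, 4),
                                               w = rep(1, 4))),
                    class = "powerlaw_fit")
  expect_warning(expect_true(is.na(r_squared(flat))), "undefined")
})

test_that("tidy and glance expose the fit in broom form", {
  f <- fit_powerlaw(pts(rep(1:6, 2), 300 * rep(1:6, 2)^-1 + c(1:6, -(1:6))),
                    label = "demo")
  td <- tidy(f)
  expect_equal(td$term, c("a", "b"))
  expect_equal(td$conf.low, c(f$ci_a[1], f$ci_b[1]))
  expect_true(all(td$std.error > 0))
  gl <- glance(f)
  expect_equal(gl$label, "demo")
  expect_equal(gl$nobs, 12L)
  expect_equal(gl$r.squared, f$r_squared)
})

test_that("parameter CIs cover the truth at roughly the nominal rate", {
  # constant-variance noise: the unweighted fit's Wald CIs are exact in
  # specification; multiplicative noise pairs with the 1/y^2-weighted fit
  # (exercised in the end-to-end property suite)
  withr::local_seed(404)
  a0 <- 600; b0 <- -1
  hits_a <- 0L; hits_b <- 0L; reps <- 200L
  for (i in seq_len(reps)) {
    x <- sample(1:20, 40, replace = TRUE)
    y <- pmax(a0 * x^b0 + rnorm(40, 0, 5), 1)
    f <- fit_powerlaw(pts(x, y))
    hits_a <- hits_a + (f$ci_a[1] <= a0 && a0 <= f$ci_a[2])
    hits_b <- hits_b + (f$ci_b[1] <= b0 && b0 <= f$ci_b[2])
  }
  expect_gte(hits_a / reps, 0.90)
  expect_lte(hits_a / reps, 0.99)
  expect_gte(hits_b / reps, 0.90)
  expect_lte(hits_b / reps, 0.99)
})
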