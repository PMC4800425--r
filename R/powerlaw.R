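#' Fit the power law Y = a*X^b to animal-period sleep architecture
#'
#' Least-squares fit of mean sleep bout length (Y) against sleep bout count
#' (X), constrained to the curve Y = a*X^b. The exponent b sits near -1 in
#' well-regulated sleep, in which case a estimates mean total sleep (since
#' total sleep = bout count x mean bout length); the coefficient of
#' determination of this fit measures how tightly total sleep is held in a
#' narrow range despite variation in bout structure.
#'
#' The minimizer is Levenberg-Marquardt ([minpack.lm::nlsLM()]) started from
#' the log-log ordinary regression of log(y) on log(x), which makes
#' convergence deterministic for well-posed inputs. The parameter covariance
#' is the usual asymptotic `s^2 (J'WJ)^-1` with `s^2 = SSres/(n - 2)`; 95%
#' confidence intervals are Wald intervals on n - 2 degrees of freedom.
#' With `weighting = "inverse_y2"` the objective weights each residual by
#' `1/y^2`; the reported R-squared stays unweighted by default so weighted
#' and unweighted fits are comparable (see [r_squared()]).
#'
#' @param data Data frame of regression points; rows with `x < 1`, `y <= 0`
#'   or missing y (animal-periods with no sleep bout) are not eligible and
#'   are dropped with a message.
#' @param x,y Columns holding bout count and mean bout length
#'   (unquoted; default `bout_count`, `mean_bout_length`).
#' @param weighting `"none"` (ordinary least squares) or `"inverse_y2"`
#'   (weights `1/y^2`).
#' @param fix_b Optional fixed exponent (e.g. `-1`); the scale `a` is then
#'   the closed-form weighted least-squares solution
#'   `a = sum(w y x^b) / sum(w x^(2b))` on n - 1 degrees of freedom.
#' @param level Confidence level for parameter intervals (default 0.95).
#' @param label Optional condition label carried into reports.
#' @return An object of class `powerlaw_fit`: estimates `a`, `b`, their
#'   covariance, `r_squared`, `ss_res`/`ss_tot`, Wald `ci_a`/`ci_b`,
#'   parameter `dependency`, residual df and convergence flag. Methods:
#'   [print()], [tidy()], [glance()], [autoplot()], [confidence_band()],
#'   [dependency()], [r_squared()], `residuals()`, `predict()`.
#' @examples
#' pts <- tibble::tibble(bout_count = c(1, 2, 4), mean_bout_length = c(100, 50, 25))
#' fit_powerlaw(pts)   # exact: a = 100, b = -1, R^2 = 1
#' @export
fit_powerlaw <- function(data, x = bout_count, y = mean_bout_length,
                         weighting = c("none", "inverse_y2"), fix_b = NULL,
                         level = 0.95, label = NULL) {
  weighting <- match.arg(weighting)
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  yv <- as.numeric(dplyr::pull(data, {{ y }}))
  ok <- !is.na(xv) & !is.na(yv) & xv >= 1 & yv > 0
  if (any(!ok)) {
    inform(sprintf("dropping %d ineligible point(s) (x < 1, y <= 0 or missing)",
                   sum(!ok)))
    xv <- xv[ok]; yv <- yv[ok]
  }
  n <- length(xv)
  npar <- if (is.null(fix_b)) 2L else 1L
  if (n < npar + 1L) {
    abort(sprintf("at least %d points needed to fit %d parameter(s); got %d",
                  npar + 1L, npar, n))
  }
  if (is.null(fix_b) && length(unique(xv)) < 2L) {
    abort("all bout counts identical: exponent b is unidentifiable")
  }
  w <- if (weighting == "inverse_y2") 1 / yv^2 else rep(1, n)

  if (is.null(fix_b)) {
    ll <- coef(lm(log(yv) ~ log(xv)))
    fit <- minpack.lm::nlsLM(
      yv ~ a * xv^b,
      start = list(a = exp(unname(ll[1])), b = unname(ll[2])),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
    )
    est <- coef(fit)
    V <- vcov(fit)
    converged <- fit$convInfo$isConv
  } else {
    b <- fix_b
    a <- sum(w * yv * xv^b) / sum(w * xv^(2 * b))
    est <- c(a = a, b = b)
    res <- yv - a * xv^b
    s2 <- sum(w * res^2) / (n - 1L)
    V <- matrix(c(s2 / sum(w * xv^(2 * b)), 0, 0, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    converged <- TRUE
  }
  fitted <- est[["a"]] * xv^est[["b"]]
  res <- yv - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((yv - mean(yv))^2)
  df <- n - npar
  tq <- qt(1 - (1 - level) / 2, df)
  se <- sqrt(diag(V))
  structure(list(
    a = unname(est[["a"]]), b = unname(est[["b"]]),
    covariance = V, se = se,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    ss_res = ss_res, ss_tot = ss_tot,
    ci_a = unname(est[["a"]] + c(-1, 1) * tq * se[["a"]]),
    ci_b = if (is.null(fix_b)) unname(est[["b"]] + c(-1, 1) * tq * se[["b"]])
           else c(fix_b, fix_b),
    dependency = dependency_from_cov(V),
    n = n, df = df, sigma2 = ss_res / df, level = level,
    weighting = weighting, fix_b = fix_b, converged = converged,
    label = label %||% NA_character_,
    data = tibble::tibble(x = xv, y = yv, w = w)
  ), class = "powerlaw_fit")
}

#' Weighted power-law fit with 1/y^2 weights
#'
#' Shorthand for `fit_powerlaw(..., weighting = "inverse_y2")`: each
#' residual is weighted by the inverse squared response, down-weighting the
#' long-bout tail.
#'
#' @inheritParams fit_powerlaw
#' @export
weighted_fit_1_over_y2 <- function(data, x = bout_count, y = mean_bout_length,
                                   ...) {
  fit_powerlaw(data, x = {{ x }}, y = {{ y }}, weighting = "inverse_y2", ...)
}

#' Coefficient of determination of a power-law fit
#'
#' `R^2 = 1 - SSres/SStot`, where SSres sums squared vertical distances from
#' the points to the fitted curve and SStot sums squared distances to the
#' horizontal line through the mean response. May be negative for a fit
#' worse than the mean line. When all responses are equal (SStot = 0) the
#' value is undefined and returned as `NA` with a warning. For weighted
#' fits the default is the unweighted R^2 (comparable across weightings);
#' `weighted = TRUE` uses the weighted sums instead.
#'
#' @param fit A `powerlaw_fit`.
#' @param data Optional new points (columns `x`, `y`) to evaluate against;
#'   defaults to the fitting data.
#' @param weighted Use the fit's weights in both sums.
#' @return A single number (or `NA` if undefined).
#' @export
r_squared <- function(fit, data = NULL, weighted = FALSE) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  d <- data %||% fit$data
  w <- if (weighted) (if (is.null(data)) fit$data$w else 1 / d$y^2) else rep(1, nrow(d))
  res <- d$y - fit$a * d$x^fit$b
  ss_tot <- sum(w * (d$y - sum(w * d$y) / sum(w))^2)
  if (ss_tot == 0) {
    warn("all responses equal: R^2 undefined (SStot = 0)")
    return(NA_real_)
  }
  1 - sum(w * res^2) / ss_tot
}

#' Delta-method confidence band around a fitted power-law curve
#'
#' Pointwise band for the fitted curve: `yhat(x) +/- t * sqrt(g' C g)` with
#' gradient `g = (x^b, a x^b log x)` and C the parameter covariance. At
#' x = 1 the gradient reduces to (1, 0), so the band width there reflects
#' the uncertainty in `a` alone. This is a confidence band for the curve,
#' not a prediction band for new observations.
#'
#' @param fit A converged `powerlaw_fit`.
#' @param x_grid Positive bout-count values at which to evaluate the band;
#'   default 200 points spanning the fitted data.
#' @param level Confidence level (default the fit's own).
#' @return Tibble with columns `x`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, x_grid = NULL, level = NULL) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  if (!fit$converged) abort("fit did not converge; no band available")
  x_grid <- x_grid %||% seq(min(fit$data$x), max(fit$data$x), length.out = 200)
  if (any(x_grid <= 0)) abort("band requires x > 0")
  level <- level %||% fit$level
  tq <- qt(1 - (1 - level) / 2, fit$df)
  yhat <- fit$a * x_grid^fit$b
  g <- cbind(x_grid^fit$b, fit$a * x_grid^fit$b * log(x_grid))
  half <- tq * sqrt(rowSums((g %*% fit$covariance) * g))
  tibble::tibble(x = x_grid, fit = yhat, lower = yhat - half, upper = yhat + half)
}

#' Dependency between the two fitted parameters
#'
#' Squared correlation of the estimates of a and b,
#' `cov(a,b)^2 / (var(a) var(b))`, in `[0, 1]`. Values near 1 indicate the
#' parameters are nearly redundant for describing the data.
#'
#' @param fit A `powerlaw_fit`.
#' @return A number in `[0, 1]`, or `NA` (with a warning) when a parameter
#'   variance is zero, e.g. for a perfect or fixed-exponent fit.
#' @export
dependency <- function(fit) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  dependency_from_cov(fit$covariance, warn_degenerate = TRUE)
}

dependency_from_cov <- function(V, warn_degenerate = FALSE) {
  va <- V[1, 1]; vb <- V[2, 2]
  if (va <= 0 || vb <= 0) {
    if (warn_degenerate) warn("zero parameter variance: dependency undefined")
    return(NA_real_)
  }
  unname(V[1, 2]^2 / (va * vb))
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit%s: Y = %.4g * X^%.4g\n",
              if (!is.na(x$label)) paste0(" [", x$label, "]") else "",
              x$a, x$b))
  cat(sprintf("  n = %d, %s least squares%s\n", x$n,
              if (x$weighting == "none") "ordinary" else "1/y^2-weighted",
              if (!is.null(x$fix_b)) sprintf(", b fixed at %g", x$fix_b) else ""))
  cat(sprintf("  R^2 = %.4g\n", x$r_squared))
  cat(sprintf("  %g%% CI a: [%.4g, %.4g]\n", 100 * x$level, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  %g%% CI b: [%.4g, %.4g]\n", 100 * x$level, x$ci_b[1], x$ci_b[2]))
  if (!is.na(x$dependency)) {
    cat(sprintf("  parameter dependency = %.3f\n", x$dependency))
  }
  if (!x$converged) cat("  WARNING: minimizer did not converge\n")
  invisible(x)
}

#' @export
residuals.powerlaw_fit <- function(object, ...) {
  object$data$y - object$a * object$data$x^object$b
}

#' @export
predict.powerlaw_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else as.numeric(newdata$x %||% newdata)
  object$a * x^object$b
}

#' Tidy a power-law fit
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with estimate, standard error,
#'   t statistic, p value and confidence bounds. `glance()`: a one-row model
#'   summary.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  est <- c(a = x$a, b = x$b)
  se <- x$se
  stat <- est / se
  tibble::tibble(
    term = c("a", "b"),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * pt_abs(stat, x$df),
    conf.low = c(x$ci_a[1], x$ci_b[1]),
    conf.high = c(x$ci_a[2], x$ci_b[2])
  )
}

pt_abs <- function(stat, df) stats::pt(abs(stat), df, lower.tail = FALSE)

#' @rdname tidy.powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(
    label = x$label, nobs = x$n, a = x$a, b = x$b,
    r.squared = x$r_squared, sigma = sqrt(x$sigma2),
    df.residual = x$df, dependency = x$dependency,
    weighting = x$weighting, converged = x$converged
  )
}
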