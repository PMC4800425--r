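#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Tests departure from normality by combining the normalizing transforms of
#' sample skewness and kurtosis: `K2 = Z(sqrt(b1))^2 + Z(b2)^2`, referred to
#' a chi-squared distribution with 2 df. Transform constants follow
#' D'Agostino, Belanger & D'Agostino (1990), the canonical published
#' formulas. The kurtosis transform requires n >= 20.
#'
#' Nonlinear least squares assumes Gaussian residuals; apply this to the
#' pooled y-residuals of a power-law fit via [k2_residuals()], or directly
#' to raw samples (e.g. a condition's marginal bout-length values).
#'
#' @param x Numeric sample, n >= 20, nonzero variance.
#' @return A one-row test tibble: `name`, `statistic`, `p_value`, `df`, `n`.
#' @examples
#' dagostino_k2(rnorm(100))
#' @export
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20L) abort(sprintf("K2 test needs n >= 20 (kurtosis transform validity); got %d", n))
  if (var(x) == 0) abort("degenerate sample: zero variance")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / m2^1.5       # sqrt(b1)
  b2 <- mean((x - m)^4) / m2^2

  # skewness transform (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(Vb2)
  sqb1_b2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1_b2 * (2 / sqb1_b2 + sqrt(1 + 4 / sqb1_b2^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Z1^2 + Z2^2
  tibble::tibble(
    name = "dagostino_pearson_k2",
    statistic = K2,
    p_value = pchisq(K2, df = 2, lower.tail = FALSE),
    df = 2,
    n = n
  )
}

#' K2 normality test on the residuals of a power-law fit
#'
#' @param fit A `powerlaw_fit`.
#' @return As [dagostino_k2()], applied to the fit's pooled unweighted
#'   y-residuals.
#' @export
k2_residuals <- function(fit) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  out <- dagostino_k2(residuals(fit))
  out$name <- "dagostino_pearson_k2_residuals"
  out
}

#' Two-tailed two-sample heteroscedastic (Welch) t-test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; the standard test for genotype comparisons of per-pair sleep
#' metrics. Wraps [stats::t.test()].
#'
#' @param sample_a,sample_b Numeric samples, each with at least 2 finite
#'   values.
#' @return A one-row test tibble: `name`, `statistic`, `p_value`, `df`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    abort("Welch test needs at least 2 finite values per sample")
  }
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    # t.test errors on two constant samples; identical constants carry p = 1
    return(tibble::tibble(
      name = "welch_t", statistic = 0,
      p_value = if (mean(sample_a) == mean(sample_b)) 1 else NA_real_,
      df = NA_real_, n_a = length(sample_a), n_b = length(sample_b),
      mean_a = mean(sample_a), mean_b = mean(sample_b)
    ))
  }
  tt <- t.test(sample_a, sample_b, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(
    name = "welch_t",
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    n_a = length(sample_a), n_b = length(sample_b),
    mean_a = mean(sample_a), mean_b = mean(sample_b)
  )
}
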