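# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: sleep scoring by explicit interval arithmetic
# instead of run-length encoding, and curve fitting by grid search plus
# Nelder-Mead refinement instead of Levenberg-Marquardt.

# Brute-force period summaries from a count vector. `abs_min` are absolute
# experiment minutes; maximal zero runs >= min_sleep are sleep, intersected
# with each 720-min period window (a run crossing a boundary contributes one
# bout per window, no re-thresholding).
oracle_period_summaries <- function(counts, abs_min, min_sleep = 5L) {
  runs <- list()
  i <- 1L
  n <- length(counts)
  while (i <= n) {
    if (counts[i] == 0L) {
      j <- i
      while (j < n && counts[j + 1L] == 0L) j <- j + 1L
      if (j - i + 1L >= min_sleep) {
        runs[[length(runs) + 1L]] <- c(abs_min[i], abs_min[j])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  periods <- unique(abs_min %/% 720L)
  do.call(rbind, lapply(periods, function(p) {
    w0 <- p * 720L; w1 <- w0 + 719L
    total <- 0L; count <- 0L
    for (r in runs) {
      lo <- max(r[1], w0); hi <- min(r[2], w1)
      if (lo <= hi) {
        total <- total + (hi - lo + 1L)
        count <- count + 1L
      }
    }
    data.frame(period_index = p, total_sleep = total, bout_count = count)
  }))
}

# Dense grid search + Nelder-Mead polish for the weighted power-law SSE.
oracle_powerlaw <- function(x, y, w = rep(1, length(x))) {
  sse <- function(p) sum(w * (y - p[1] * x^p[2])^2)
  ll <- stats::coef(stats::lm(log(y) ~ log(x)))
  a0 <- exp(ll[1])
  grid <- expand.grid(a = a0 * seq(0.2, 3, length.out = 60),
                      b = seq(-3, 1, length.out = 80))
  vals <- mapply(function(a, b) sse(c(a, b)), grid$a, grid$b)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(a = fit$par[1], b = fit$par[2], sse = fit$value)
}

# A contiguous random trace for one animal (full days).
random_trace <- function(n_days = 2L, p_zero = 0.6, id = "a1") {
  n <- n_days * 1440L
  counts <- ifelse(stats::runif(n) < p_zero, 0L, stats::rpois(n, 2) + 1L)
  zt <- rep(0:1439, n_days)
  tibble::tibble(
    animal_id = id,
    day_index = rep(seq_len(n_days), each = 1440L),
    zt_minute = zt,
    lights_on = zt < 720L,
    count = as.integer(counts)
  )
}

# Minimal trace builder: one animal, one period, given counts.
mini_trace <- function(counts, period = "night", day_index = 1L, id = "a1",
                       start = 0L) {
  offset <- if (period == "day") 0L else 720L
  zt <- offset + start + seq_along(counts) - 1L
  tibble::tibble(animal_id = id, day_index = as.integer(day_index),
                 zt_minute = as.integer(zt), lights_on = zt < 720L,
                 count = as.integer(counts))
}
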