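# Independent brute-force oracles used to cross-check the package's
# statistics, written naively (explicit loops, no shared code paths).

# All pairwise slopes of a scatter, as the Passing-Bablok estimator defines
# them: loop over i < j, skip vertical pairs, discard slopes exactly -1.
oracle_pb_slopes <- function(x, y) {
  n <- length(x)
  s <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) {
        sij <- (y[j] - y[i]) / (x[j] - x[i])
        if (sij != -1) s <- c(s, sij)
      }
    }
  }
  s
}

# Shifted-median slope and median-residual intercept, by direct indexing.
# valid = FALSE marks scatters where the shifted-median rank leaves 1..N
# (negatively related methods), for which the estimator is undefined.
oracle_pb_fit <- function(x, y) {
  s <- sort(oracle_pb_slopes(x, y))
  N <- length(s)
  K <- 0
  for (v in s) if (v < -1) K <- K + 1
  hi_rank <- if (N %% 2 == 1) (N + 1) / 2 + K else N / 2 + 1 + K
  if (N == 0 || hi_rank > N) {
    return(list(valid = FALSE))
  }
  slope <- if (N %% 2 == 1) {
    s[(N + 1) / 2 + K]
  } else {
    (s[N / 2 + K] + s[N / 2 + 1 + K]) / 2
  }
  res <- sort(y - slope * x)
  m <- length(res)
  intercept <- if (m %% 2 == 1) res[(m + 1) / 2] else
    (res[m / 2] + res[m / 2 + 1]) / 2
  list(valid = TRUE, slope = slope, intercept = intercept,
       n_slopes = N, K = K)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the nonzero differences.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  stats <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    stats[m + 1] <- sum(r[signs == 1])
  }
  mean_v <- n * (n + 1) / 4
  p <- mean(abs(stats - mean_v) >= abs(v_obs - mean_v))
  min(1, p)
}

# Every 3x3 contingency table with total count exactly n (compositions of
# n into 9 ordered non-negative parts).
oracle_tables_with_total <- function(n, cells = 9) {
  if (cells == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (first in 0:n) {
    rest <- oracle_tables_with_total(n - first, cells - 1)
    out[[first + 1]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# Random small method-comparison scatter (ties included on purpose).
random_scatter <- function(n) {
  x <- round(runif(n, 0, 4), 1)
  while (length(unique(x)) == 1) x <- round(runif(n, 0, 4), 1)
  y <- round(0.5 + runif(1, 0.5, 2) * x + rnorm(n, 0, 0.5), 1)
  list(x = x, y = y)
}
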