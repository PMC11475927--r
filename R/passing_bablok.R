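#' Passing-Bablok regression for method comparison
#'
#' Nonparametric regression of `y` on `x` (equation `y = k*x + b`) designed
#' for comparing two measurement methods that are both subject to error.
#' The slope is a shifted median of all pairwise slopes
#' `S_ij = (y_j - y_i) / (x_j - x_i)`:
#'
#' * pairs with `x_i = x_j` contribute no slope;
#' * slopes exactly equal to -1 are discarded;
#' * with `K` = number of remaining slopes below -1 and the `N` remaining
#'   slopes sorted ascending, the estimate is the `K`-shifted median
#'   (for odd `N` the element at rank `(N+1)/2 + K`; for even `N` the mean
#'   of ranks `N/2 + K` and `N/2 + 1 + K`).
#'
#' The intercept is `median(y - k*x)`. The slope confidence interval comes
#' from the rank bounds `M1 = round((N - C)/2)` and `M2 = N - M1 + 1` with
#' `C = z * sqrt(n(n-1)(2n+5)/18)` (`z` the standard normal quantile at
#' `1 - alpha/2`; rank rounding is round-half-to-even), taking the sorted
#' slopes at ranks `M1 + K` and `M2 + K`; the intercept interval evaluates
#' `median(y - k*x)` at the two slope bounds. A slope outside whose interval
#' 1 does not fall indicates *proportional* bias between the methods; an
#' intercept interval excluding 0 indicates *constant* bias. For very small
#' `n` the rank bounds can fall outside `1..N`; the intervals (and bias
#' flags) are then undefined and returned as `NA` with a warning advising a
#' larger sample.
#'
#' @param x,y Equal-length numeric vectors (n >= 3) of paired measurements
#'   by the two methods; `x` must not be constant.
#' @param alpha Two-sided significance level for the confidence intervals
#'   (default 0.05 for 95% intervals).
#' @return Object of class `passing_bablok`: list with `slope`, `intercept`,
#'   `ci_slope`, `ci_intercept` (length-2 numeric, possibly `NA`),
#'   `proportional_bias`, `constant_bias` (logical, possibly `NA`), `n`,
#'   `n_slopes`, `alpha`, and the input `data`. Use [tidy()] / [glance()]
#'   for tibble summaries and [autoplot()] for the scatter with the fitted
#'   line.
#' @export
#' @examples
#' fit <- passing_bablok(1:5, c(2.1, 3.9, 6.2, 8.0, 9.9))
#' tidy(fit)
passing_bablok <- function(x, y, alpha = 0.05) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort("x and y must be equal-length numeric vectors.")
  }
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) abort("x and y must be finite.")
  n <- length(x)
  if (n < 3) abort("Passing-Bablok needs at least 3 paired points.")
  if (length(unique(x)) == 1) abort("x is constant; slope undefined.")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1).")
  }

  S <- pairwise_slopes(x, y)
  if (length(S) == 0) abort("all pairwise slopes are undefined.")
  S <- S[S != -1]                     # exact -1 slopes are discarded
  N <- length(S)
  if (N == 0) abort("all pairwise slopes are undefined or equal to -1.")
  K <- sum(S < -1)
  S <- sort(S)

  med_idx <- if (N %% 2 == 1) (N + 1) / 2 + K else
    c(N / 2 + K, N / 2 + 1 + K)
  if (any(med_idx < 1) || any(med_idx > N)) {
    abort(paste0(
      "More than half of the pairwise slopes lie below -1; the methods ",
      "appear negatively related and the Passing-Bablok estimator is ",
      "undefined."
    ))
  }
  slope <- shifted_median(S, K)
  intercept <- median(y - slope * x)

  C <- qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  lo_idx <- M1 + K
  hi_idx <- M2 + K
  if (lo_idx < 1 || hi_idx > N) {
    warn(paste0("Confidence-interval ranks fall outside 1..", N,
                " at this sample size; intervals and bias flags are NA.",
                " Use more points for inference."))
    ci_slope <- c(NA_real_, NA_real_)
    ci_intercept <- c(NA_real_, NA_real_)
    prop_bias <- NA
    const_bias <- NA
  } else {
    ci_slope <- c(S[lo_idx], S[hi_idx])
    ci_intercept <- sort(c(median(y - ci_slope[2] * x),
                           median(y - ci_slope[1] * x)))
    prop_bias <- ci_slope[1] > 1 || ci_slope[2] < 1
    const_bias <- ci_intercept[1] > 0 || ci_intercept[2] < 0
  }

  structure(
    list(slope = slope, intercept = intercept,
         ci_slope = ci_slope, ci_intercept = ci_intercept,
         proportional_bias = prop_bias, constant_bias = const_bias,
         n = n, n_slopes = N, alpha = alpha,
         data = tibble(x = x, y = y)),
    class = "passing_bablok"
  )
}

pairwise_slopes <- function(x, y) {
  idx <- which(upper.tri(matrix(0, length(x), length(x))), arr.ind = TRUE)
  dx <- x[idx[, 2]] - x[idx[, 1]]
  dy <- y[idx[, 2]] - y[idx[, 1]]
  keep <- dx != 0
  dy[keep] / dx[keep]
}

shifted_median <- function(S_sorted, K) {
  N <- length(S_sorted)
  if (N %% 2 == 1) {
    S_sorted[(N + 1) / 2 + K]
  } else {
    mean(S_sorted[c(N / 2 + K, N / 2 + 1 + K)])
  }
}

#' @export
print.passing_bablok <- function(x, ...) {
  fmt <- function(ci) {
    if (anyNA(ci)) "[NA, NA]" else sprintf("[%.4g, %.4g]", ci[1], ci[2])
  }
  cat(sprintf(
    "<passing_bablok> y = %.4g x + %.4g  (n = %d)\n  slope CI %s%s | intercept CI %s%s\n",
    x$slope, x$intercept, x$n,
    fmt(x$ci_slope),
    if (isTRUE(x$proportional_bias)) " *proportional bias*" else "",
    fmt(x$ci_intercept),
    if (isTRUE(x$constant_bias)) " *constant bias*" else ""
  ))
  invisible(x)
}

#' @rdname passing_bablok
#' @param x A `passing_bablok` fit.
#' @param ... Unused.
#' @method tidy passing_bablok
#' @export
tidy.passing_bablok <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf.low = c(x$ci_slope[1], x$ci_intercept[1]),
    conf.high = c(x$ci_slope[2], x$ci_intercept[2]),
    bias = c(x$proportional_bias, x$constant_bias)
  )
}

#' @rdname passing_bablok
#' @method glance passing_bablok
#' @export
glance.passing_bablok <- function(x, ...) {
  tibble(
    n = x$n, n_slopes = x$n_slopes, slope = x$slope,
    intercept = x$intercept,
    slope_lo = x$ci_slope[1], slope_hi = x$ci_slope[2],
    intercept_lo = x$ci_intercept[1], intercept_hi = x$ci_intercept[2],
    proportional_bias = x$proportional_bias,
    constant_bias = x$constant_bias, alpha = x$alpha
  )
}

#' Relative discrepancy between two quantitative methods
#'
#' Per-observation scale-free disagreement
#' `d_i = |y_i - x_i| / max(x_i, y_i)`, lying in \[0, 1\] with 0 meaning the
#' two measurements agree exactly (a pair with `x_i = y_i = 0` is defined
#' as 0). Complements regression-based comparison: scatter around the
#' identity line inflates `d` even when no proportional or constant bias is
#' detectable. Quartiles use the linear-interpolation convention
#' (`stats::quantile()` type 7).
#'
#' @param x,y Equal-length non-negative numeric vectors.
#' @return Object of class `cn_discrepancy`: list with `d` (the per-pair
#'   values), `median`, `q1`, `q3`, `n`. [tidy()] returns the per-pair
#'   values; [glance()] the quartile summary.
#' @export
#' @examples
#' relative_discrepancy(c(2, 2, 2), c(2, 3, 4))
relative_discrepancy <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort("x and y must be equal-length numeric vectors.")
  }
  if (any(!is.finite(x) | !is.finite(y) | x < 0 | y < 0)) {
    abort("relative discrepancy requires finite non-negative values.")
  }
  denom <- pmax(x, y)
  d <- ifelse(denom == 0, 0, abs(y - x) / denom)
  qs <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(
    list(d = d, median = qs[2], q1 = qs[1], q3 = qs[3], n = length(d)),
    class = "cn_discrepancy"
  )
}

#' @export
print.cn_discrepancy <- function(x, ...) {
  cat(sprintf("<cn_discrepancy> n = %d | median %.3f [Q1 %.3f, Q3 %.3f]\n",
              x$n, x$median, x$q1, x$q3))
  invisible(x)
}

#' @rdname relative_discrepancy
#' @param x A `cn_discrepancy` object.
#' @param ... Unused.
#' @method tidy cn_discrepancy
#' @export
tidy.cn_discrepancy <- function(x, ...) {
  tibble(d = x$d)
}

#' @rdname relative_discrepancy
#' @method glance cn_discrepancy
#' @export
glance.cn_discrepancy <- function(x, ...) {
  tibble(n = x$n, d_median = x$median, d_q1 = x$q1, d_q3 = x$q3)
}

#' Pairwise quantitative-agreement panel
#'
#' For each pair of quantitative methods, pools every (gene, patient,
#' tissue) sample measured by both, fits a Passing-Bablok regression and
#' computes the relative-discrepancy summary. Restrict to QC-passing
#' groups by supplying a QC report (see [qc_normal_medians()]).
#'
#' @param ds A [cnv_dataset()] or coercible data frame.
#' @param method_pairs Pairs to compare: a list of length-2 character
#'   vectors, or `"a:b"` strings; within a pair the first method is `x`,
#'   the second `y`.
#' @param genes Genes pooled into each comparison; all shared genes by
#'   default.
#' @param qc Optional QC report from [qc_normal_medians()]; failing
#'   (method, gene) groups are excluded before pooling.
#' @param alpha Significance level for the regression intervals.
#' @return Tibble of class `quant_panel`, one row per pair: `pair`, `n`,
#'   `slope`, `slope_lo`, `slope_hi`, `intercept`, `intercept_lo`,
#'   `intercept_hi`, `proportional_bias`, `constant_bias`, `d_median`,
#'   `d_q1`, `d_q3`, with the fit objects in attribute `fits` and the
#'   pooled points in attribute `points`.
#' @export
quantitative_panel <- function(ds, method_pairs, genes = NULL, qc = NULL,
                               alpha = 0.05) {
  ds <- as_cnv_dataset(ds)
  if (!is.null(qc)) ds <- apply_qc(ds, qc)
  pairs <- normalize_pairs(method_pairs)
  tbl <- dplyr::filter(as_tibble(ds), .data$value_kind == "quantitative")
  if (!is.null(genes)) tbl <- dplyr::filter(tbl, .data$gene %in% !!genes)

  fits <- list()
  points <- list()
  rows <- purrr::map(pairs, function(pr) {
    check_method(ds, pr[1], kind = "quantitative")
    check_method(ds, pr[2], kind = "quantitative")
    a <- dplyr::filter(tbl, .data$method_id == pr[1])
    b <- dplyr::filter(tbl, .data$method_id == pr[2])
    shared <- dplyr::inner_join(
      dplyr::select(a, "patient_id", "tissue", "gene", x = "value"),
      dplyr::select(b, "patient_id", "tissue", "gene", y = "value"),
      by = c("patient_id", "tissue", "gene")
    )
    shared <- dplyr::arrange(shared, .data$gene, .data$patient_id,
                             .data$tissue)
    pair_id <- paste(pr, collapse = ":")
    if (nrow(shared) < 3) {
      abort(paste0("Pair ", pair_id, ": fewer than 3 shared points."))
    }
    fit <- passing_bablok(shared$x, shared$y, alpha = alpha)
    disc <- relative_discrepancy(shared$x, shared$y)
    fits[[pair_id]] <<- fit
    points[[pair_id]] <<- shared
    dplyr::bind_cols(
      tibble(pair = pair_id),
      dplyr::select(glance(fit), -"alpha"),
      dplyr::select(glance(disc), -"n")
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  attr(out, "points") <- points
  class(out) <- c("quant_panel", class(out))
  out
}
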